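#' Load a BEELINE-style benchmark dataset directory
#'
#' Expects `ExpressionData.csv` (genes in rows, cells in columns, gene names
#' in the first column) and `refNetwork.csv` (columns Gene1, Gene2 and
#' optionally Type) in `dir`. Duplicate reference rows are collapsed. A
#' warning is issued when the cell count differs from the 200 cells the
#' benchmark protocol assumes.
#'
#' @param dir dataset directory.
#' @return List with `expression` (`sctiger_matrix`) and `reference` (a
#'   `reference_network`: data.frame of edges plus the gene universe).
#' @export
load_beeline <- function(dir) {
  expr_f <- file.path(dir, "ExpressionData.csv")
  ref_f <- file.path(dir, "refNetwork.csv")
  if (!file.exists(expr_f) || !file.exists(ref_f))
    stopf("directory %s must contain ExpressionData.csv and refNetwork.csv", dir)
  m <- load_matrix(expr_f, format = "csv", condition = "benchmark")
  ref <- read.csv(ref_f, stringsAsFactors = FALSE)
  if (!all(c("Gene1", "Gene2") %in% names(ref)))
    stopf("refNetwork.csv must have columns Gene1 and Gene2")
  edges <- unique(data.frame(from = ref$Gene1, to = ref$Gene2,
                             type = if ("Type" %in% names(ref)) ref$Type
                                    else NA_character_,
                             stringsAsFactors = FALSE))
  if (ncol(m$counts) != 200)
    warnf("dataset has %d cells; the benchmark protocol assumes 200",
          ncol(m$counts))
  reference <- structure(list(edges = edges, genes = gene_ids(m)),
                         class = "reference_network")
  list(expression = m, reference = reference)
}

#' Canonicalize an edge set for benchmark scoring
#'
#' Self-loops are removed, direction and sign are dropped, and each pair is
#' represented once as an alphabetically ordered unordered pair, so all
#' methods are scored identically regardless of whether they report
#' direction, sign or self-loops.
#'
#' @param from,to character vectors of edge endpoints (or a 2-column
#'   data.frame/matrix passed as `from`).
#' @return data.frame with columns `a`, `b` (a < b), one row per unordered
#'   pair.
#' @export
canonicalize_edges <- function(from, to = NULL) {
  if (is.null(to)) {
    from <- as.data.frame(from)
    to <- as.character(from[[2]]); from <- as.character(from[[1]])
  }
  from <- as.character(from); to <- as.character(to)
  keep <- from != to                       # drop self-loops
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  unique(data.frame(a = a, b = b, stringsAsFactors = FALSE)[order(a, b), ,
                                                            drop = FALSE])
}

#' Confusion metrics over unordered gene pairs
#'
#' Scores a canonicalized predicted edge set against a canonicalized
#' reference over the universe of all unordered non-self gene pairs:
#' TN = C(n, 2) - TP - FP - FN. Ratios whose denominator is zero are
#' reported as 0 with `undefined` flagging which ones.
#'
#' @param pred,ref canonical pair sets (as returned by
#'   [canonicalize_edges()]).
#' @param universe character vector of genes defining the negative universe.
#' @return A `benchmark_result`: TP, FP, FN, TN, precision, recall,
#'   specificity, f1, undefined.
#' @export
compute_metrics <- function(pred, ref, universe) {
  pk <- paste(pred$a, pred$b, sep = "\r")
  rk <- paste(ref$a, ref$b, sep = "\r")
  all_genes <- unique(c(pred$a, pred$b, ref$a, ref$b))
  if (!all(all_genes %in% universe))
    stopf("edge gene(s) outside the declared universe: %s",
          paste(head(setdiff(all_genes, universe), 3), collapse = ", "))
  n <- length(universe)
  n_pairs <- n * (n - 1) / 2
  TP <- length(intersect(pk, rk))
  FP <- length(setdiff(pk, rk))
  FN <- length(setdiff(rk, pk))
  TN <- n_pairs - TP - FP - FN
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); 0 } else num / den
  }
  precision <- ratio(TP, TP + FP, "precision")
  recall <- ratio(TP, TP + FN, "recall")
  specificity <- ratio(TN, TN + FP, "specificity")
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else { undefined <- c(undefined, "f1"); 0 }
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 precision = precision, recall = recall,
                 specificity = specificity, f1 = f1,
                 undefined = undefined),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> P=%.3f R=%.3f spec=%.3f F1=%.3f (TP=%d FP=%d FN=%d TN=%d)%s\n",
              x$precision, x$recall, x$specificity, x$f1,
              x$TP, x$FP, x$FN, x$TN,
              if (length(x$undefined)) paste0(" [undefined: ",
                                              paste(x$undefined, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Run the benchmark protocol on one dataset
#'
#' The paired-input stages are bypassed (no control condition exists in the
#' benchmark data): the expression matrix is log-normalized, pseudotime
#' ordered and fed directly to causal discovery, repeated over random cell
#' subsamples, thresholded against a gene-shuffled background with the
#' negative binomial model, and scored against the reference network under
#' the undirected/unsigned/no-self-loop canonicalization.
#'
#' @param dir BEELINE-style dataset directory.
#' @param cfg an [addstcn_config()].
#' @param R discovery repetitions (and background repetitions).
#' @param alpha significance level.
#' @param subsample_frac fraction of cells drawn per repetition.
#' @param seed integer seed.
#' @param normalize depth-normalize before ordering (the curated simulated
#'   datasets are not UMI counts, so this defaults to a plain log1p).
#' @return List with `metrics` (a `benchmark_result`), `grn` (the
#'   significant network) and `observed`/`background` frequency tables.
#' @export
benchmark_dataset <- function(dir, cfg = addstcn_config(), R = 10,
                              alpha = 0.05, subsample_frac = 0.9, seed = 0,
                              normalize = FALSE) {
  ds <- load_beeline(dir)
  m <- ds$expression
  if (normalize) m <- normalize_counts(qc_filter(m, qc_config(0, 0, 1, 0)))
  else m <- expression_matrix(log1p(m$counts), m$condition, normalized = TRUE)
  genes <- gene_ids(m)
  obs <- benchmark_runs(m, R, cfg, subsample_frac, seed, shuffle = FALSE)
  bg <- benchmark_runs(m, R, cfg, subsample_frac, seed + 1, shuffle = TRUE)
  model <- fit_significance(bg, alpha = alpha,
                            universe_size = length(genes) * (length(genes) - 1))
  grn <- significant_edges(obs, model)
  pred <- canonicalize_edges(grn$edges$cause, grn$edges$target)
  ref <- canonicalize_edges(ds$reference$edges$from, ds$reference$edges$to)
  metrics <- compute_metrics(pred, ref, genes)
  list(metrics = metrics, grn = grn, observed = obs, background = bg,
       model = model, reference = ds$reference)
}

# repeated subsample -> order -> discover passes over a single expression
# matrix (benchmark mode: no case/control pairing, no codiff, no candidate
# correlation screening)
benchmark_runs <- function(m, R, cfg, subsample_frac, seed, shuffle = FALSE) {
  run_edges <- vector("list", R)
  n_keep <- max(2, floor(subsample_frac * ncol(m$counts)))
  for (r in seq_len(R)) {
    sr <- derive_seed(seed, r)
    mm <- if (shuffle) shuffle_genewise(m, derive_seed(sr, 11)) else m
    ms <- subsample_cells(mm, n_keep, seed = derive_seed(sr, 1))
    ord <- order_cells(ms, seed = derive_seed(sr, 3))
    mo <- apply_ordering(ms, ord)
    keep <- apply(mo$counts, 1, sd) > 0
    X <- codiff_matrix(mo$counts[keep, , drop = FALSE])
    cfg_run <- cfg; cfg_run$seed <- sr
    g <- discover(X, cfg = cfg_run)
    e <- g$edges
    e$goi <- NA_character_
    run_edges[[r]] <- e[, c("cause", "target", "sign", "delay", "goi")]
  }
  build_freq_table(run_edges, R, shuffle, gene_ids(m),
                   max(1, nrow(m$counts) - 1))
}
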