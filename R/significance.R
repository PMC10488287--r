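#' Repeated subsampled discovery runs
#'
#' Repeats the downstream pipeline `R` times: subsample the larger condition
#' to match cell counts, order each condition along its own pseudotime
#' trajectory, form the co-differential matrix, screen candidates for each
#' gene of interest and run causal discovery. Edge detections are counted
#' per (cause, target, sign) identity; delays are collected per run so the
#' modal delay can be reported later.
#'
#' @param case,control normalized, QC-filtered `sctiger_matrix` objects over
#'   a shared gene universe.
#' @param targets genes of interest.
#' @param R number of repetitions.
#' @param cfg an [addstcn_config()] for the causal engine.
#' @param top_k candidate genes screened per gene of interest.
#' @param max_steps optional maximum delay for reported edges.
#' @param seed integer seed; run r uses a seed derived from `seed + r`.
#' @param shuffle_background if `TRUE`, every gene's values are shuffled
#'   across cells (independently per gene) *once*, before the repetition
#'   loop, destroying all structure while preserving per-gene marginals;
#'   the repeated runs then process the shuffled matrices exactly like the
#'   observed ones. Shuffling once (rather than per run) matches the
#'   observed runs' persistence structure: the subsample overlap between
#'   runs is the same in the background as in the observed table, which is
#'   what makes the background frequencies a calibrated null.
#' @return An `edge_freq_table`: data.frame of per-edge counts plus
#'   attributes `R`, `is_background`, `universe_size` and `run_edges`.
#' @export
run_permutations <- function(case, control, targets, R = 100,
                             cfg = addstcn_config(), top_k = 100,
                             max_steps = NULL, seed = 0,
                             shuffle_background = FALSE) {
  assert_matrix(case, "case"); assert_matrix(control, "control")
  if (R < 1) stopf("R must be >= 1")
  ca <- case; co <- control
  if (shuffle_background) {
    h_ca <- name_hash(paste(sort(colnames(case$counts)), collapse = ""))
    h_co <- name_hash(paste(sort(colnames(control$counts)), collapse = ""))
    ca <- shuffle_genewise(ca, derive_seed(seed, 11 + h_ca))
    co <- shuffle_genewise(co, derive_seed(seed, 11 + h_co))
  }
  run_edges <- vector("list", R)
  for (r in seq_len(R)) {
    sr <- derive_seed(seed, r)
    run_edges[[r]] <- single_run(ca, co, targets, cfg, top_k, max_steps, sr)
  }
  build_freq_table(run_edges, R, shuffle_background, targets, top_k)
}

#' @rdname run_permutations
#' @export
background_run <- function(case, control, targets, R = 100,
                           cfg = addstcn_config(), top_k = 100,
                           max_steps = NULL, seed = 0) {
  run_permutations(case, control, targets, R = R, cfg = cfg, top_k = top_k,
                   max_steps = max_steps, seed = seed,
                   shuffle_background = TRUE)
}

# shuffle each gene's values across cells, independently per gene
shuffle_genewise <- function(m, seed) {
  x <- m$counts
  x <- with_seed(seed, {
    for (i in seq_len(nrow(x))) x[i, ] <- x[i, sample(ncol(x))]
    x
  })
  expression_matrix(x, m$condition, normalized = m$normalized)
}

# one subsample -> order -> codiff -> candidates -> discover pass.
# Per-side seeds derive from a hash of the side's cell ids, not from the
# case/control role, so flipping the two conditions reproduces the same
# subsamples and orderings.
single_run <- function(case, control, targets, cfg, top_k, max_steps, seed) {
  n_match <- min(ncol(case$counts), ncol(control$counts))
  h_ca <- name_hash(paste(sort(colnames(case$counts)), collapse = ""))
  h_co <- name_hash(paste(sort(colnames(control$counts)), collapse = ""))
  ca <- subsample_cells(case, n_match, seed = derive_seed(seed, h_ca))
  co <- subsample_cells(control, n_match, seed = derive_seed(seed, h_co))
  orda <- order_cells(ca, seed = derive_seed(seed, h_ca + 1))
  ordo <- order_cells(co, seed = derive_seed(seed, h_co + 1))
  X <- compute_codiff(apply_ordering(ca, orda), apply_ordering(co, ordo))
  cfg_run <- cfg; cfg_run$seed <- seed
  edges <- list()
  for (goi in targets) {
    if (sd(X$X[goi, ]) == 0) next
    cand <- select_candidates(X, goi, k = top_k)
    sub_genes <- c(goi, cand$candidates$gene)
    if (length(sub_genes) < 2) next
    Xs <- codiff_matrix(X$X[sub_genes, , drop = FALSE])
    g <- discover(Xs, targets = goi, cfg = cfg_run, max_steps = max_steps)
    # the gene of interest may also act as the cause: model each candidate
    # as a target with the goi among its inputs
    if (nrow(g$edges) > 0) {
      g$edges$goi <- goi
      edges[[length(edges) + 1]] <- g$edges
    }
    rev_edges <- discover_toward(Xs, goi, cfg_run, max_steps)
    if (nrow(rev_edges) > 0) {
      rev_edges$goi <- goi
      edges[[length(edges) + 1]] <- rev_edges
    }
  }
  if (length(edges) == 0)
    return(data.frame(cause = character(0), target = character(0),
                      sign = character(0), delay = integer(0),
                      goi = character(0), stringsAsFactors = FALSE))
  unique(do.call(rbind, edges)[, c("cause", "target", "sign", "delay", "goi")])
}

# discover edges goi -> candidate by training networks with each candidate
# as target and retaining only edges whose cause is the goi
discover_toward <- function(Xs, goi, cfg, max_steps) {
  g <- discover(Xs, targets = setdiff(rownames(Xs$X), goi), cfg = cfg,
                max_steps = max_steps)
  g$edges[g$edges$cause == goi, , drop = FALSE]
}

build_freq_table <- function(run_edges, R, is_background, targets, top_k) {
  all_e <- do.call(rbind, run_edges[vapply(run_edges, nrow, 1L) > 0])
  if (is.null(all_e) || nrow(all_e) == 0) {
    tab <- data.frame(cause = character(0), target = character(0),
                      sign = character(0), count = integer(0),
                      modal_delay = integer(0), goi = character(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(all_e$cause, all_e$target, all_e$sign, sep = "\r")
    tab <- do.call(rbind, lapply(split(all_e, key), function(d) {
      data.frame(cause = d$cause[1], target = d$target[1], sign = d$sign[1],
                 count = nrow(d),
                 modal_delay = modal_value(d$delay),
                 goi = paste(sort(unique(d$goi)), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
  }
  structure(tab, class = c("edge_freq_table", "data.frame"),
            R = R, is_background = is_background,
            universe_size = length(targets) * top_k * 2L,
            targets = targets)
}

modal_value <- function(v) {
  tb <- table(v)
  as.integer(names(tb)[which.max(tb)])
}

#' Fit the background significance model
#'
#' Pools the background per-edge detection counts (padding with zeros up to
#' the candidate-pair universe size), fits a negative binomial by the method
#' of moments, and derives the minimum detection count whose upper tail
#' probability is at most `alpha`. Falls back to a Poisson model when the
#' sample variance does not exceed the mean, and to the convention
#' `min_detections = 1` when the background contains no detections at all.
#'
#' @param background an `edge_freq_table` from [background_run()].
#' @param alpha significance level.
#' @param universe_size number of candidate edges over which zeros are
#'   counted; defaults to the table's recorded universe.
#' @param family_wise if `TRUE`, `alpha` bounds the *expected number* of
#'   background-level edges crossing the threshold over the whole candidate
#'   universe (the tail criterion becomes `tail(m) <= alpha /
#'   universe_size`), so a null dataset yields an empty network with
#'   probability about `exp(-alpha)`. With `FALSE` (default) `alpha` is the
#'   per-edge tail bound; over a universe of `U` candidates a null dataset
#'   then still passes about `U * alpha` edges. The pipeline runs with the
#'   family-wise mode.
#' @return A `significance_model` list: `mean`, `dispersion` (NA for the
#'   Poisson fallback), `alpha`, `min_detections`, `R`, and `tail(m)`
#'   function.
#' @export
fit_significance <- function(background, alpha = 0.05,
                             universe_size = NULL, family_wise = FALSE) {
  stopifnot(inherits(background, "edge_freq_table"))
  if (!isTRUE(attr(background, "is_background")))
    warnf("fitting significance model to a non-background frequency table")
  R <- attr(background, "R")
  universe_size <- universe_size %||% attr(background, "universe_size")
  if (universe_size < 1) stopf("empty candidate universe")
  counts <- c(background$count,
              rep(0, max(0, universe_size - nrow(background))))
  mu <- mean(counts); v <- var(counts)
  if (all(counts == 0)) {
    tail_fun <- function(m) ifelse(m <= 0, 1, 0)
    model <- list(mean = 0, dispersion = NA_real_, family = "degenerate")
  } else if (v > mu) {
    size <- mu^2 / (v - mu)            # moments: var = mu + mu^2/size
    tail_fun <- function(m) ifelse(m <= 0, 1,
                                   pnbinom(m - 1, size = size, mu = mu,
                                           lower.tail = FALSE))
    model <- list(mean = mu, dispersion = 1 / size, family = "nbinom",
                  size = size)
  } else {
    tail_fun <- function(m) ifelse(m <= 0, 1,
                                   ppois(m - 1, lambda = mu,
                                         lower.tail = FALSE))
    model <- list(mean = mu, dispersion = NA_real_, family = "poisson")
  }
  alpha_eff <- if (family_wise) alpha / universe_size else alpha
  m <- 0
  while (tail_fun(m) > alpha_eff && m <= R) m <- m + 1
  structure(c(model, list(alpha = alpha, family_wise = family_wise,
                          min_detections = as.integer(m), R = R,
                          tail = tail_fun, universe_size = universe_size)),
            class = "significance_model")
}

#' @export
print.significance_model <- function(x, ...) {
  cat(sprintf("<significance_model> %s(mean=%.3g%s), alpha=%g -> min detections %d of %d runs\n",
              x$family, x$mean,
              if (!is.na(x$dispersion)) sprintf(", dispersion=%.3g", x$dispersion) else "",
              x$alpha, x$min_detections, x$R))
  invisible(x)
}

#' Call significant edges against the background model
#'
#' Retains edges detected at least `min_detections` times, annotated with
#' their detection count and background tail probability. When one (cause,
#' target) pair was detected with both signs, the majority sign is kept; an
#' exact tie drops the pair (with a message).
#'
#' @param observed an `edge_freq_table` from [run_permutations()].
#' @param model a `significance_model` from [fit_significance()].
#' @return An `annotated_grn`: `causal_graph` whose edges carry `count`,
#'   `p_tail`, `modal_delay`, and source `goi` annotations.
#' @export
significant_edges <- function(observed, model) {
  stopifnot(inherits(observed, "edge_freq_table"),
            inherits(model, "significance_model"))
  if (!identical(attr(observed, "R"), model$R))
    stopf("observed table has R=%s but model was fitted for R=%s",
          attr(observed, "R"), model$R)
  tab <- observed[observed$count >= max(model$min_detections, 0), ,
                  drop = FALSE]
  # resolve sign conflicts per (cause, target): majority wins, tie drops
  if (nrow(tab) > 0) {
    key <- paste(tab$cause, tab$target, sep = "\r")
    keep <- rep(TRUE, nrow(tab))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      cnts <- tab$count[idx]
      if (max(cnts) == min(cnts)) {
        keep[idx] <- FALSE
        message(sprintf("sign tie for %s -> %s (both signs detected %d times); dropped",
                        tab$cause[idx[1]], tab$target[idx[1]], cnts[1]))
      } else keep[idx[cnts < max(cnts)]] <- FALSE
    }
    tab <- tab[keep, , drop = FALSE]
  }
  edges <- data.frame(cause = tab$cause, target = tab$target,
                      sign = tab$sign, delay = tab$modal_delay,
                      count = tab$count,
                      frequency = tab$count / model$R,
                      p_tail = vapply(tab$count, model$tail, 0),
                      goi = tab$goi, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  genes <- unique(c(attr(observed, "targets"), edges$cause, edges$target))
  g <- causal_graph(edges, genes)
  class(g) <- c("annotated_grn", class(g))
  g$goi <- attr(observed, "targets")
  g
}

#' Histogram of edge-detection frequencies
#'
#' Tabulates how many edges were detected at each frequency and optionally
#' writes a TSV and an SVG bar plot.
#'
#' @param freq an `edge_freq_table`.
#' @param path_tsv,path_svg optional output paths.
#' @return data.frame with columns count, n_edges.
#' @export
frequency_histogram <- function(freq, path_tsv = NULL, path_svg = NULL) {
  stopifnot(inherits(freq, "edge_freq_table"))
  tb <- table(factor(freq$count, levels = seq_len(attr(freq, "R"))))
  df <- data.frame(count = as.integer(names(tb)), n_edges = as.integer(tb))
  if (!is.null(path_tsv))
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_svg) && isTRUE(capabilities("cairo")[[1]])) {
    grDevices::svg(path_svg, width = 7, height = 4)
    graphics::barplot(df$n_edges, names.arg = df$count,
                      xlab = "detection count", ylab = "number of edges",
                      main = "edge detection frequencies", col = "steelblue")
    grDevices::dev.off()
  }
  df
}
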