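#' Full-run configuration
#'
#' Bundles every user-facing parameter of the pipeline: input locations (or
#' in-memory matrices), genes of interest, permutation counts, candidate
#' screening size, dropout threshold, significance level, delay cap, seed
#' and output directory. All defaults are overridable and the configuration
#' is serialized into the output directory for reproducibility.
#'
#' @param case,control paths to expression matrices or `sctiger_matrix`
#'   objects.
#' @param genes_of_interest character vector of genes of interest.
#' @param permutations number of subsampled discovery repetitions R.
#' @param top_k candidate genes screened per gene of interest.
#' @param max_dropout maximum pooled dropout fraction for gene inclusion.
#' @param alpha significance level for edge calling.
#' @param max_steps optional maximum pseudotime-step delay per edge.
#' @param qc a [qc_config()].
#' @param addstcn an [addstcn_config()].
#' @param target_sum normalization target per cell.
#' @param use_gpu accepted for interface compatibility; computation is CPU.
#' @param seed master seed for the run.
#' @param out_dir output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(case, control, genes_of_interest,
                       permutations = 100, top_k = 100, max_dropout = 0.9,
                       alpha = 0.05, max_steps = NULL, qc = qc_config(),
                       addstcn = addstcn_config(), target_sum = 1e4,
                       use_gpu = FALSE, seed = 0, out_dir = "sctiger_out") {
  stopifnot(permutations >= 1, top_k >= 1,
            max_dropout >= 0, max_dropout <= 1, alpha > 0, alpha <= 1)
  structure(list(case = case, control = control,
                 genes_of_interest = genes_of_interest,
                 permutations = as.integer(permutations),
                 top_k = as.integer(top_k), max_dropout = max_dropout,
                 alpha = alpha, max_steps = max_steps, qc = qc,
                 addstcn = addstcn, target_sum = target_sum,
                 use_gpu = isTRUE(use_gpu), seed = seed, out_dir = out_dir),
            class = "run_config")
}

resolve_matrix <- function(x, condition) {
  if (inherits(x, "sctiger_matrix")) x
  else load_matrix(x, condition = condition)
}

config_json <- function(cfg) {
  ser <- cfg
  ser$case <- if (inherits(cfg$case, "sctiger_matrix")) "<in-memory matrix>"
              else cfg$case
  ser$control <- if (inherits(cfg$control, "sctiger_matrix")) "<in-memory matrix>"
                 else cfg$control
  ser$qc <- unclass(ser$qc); ser$addstcn <- unclass(ser$addstcn)
  jsonlite::toJSON(unclass(ser), auto_unbox = TRUE, null = "null",
                   pretty = TRUE)
}

#' Execute the full inference pipeline
#'
#' Ingest, QC, normalization, dropout filtering, repeated subsampled
#' discovery, background runs, negative-binomial edge calling and export:
#' one GraphML per gene of interest, a merged GraphML, a Cytoscape-style
#' edge table, raw per-edge TSVs, detection-frequency histograms and the
#' serialized configuration.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-goi networks (`grns`), the merged
#'   network (`merged`), frequency tables and the significance model.
#' @export
run_full <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(config_json(cfg), file.path(cfg$out_dir, "config.json"))

  case <- stage("ingest", resolve_matrix(cfg$case, "case"))
  control <- stage("ingest", resolve_matrix(cfg$control, "control"))
  missing <- setdiff(cfg$genes_of_interest,
                     intersect(gene_ids(case), gene_ids(control)))
  if (length(missing) > 0)
    stopf("[ingest] gene(s) of interest absent from the data: %s",
          paste(missing, collapse = ", "))

  say("QC filtering (%d/%d case/control cells in)", ncol(case$counts),
      ncol(control$counts))
  case <- stage("qc", qc_filter(case, cfg$qc))
  control <- stage("qc", qc_filter(control, cfg$qc))
  flt <- stage("dropout_filter",
               filter_genes_by_dropout(case, control, cfg$max_dropout,
                                       cfg$genes_of_interest))
  case <- stage("normalize", normalize_counts(flt$case, cfg$target_sum))
  control <- stage("normalize", normalize_counts(flt$control, cfg$target_sum))
  say("retained %d genes, %d/%d cells", nrow(case$counts),
      ncol(case$counts), ncol(control$counts))

  say("observed runs (R = %d)", cfg$permutations)
  observed <- stage("permutations",
    run_permutations(case, control, cfg$genes_of_interest,
                     R = cfg$permutations, cfg = cfg$addstcn,
                     top_k = cfg$top_k, max_steps = cfg$max_steps,
                     seed = derive_seed(cfg$seed, 100)))
  say("background runs")
  background <- stage("background",
    background_run(case, control, cfg$genes_of_interest,
                   R = cfg$permutations, cfg = cfg$addstcn,
                   top_k = cfg$top_k, max_steps = cfg$max_steps,
                   seed = derive_seed(cfg$seed, 200)))
  model <- stage("significance",
                 fit_significance(background, cfg$alpha, family_wise = TRUE))
  say("minimum detections for significance: %d of %d",
      model$min_detections, model$R)
  grn_all <- stage("significance", significant_edges(observed, model))

  out <- cfg$out_dir
  write.table(observed, file.path(out, "raw_observed_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(background, file.path(out, "raw_background_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  frequency_histogram(observed, file.path(out, "frequency_histogram.tsv"),
                      file.path(out, "frequency_histogram.svg"))

  grns <- list()
  for (goi in cfg$genes_of_interest) {
    hit <- grepl(paste0("(^|,)", goi, "($|,)"), grn_all$edges$goi)
    gg <- causal_graph(grn_all$edges[hit, , drop = FALSE],
                       unique(c(goi, grn_all$edges$cause[hit],
                                grn_all$edges$target[hit])))
    class(gg) <- c("annotated_grn", class(gg))
    gg$goi <- goi
    grns[[goi]] <- gg
    write_graphml(gg, file.path(out, sprintf("grn_%s.graphml", goi)))
  }
  merged <- merge_grns(grns)
  write_graphml(merged, file.path(out, "grn_merged.graphml"))
  write_cytoscape_table(merged, file.path(out, "edges_cytoscape.tsv"))
  write_edge_table(merged, file.path(out, "edges_raw.tsv"))
  say("wrote %d significant edges to %s", nrow(merged$edges), out)
  invisible(list(grns = grns, merged = merged, observed = observed,
                 background = background, model = model))
}

#' Dropout-robustness protocol
#'
#' Runs the pipeline on the original data as a baseline, then for each
#' requested artificial dropout level injects zeros into the raw counts,
#' reruns, and reports the per-run percentage overlap of the detected edge
#' set with the baseline (`|intersection| / |baseline| * 100`), with the
#' median and minimum across runs per level.
#'
#' @param cfg a [run_config()].
#' @param dropout_levels added dropout, as increments of the matrix-wide
#'   zero fraction (e.g. `c(0.01, 0.02, 0.05)`).
#' @param n_runs independent injection runs per level.
#' @return data.frame with columns level, run, overlap_pct plus a summary
#'   attribute (median/min per level).
#' @export
run_robustness <- function(cfg, dropout_levels = c(0.01, 0.02, 0.05),
                           n_runs = 10) {
  stopifnot(inherits(cfg, "run_config"))
  base_case <- resolve_matrix(cfg$case, "case")
  base_control <- resolve_matrix(cfg$control, "control")
  base_cfg <- cfg
  base_cfg$case <- base_case; base_cfg$control <- base_control
  base_cfg$out_dir <- file.path(cfg$out_dir, "baseline")
  baseline <- run_full(base_cfg, quiet = TRUE)
  base_edges <- edge_keys(baseline$merged)
  rows <- list()
  for (lev in dropout_levels) {
    for (run in seq_len(n_runs)) {
      ov <- if (lev == 0) 100 else {
        sr <- derive_seed(cfg$seed, lev * 1e4 + run)
        z_case <- sum(base_case$counts == 0) / length(base_case$counts)
        z_ctrl <- sum(base_control$counts == 0) / length(base_control$counts)
        cc <- cfg
        cc$case <- inject_dropout(base_case, min(z_case + lev, 1),
                                  seed = derive_seed(sr, 1))
        cc$control <- inject_dropout(base_control, min(z_ctrl + lev, 1),
                                     seed = derive_seed(sr, 2))
        cc$out_dir <- file.path(cfg$out_dir,
                                sprintf("dropout_%g_run%d", lev, run))
        res <- run_full(cc, quiet = TRUE)
        overlap_pct(edge_keys(res$merged), base_edges)
      }
      rows[[length(rows) + 1]] <- data.frame(level = lev, run = run,
                                             overlap_pct = ov)
    }
  }
  df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(df, df$level), function(d)
    data.frame(level = d$level[1], median_overlap = median(d$overlap_pct),
               min_overlap = min(d$overlap_pct))))
  attr(df, "summary") <- summ
  df
}

edge_keys <- function(grn) {
  if (nrow(grn$edges) == 0) character(0)
  else paste(grn$edges$cause, grn$edges$target, grn$edges$sign, sep = "\r")
}

# |intersection| / |baseline| * 100; an empty baseline counts as full overlap
overlap_pct <- function(edges, baseline) {
  if (length(baseline) == 0) return(100)
  100 * length(intersect(edges, baseline)) / length(baseline)
}

#' Case/control flip concordance
#'
#' Reruns the pipeline with the two conditions swapped and reports the
#' Jaccard index of the signed edge sets (signs are invariant under the
#' swap because the co-differential series are jointly negated).
#'
#' @param cfg a [run_config()].
#' @return List with `jaccard`, `edges_original`, `edges_flipped`.
#' @export
run_flip_check <- function(cfg) {
  res1 <- run_full(cfg, quiet = TRUE)
  cfg2 <- cfg
  cfg2$case <- cfg$control; cfg2$control <- cfg$case
  cfg2$out_dir <- file.path(cfg$out_dir, "flipped")
  res2 <- run_full(cfg2, quiet = TRUE)
  k1 <- edge_keys(res1$merged); k2 <- edge_keys(res2$merged)
  u <- union(k1, k2)
  list(jaccard = if (length(u) == 0) 1
                 else length(intersect(k1, k2)) / length(u),
       edges_original = k1, edges_flipped = k2)
}
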