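#' Quality-control configuration
#'
#' Thresholds for cell- and gene-level quality filtering. The defaults are the
#' usual droplet scRNA-seq conventions and are deliberately permissive; all of
#' them are user-overridable and recorded in pipeline logs.
#'
#' @param min_genes_per_cell minimum number of expressed (nonzero) genes a
#'   cell must have.
#' @param min_counts_per_cell minimum total counts per cell.
#' @param max_mito_fraction maximum fraction of a cell's counts coming from
#'   mitochondrial genes (identified by `mito_prefix`).
#' @param min_cells_per_gene minimum number of cells a gene must be expressed
#'   in to be retained.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#'   (matched case-insensitively, e.g. "MT-" also catches "mt-").
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes_per_cell = 200, min_counts_per_cell = 500,
                      max_mito_fraction = 0.2, min_cells_per_gene = 3,
                      mito_prefix = "MT-") {
  stopifnot(min_genes_per_cell >= 0, min_counts_per_cell >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_cells_per_gene >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_counts_per_cell = min_counts_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix),
            class = "qc_config")
}

#' Filter low-quality cells and genes
#'
#' Cells with too few expressed genes, too few total counts, or an excessive
#' mitochondrial fraction are removed first; genes expressed in too few of the
#' surviving cells are removed second. The fixed order (cells, then genes)
#' makes the result reproducible.
#'
#' Gene filtering can lower a cell's expressed-gene count, so the cell/gene
#' passes are repeated until a fixed point is reached; every retained cell and
#' gene then satisfies its thresholds simultaneously and the operation is
#' idempotent.
#'
#' @param m raw-count `sctiger_matrix`.
#' @param cfg a [qc_config()].
#' @return The filtered `sctiger_matrix`.
#' @export
qc_filter <- function(m, cfg = qc_config()) {
  assert_matrix(m)
  x <- m$counts
  repeat {
    genes_per_cell <- colSums(x > 0)
    counts_per_cell <- colSums(x)
    mito <- grepl(paste0("^", cfg$mito_prefix), rownames(x), ignore.case = TRUE)
    mito_frac <- if (any(mito)) {
      colSums(x[mito, , drop = FALSE]) / pmax(counts_per_cell, 1)
    } else rep(0, ncol(x))

    keep_cell <- genes_per_cell >= cfg$min_genes_per_cell &
      counts_per_cell >= cfg$min_counts_per_cell &
      mito_frac <= cfg$max_mito_fraction
    if (!any(keep_cell)) {
      fail <- if (all(genes_per_cell < cfg$min_genes_per_cell)) "min_genes_per_cell"
        else if (all(counts_per_cell < cfg$min_counts_per_cell)) "min_counts_per_cell"
        else "max_mito_fraction"
      stopf("qc_filter removed every cell (threshold '%s' eliminates all cells)", fail)
    }
    x2 <- x[, keep_cell, drop = FALSE]
    keep_gene <- rowSums(x2 > 0) >= cfg$min_cells_per_gene
    x2 <- x2[keep_gene, , drop = FALSE]
    if (identical(dim(x2), dim(x))) break
    x <- x2
  }
  expression_matrix(x2, m$condition)
}

#' Depth-normalize and log-transform
#'
#' Scales each cell's counts to a common total (`target_sum`), then applies
#' `log(1 + x)`.
#'
#' @param m QC-filtered raw-count `sctiger_matrix`.
#' @param target_sum per-cell total after scaling (default `1e4`).
#' @return A normalized `sctiger_matrix`.
#' @export
normalize_counts <- function(m, target_sum = 1e4) {
  assert_matrix(m)
  stopifnot(target_sum > 0)
  totals <- colSums(m$counts)
  if (any(totals == 0))
    stopf("cell(s) with zero total counts present (%s); run qc_filter first",
          paste(head(cell_ids(m)[totals == 0], 3), collapse = ", "))
  x <- sweep(m$counts, 2, totals / target_sum, "/")
  expression_matrix(log1p(x), m$condition, normalized = TRUE)
}

# k-nearest-neighbour graph on top principal components; returns an
# undirected igraph with distance-derived edge weights plus the PC scores
knn_graph <- function(m, k_neighbors = 15, n_pcs = 20) {
  x <- t(m$counts)                       # cells x genes
  n <- nrow(x)
  k <- min(k_neighbors, n - 1)
  if (k < 1) stopf("need at least 2 cells to build a neighbor graph")
  n_pcs <- min(n_pcs, n - 1, ncol(x))
  pr <- tryCatch(prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs),
                 error = function(e) NULL)
  if (is.null(pr)) {
    pcs <- x
    pc1_anchor <- rowSums(x)
  } else {
    pcs <- pr$x
    # PC1 score with its sign anchored in gene space (sum of loadings
    # positive), so trajectory orientation is comparable across datasets
    # sharing a gene universe
    flip <- if (sum(pr$rotation[, 1]) < 0) -1 else 1
    pc1_anchor <- flip * pcs[, 1]
  }
  d <- as.matrix(dist(pcs))
  edges <- matrix(0L, nrow = 0, ncol = 2)
  el <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    el[[i]] <- cbind(i, nb)
  }
  edges <- do.call(rbind, el)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  ends <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- 1 / (1 + d[cbind(ends[, 1], ends[, 2])])
  igraph::E(g)$distance <- d[cbind(ends[, 1], ends[, 2])]
  list(graph = g, pcs = pcs, dist = d, pc1_anchor = pc1_anchor)
}

#' Cluster cells with the Leiden algorithm
#'
#' Builds a k-nearest-neighbour graph on the top principal components and
#' partitions it with Leiden community detection.
#'
#' @param m normalized `sctiger_matrix` with at least 2 cells.
#' @param resolution Leiden resolution parameter.
#' @param k_neighbors neighbours per cell in the kNN graph.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return Integer vector of cluster ids (1-based), named by cell id.
#' @export
cluster_cells <- function(m, resolution = 1, k_neighbors = 15, seed = 0) {
  assert_matrix(m)
  if (ncol(m$counts) < 2) stopf("need at least 2 cells to cluster")
  if (ncol(m$counts) <= k_neighbors)
    k_neighbors <- ncol(m$counts) - 1
  kg <- knn_graph(m, k_neighbors)
  cl <- with_seed(seed, igraph::cluster_leiden(
    kg$graph, objective_function = "modularity",
    resolution = resolution, n_iterations = 5
  ))
  labels <- as.integer(igraph::membership(cl))
  names(labels) <- cell_ids(m)
  labels
}

#' Subsample cells without replacement
#'
#' Draws `n_target` cells uniformly at random. Sampling is performed over the
#' lexicographically sorted cell identifiers, so the selected cell *set* is
#' invariant to the column order of the input (a requirement for the
#' column-shuffle reproducibility check).
#'
#' @param m `sctiger_matrix`.
#' @param n_target number of cells to keep (`<=` current cell count).
#' @param seed integer seed.
#' @return `sctiger_matrix` with `n_target` columns, in original column order.
#' @export
subsample_cells <- function(m, n_target, seed = 0) {
  assert_matrix(m)
  n <- ncol(m$counts)
  if (n_target > n)
    stopf("n_target (%d) exceeds number of cells (%d)", n_target, n)
  if (n_target == n) return(m)
  ids_sorted <- sort(cell_ids(m))
  chosen <- with_seed(seed, sample(ids_sorted, n_target))
  keep <- cell_ids(m) %in% chosen
  expression_matrix(m$counts[, keep, drop = FALSE], m$condition,
                    normalized = m$normalized)
}
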