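#' Order cells along a pseudotime trajectory
#'
#' Builds a k-nearest-neighbour graph on the top principal components,
#' computes a diffusion map of its transition operator, derives a
#' partition-based abstraction over the supplied clusters (inter-cluster
#' connectivity graph), and assigns each cell a diffusion pseudotime relative
#' to a root cell. Cells are returned sorted by pseudotime; ties are broken by
#' original input index.
#'
#' If the neighbour graph is disconnected, each component is ordered
#' separately and the per-component orderings are concatenated by decreasing
#' component size (with a warning).
#'
#' @param m normalized `sctiger_matrix`.
#' @param clusters optional integer cluster labels per cell (as from
#'   [cluster_cells()]); computed on the fly when missing.
#' @param root optional cell id to use as the trajectory root. By default the
#'   root is the cell with the most extreme first diffusion component within
#'   the largest cluster.
#' @param k_neighbors neighbours per cell for the graph.
#' @param n_comps number of diffusion components.
#' @param seed integer seed (used only if `clusters` must be computed).
#' @return A `pseudotime_ordering`: list with `order` (integer permutation of
#'   cell indices), `pseudotime` (named per-cell values, input order),
#'   `root` (cell id) and `cluster_graph` (igraph over clusters).
#' @export
order_cells <- function(m, clusters = NULL, root = NULL, k_neighbors = 15,
                        n_comps = 10, seed = 0) {
  assert_matrix(m)
  n <- ncol(m$counts)
  if (n < 2) stopf("need at least 2 cells to order")
  k_neighbors <- min(k_neighbors, n - 1)
  if (is.null(clusters))
    clusters <- cluster_cells(m, k_neighbors = k_neighbors, seed = seed)
  if (length(clusters) != n) stopf("one cluster label per cell required")

  kg <- knn_graph(m, k_neighbors)
  comp <- igraph::components(kg$graph)
  ids <- cell_ids(m)

  cluster_graph <- abstraction_graph(kg$graph, clusters)

  pt <- rep(NA_real_, n)
  comp_order <- order(-comp$csize)       # largest component first
  offset <- 0
  root_used <- NULL
  order_all <- integer(0)
  if (comp$no > 1)
    warnf("neighbor graph has %d components; ordering each separately", comp$no)
  for (ci in comp_order) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) {
      pt[idx] <- offset
      order_all <- c(order_all, idx)
      offset <- offset + 1
      next
    }
    dsub <- kg$dist[idx, idx, drop = FALSE]
    if (max(dsub) < 1e-10) {      # degenerate: identical cells, pure ties
      pt[idx] <- offset
      order_all <- c(order_all, idx)
      offset <- offset + 1
      next
    }
    dmap <- diffusion_map(dsub, n_comps = min(n_comps, length(idx) - 1))
    r <- pick_root(dmap, clusters[idx], ids[idx], root)
    dpt <- diffusion_pseudotime(dmap, r)
    if (is.null(root) && length(idx) > 2) {
      # two-sweep endpoint refinement: the initial (cluster-based) root may
      # sit mid-trajectory; the cell farthest from it is an endpoint
      r <- which.max(dpt)
      dpt <- diffusion_pseudotime(dmap, r)
      # orient the trajectory consistently across datasets sharing a gene
      # universe: pseudotime increases along the gene-space-anchored PC1.
      # If this endpoint is the wrong end, re-root at the other end (keeps
      # the root-cell-has-minimum-pseudotime invariant).
      if (isTRUE(cor(dpt, kg$pc1_anchor[idx]) < 0)) {
        r <- which.max(dpt)
        dpt <- diffusion_pseudotime(dmap, r)
      }
    }
    pt[idx] <- offset + dpt
    ord_local <- idx[order(dpt, seq_along(idx))]  # ties by input index
    order_all <- c(order_all, ord_local)
    if (is.null(root_used)) root_used <- ids[idx][r]
    offset <- offset + max(dpt) + 1
  }
  names(pt) <- ids
  structure(list(order = order_all, pseudotime = pt, root = root_used,
                 cluster_graph = cluster_graph),
            class = "pseudotime_ordering")
}

# PAGA-style cluster abstraction: nodes are clusters, edge weights the
# observed inter-cluster kNN edge counts normalized by the expected count
# under random wiring
abstraction_graph <- function(g, clusters) {
  el <- igraph::as_edgelist(g, names = FALSE)
  cl_sizes <- table(factor(clusters))
  ncl <- length(cl_sizes)
  w <- matrix(0, ncl, ncl, dimnames = list(names(cl_sizes), names(cl_sizes)))
  c1 <- as.character(clusters[el[, 1]]); c2 <- as.character(clusters[el[, 2]])
  for (e in seq_len(nrow(el))) {
    w[c1[e], c2[e]] <- w[c1[e], c2[e]] + 1
    w[c2[e], c1[e]] <- w[c2[e], c1[e]] + 1
  }
  sizes <- as.numeric(cl_sizes)
  expected <- outer(sizes, sizes) * (2 * nrow(el)) / (sum(sizes)^2)
  conn <- w / pmax(expected, .Machine$double.eps)
  diag(conn) <- 0
  igraph::graph_from_adjacency_matrix(conn, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# symmetric diffusion map with adaptive Gaussian kernel widths
diffusion_map <- function(d, n_comps = 10) {
  n <- nrow(d)
  kth <- apply(d, 1, function(r) sort(r)[min(n, 8)])   # local scale
  sig <- outer(kth, kth, function(a, b) (a + b) / 2)
  sig[sig == 0] <- min(sig[sig > 0], 1)
  w <- exp(-d^2 / (2 * sig^2))
  diag(w) <- 0
  deg <- rowSums(w)
  deg[deg == 0] <- .Machine$double.eps
  s <- 1 / sqrt(deg)
  ms <- sweep(sweep(w, 1, s, "*"), 2, s, "*")   # D^-1/2 W D^-1/2, symmetric
  eig <- eigen((ms + t(ms)) / 2, symmetric = TRUE)
  keep <- 2:(min(n_comps + 1, n))               # drop trivial first component
  lambda <- eig$values[keep]
  psi <- sweep(eig$vectors[, keep, drop = FALSE], 1, s, "*")
  # canonical sign: largest-|entry| coordinate positive (makes the map
  # invariant to input column permutations)
  for (q in seq_len(ncol(psi))) {
    iq <- which.max(abs(psi[, q]))
    if (psi[iq, q] < 0) psi[, q] <- -psi[, q]
  }
  list(lambda = lambda, psi = psi)
}

# diffusion pseudotime: distance from the root in eigencoordinates scaled by
# lambda / (1 - lambda)
diffusion_pseudotime <- function(dmap, root) {
  lam <- pmin(dmap$lambda, 1 - 1e-10)
  scale <- lam / (1 - lam)
  z <- sweep(dmap$psi, 2, scale, "*")
  dpt <- sqrt(rowSums((z - matrix(z[root, ], nrow(z), ncol(z),
                                  byrow = TRUE))^2))
  dpt
}

pick_root <- function(dmap, clusters, ids, root) {
  if (!is.null(root)) {
    r <- match(root, ids)
    if (is.na(r)) return(which.max(abs(dmap$psi[, 1])))  # root in other component
    return(r)
  }
  main <- names(which.max(table(factor(clusters))))
  in_main <- which(as.character(clusters) == main)
  dc1 <- abs(dmap$psi[, 1])
  # extreme first diffusion component within the largest cluster;
  # deterministic tie-break by cell id
  cand <- in_main[order(-dc1[in_main], ids[in_main])]
  cand[1]
}

#' Apply a pseudotime ordering to an expression matrix
#'
#' @param m `sctiger_matrix` whose cells are covered by `ord`.
#' @param ord a `pseudotime_ordering` from [order_cells()].
#' @return The matrix with columns permuted into pseudotime order.
#' @export
apply_ordering <- function(m, ord) {
  assert_matrix(m)
  if (!inherits(ord, "pseudotime_ordering"))
    stopf("'ord' must come from order_cells()")
  if (length(ord$order) != ncol(m$counts) ||
      !setequal(names(ord$pseudotime), cell_ids(m)))
    stopf("ordering does not cover exactly the cells of 'm'")
  # positional semantics: column p of the result is input column order[p]
  expression_matrix(m$counts[, ord$order, drop = FALSE], m$condition,
                    normalized = m$normalized)
}

#' Export a per-cell pseudotime table
#'
#' @param ord a `pseudotime_ordering`.
#' @param clusters optional cluster labels to include.
#' @param path optional TSV path; when given the table is also written there.
#' @return data.frame with cell_id, cluster, pseudotime (in pseudotime order).
#' @export
pseudotime_table <- function(ord, clusters = NULL, path = NULL) {
  ids <- names(ord$pseudotime)[ord$order]
  df <- data.frame(cell_id = ids,
                   cluster = if (is.null(clusters)) NA_integer_
                             else as.integer(clusters[ids]),
                   pseudotime = unname(ord$pseudotime[ids]))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
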