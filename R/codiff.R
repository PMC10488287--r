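#' Dropout fraction of a gene across a case/control pair
#'
#' Fraction of zero entries for `gene` pooled over the cells of both
#' matrices. Computed on raw counts: zeros are a property of transcript
#' capture, not of scaling.
#'
#' @param m_case,m_control `sctiger_matrix` objects sharing the gene.
#' @param gene gene identifier.
#' @return Fraction in `[0, 1]`.
#' @export
dropout_fraction <- function(m_case, m_control, gene) {
  assert_matrix(m_case, "m_case"); assert_matrix(m_control, "m_control")
  if (!(gene %in% gene_ids(m_case)) || !(gene %in% gene_ids(m_control)))
    stopf("gene '%s' absent from one of the matrices", gene)
  z <- sum(m_case$counts[gene, ] == 0) + sum(m_control$counts[gene, ] == 0)
  z / (ncol(m_case$counts) + ncol(m_control$counts))
}

#' Filter genes by pooled dropout fraction
#'
#' Retains genes whose pooled dropout fraction (see [dropout_fraction()]) is
#' at most `max_dropout`; both matrices keep the same genes in the same
#' order. If a gene of interest would be removed, an explicit error names it.
#'
#' @param m_case,m_control matrices over a shared gene universe.
#' @param max_dropout maximum tolerated dropout fraction (default 0.9).
#' @param genes_of_interest genes that must survive the filter.
#' @return List with elements `case` and `control`.
#' @export
filter_genes_by_dropout <- function(m_case, m_control, max_dropout = 0.9,
                                    genes_of_interest = character(0)) {
  assert_matrix(m_case, "m_case"); assert_matrix(m_control, "m_control")
  shared <- intersect(gene_ids(m_case), gene_ids(m_control))
  n_tot <- ncol(m_case$counts) + ncol(m_control$counts)
  zc <- rowSums(m_case$counts[shared, , drop = FALSE] == 0)
  zk <- rowSums(m_control$counts[shared, , drop = FALSE] == 0)
  frac <- (zc + zk) / n_tot
  keep <- shared[frac <= max_dropout]
  lost <- setdiff(genes_of_interest, keep)
  if (length(lost) > 0) {
    g <- lost[1]
    stopf("gene of interest '%s' removed by the dropout filter (dropout fraction %.3f > %.3f)",
          g, frac[match(g, shared)], max_dropout)
  }
  keep_case <- gene_ids(m_case)[gene_ids(m_case) %in% keep]
  list(case = expression_matrix(m_case$counts[keep_case, , drop = FALSE],
                                m_case$condition, m_case$normalized),
       control = expression_matrix(m_control$counts[keep_case, , drop = FALSE],
                                   m_control$condition, m_control$normalized))
}

#' Co-differential expression matrix
#'
#' Position-wise case-minus-control difference of two pseudotime-ordered,
#' cell-count-matched expression matrices: `X[i, t] = case[i, t] -
#' control[i, t]`. Each row is one gene's co-differential series, the time
#' series consumed by the causal discovery engine.
#'
#' @param case_ordered,control_ordered ordered matrices with identical gene
#'   sets and equal cell counts.
#' @return A `codiff_matrix`: list with `X` (genes x positions) and
#'   `gene_ids`.
#' @export
compute_codiff <- function(case_ordered, control_ordered) {
  assert_matrix(case_ordered, "case_ordered")
  assert_matrix(control_ordered, "control_ordered")
  if (ncol(case_ordered$counts) != ncol(control_ordered$counts))
    stopf("cell counts differ (%d vs %d); subsample the larger condition first (subsample_cells)",
          ncol(case_ordered$counts), ncol(control_ordered$counts))
  if (!identical(sort(gene_ids(case_ordered)), sort(gene_ids(control_ordered))))
    stopf("case and control gene sets differ; harmonize them first")
  ctrl <- control_ordered$counts[gene_ids(case_ordered), , drop = FALSE]
  X <- case_ordered$counts - ctrl
  colnames(X) <- NULL
  codiff_matrix(X)
}

#' @rdname compute_codiff
#' @param X numeric genes-by-positions matrix of differential series.
#' @export
codiff_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  if (anyDuplicated(rownames(X))) stopf("gene ids must be unique")
  structure(list(X = X, gene_ids = rownames(X)), class = "codiff_matrix")
}

#' @export
print.codiff_matrix <- function(x, ...) {
  cat(sprintf("<codiff_matrix> %d genes x %d pseudotime positions\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Screen candidate regulators for a gene of interest
#'
#' Ranks all other finite-variance genes by absolute Pearson correlation
#' between their co-differential series and that of the gene of interest, and
#' returns the top `k`. Absolute correlation is used so that repressive
#' (anti-correlated) regulators survive screening. Ties are broken by gene id
#' order.
#'
#' @param X a `codiff_matrix`.
#' @param goi gene of interest (must have nonzero variance).
#' @param k number of candidates to return.
#' @return A `candidate_set`: list with `goi` and a data.frame `candidates`
#'   (gene, r) ordered by decreasing `|r|`.
#' @export
select_candidates <- function(X, goi, k = 100) {
  stopifnot(inherits(X, "codiff_matrix"))
  if (!(goi %in% X$gene_ids)) stopf("gene '%s' not present", goi)
  y <- X$X[goi, ]
  if (sd(y) == 0)
    stopf("gene '%s' has no co-differential signal (zero variance)", goi)
  others <- setdiff(X$gene_ids, goi)
  v <- apply(X$X[others, , drop = FALSE], 1, sd)
  others <- others[v > 0]
  if (length(others) == 0)
    return(structure(list(goi = goi,
                          candidates = data.frame(gene = character(0),
                                                  r = numeric(0))),
                     class = "candidate_set"))
  r <- as.numeric(cor(t(X$X[others, , drop = FALSE]), y))
  ord <- order(-abs(r), others)
  sel <- head(ord, k)
  structure(list(goi = goi,
                 candidates = data.frame(gene = others[sel], r = r[sel],
                                         stringsAsFactors = FALSE)),
            class = "candidate_set")
}

#' Sign of regulation between two co-differential series
#'
#' Positive regulation corresponds to a positive Pearson correlation between
#' the two differential expression series, negative regulation to a negative
#' correlation. An exactly-zero correlation is classified as positive by
#' convention (with a message).
#'
#' @param x_i,x_j numeric series of equal length and finite variance.
#' @return `"positive"` or `"negative"`.
#' @export
regulation_sign <- function(x_i, x_j) {
  if (sd(x_i) == 0 || sd(x_j) == 0)
    stopf("regulation_sign requires both series to have nonzero variance")
  r <- cor(x_i, x_j)
  if (r == 0) message("correlation exactly zero; classified as positive by convention")
  if (r >= 0) "positive" else "negative"
}
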