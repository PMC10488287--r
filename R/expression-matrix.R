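#' Expression matrix container
#'
#' A light container for a genes-by-cells expression matrix belonging to one
#' experimental condition (e.g. "case" or "control"). Gene identifiers are the
#' row names and cell barcodes the column names of the dense numeric matrix.
#'
#' @param counts numeric matrix, genes in rows, cells in columns; no negative
#'   entries.
#' @param condition label for the condition this matrix belongs to.
#' @param normalized logical; whether the matrix has been depth-normalized and
#'   log-transformed (see [normalize_counts()]).
#'
#' @return An object of class `sctiger_matrix`.
#' @export
expression_matrix <- function(counts, condition = "unspecified",
                              normalized = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)))
    stopf("expression matrix contains non-finite entries")
  if (any(counts < 0))
    stopf("expression matrix contains negative entries")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    rownames(counts) <- dedup_ids(rownames(counts))
  if (anyDuplicated(colnames(counts)))
    stopf("cell identifiers must be unique")
  structure(
    list(counts = counts, condition = as.character(condition),
         normalized = isTRUE(normalized)),
    class = "sctiger_matrix"
  )
}

# duplicate gene symbols get a numeric suffix (second copy of G -> "G.1"),
# preserving row identity for gene-of-interest lookup
dedup_ids <- function(ids) make.unique(ids, sep = ".")

#' @export
print.sctiger_matrix <- function(x, ...) {
  cat(sprintf("<sctiger_matrix> %d genes x %d cells, condition '%s'%s\n",
              nrow(x$counts), ncol(x$counts), x$condition,
              if (x$normalized) " (normalized)" else " (raw counts)"))
  invisible(x)
}

#' @export
dim.sctiger_matrix <- function(x) dim(x$counts)

gene_ids <- function(m) rownames(m$counts)
cell_ids <- function(m) colnames(m$counts)

assert_matrix <- function(m, arg = "m") {
  if (!inherits(m, "sctiger_matrix"))
    stopf("'%s' must be an sctiger_matrix (see expression_matrix())", arg)
  invisible(m)
}

#' Load an expression matrix from disk
#'
#' Reads either a 10x-style MTX triplet directory (`matrix.mtx` plus
#' `genes.tsv`/`features.tsv` and `barcodes.tsv`) or a dense CSV/TSV with gene
#' identifiers in the first column and a header row of cell barcodes.
#'
#' @param path path to the file (CSV/TSV or `matrix.mtx`) or to an MTX
#'   directory.
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`.
#' @param condition condition label stored on the returned object.
#' @return An `sctiger_matrix` of raw counts.
#' @export
load_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        condition = "unspecified") {
  format <- match.arg(format)
  if (!file.exists(path))
    stopf("input path does not exist: %s", path)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx"
      else if (grepl("\\.csv$", path)) "csv" else "tsv"
  }
  if (format == "mtx") load_mtx(path, condition)
  else load_dense(path, sep = if (format == "csv") "," else "\t", condition)
}

load_mtx <- function(path, condition) {
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- if (dir.exists(path)) file.path(dir, "matrix.mtx") else path
  if (!file.exists(mtx)) stopf("missing MTX file: %s", mtx)
  genes_f <- file.path(dir, c("genes.tsv", "features.tsv"))
  genes_f <- genes_f[file.exists(genes_f)][1]
  barcodes_f <- file.path(dir, "barcodes.tsv")
  if (is.na(genes_f) || !file.exists(barcodes_f))
    stopf("MTX sidecar files (genes.tsv/features.tsv, barcodes.tsv) not found in %s", dir)
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- read.delim(genes_f, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- read.delim(barcodes_f, header = FALSE, stringsAsFactors = FALSE)[[1]]
  gene_names <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  if (length(gene_names) != nrow(m))
    stopf("genes sidecar has %d entries but matrix has %d rows",
          length(gene_names), nrow(m))
  if (length(barcodes) != ncol(m))
    stopf("barcodes sidecar has %d entries but matrix has %d columns",
          length(barcodes), ncol(m))
  rownames(m) <- dedup_ids(gene_names)
  colnames(m) <- barcodes
  expression_matrix(m, condition)
}

load_dense <- function(path, sep, condition) {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dedup_ids(as.character(df[[1]]))
  expression_matrix(m, condition)
}
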