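# small programmatic fixtures shared across test files

# deterministic toy count matrix; optionally with mitochondrial genes
toy_counts <- function(n_genes = 6, n_cells = 8, seed = 42, mito = 0) {
  m <- sctiger:::with_seed(seed,
    matrix(rpois(n_genes * n_cells, lambda = 5), n_genes, n_cells))
  genes <- sprintf("G%02d", seq_len(n_genes))
  if (mito > 0) genes[seq_len(mito)] <- paste0("MT-", seq_len(mito))
  rownames(m) <- genes
  colnames(m) <- sprintf("c%02d", seq_len(n_cells))
  m
}

# normalized matrix along a clean monotone 1-D gradient (latent order =
# column order); generous signal so trajectory recovery is near-exact
gradient_matrix <- function(n_cells = 90, n_genes = 25, seed = 7,
                            noise_sd = 0.3) {
  sctiger:::with_seed(seed, {
    s <- sort(runif(n_cells))
    mu <- sapply(seq_len(n_genes), function(k)
      runif(1, 6, 10) + sample(c(-1, 1), 1) * runif(1, 2.5, 5) * s +
        runif(1, -1, 1) * s^2)
    x <- t(mu) + matrix(rnorm(n_cells * n_genes, sd = noise_sd),
                        n_genes, n_cells)
    x <- pmax(x, 0)
    rownames(x) <- sprintf("g%02d", seq_len(n_genes))
    colnames(x) <- sprintf("cell%03d", seq_len(n_cells))
    list(m = expression_matrix(x, normalized = TRUE), s = s)
  })
}

# write a dense CSV expression file; returns the path
write_csv_matrix <- function(m, path = tempfile(fileext = ".csv")) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# tiny fast causal-engine configuration for tests
fast_cfg <- function(epochs = 300, seed = 1, ...) {
  addstcn_config(epochs = epochs, seed = seed, ...)
}

edge_key <- function(edges) paste(edges$cause, edges$target)
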