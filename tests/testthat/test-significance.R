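# compact paired dataset with one planted module, used across these tests
sig_fixture <- function(seed = 4) {
  sim <- generate_case_control(n_genes = 30, n_cells_case = 70,
                               n_cells_control = 90, n_markers = 14,
                               seed = seed, burst_weight = 0.4)
  list(case = normalize_counts(sim$case),
       control = normalize_counts(sim$control), truth = sim$truth)
}

test_that("run_permutations is deterministic and counts per signed edge", {
  fx <- sig_fixture()
  cfg <- fast_cfg(epochs = 60, seed = 1)
  f1 <- run_permutations(fx$case, fx$control, "G001", R = 2, cfg = cfg,
                         top_k = 6, seed = 5)
  f2 <- run_permutations(fx$case, fx$control, "G001", R = 2, cfg = cfg,
                         top_k = 6, seed = 5)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(attr(f1, "R"), 2)
  expect_false(attr(f1, "is_background"))
  if (nrow(f1) > 0) expect_true(all(f1$count >= 1 & f1$count <= 2))
  expect_error(run_permutations(fx$case, fx$control, "G001", R = 0), "R must")
})

test_that("identical per-run inputs give counts that are 0 or R", {
  # two repetitions over identical data with no subsampling variation on
  # either side (equal cell counts) and the same engine seed reproduce the
  # same edge set in every run
  fx <- sig_fixture()
  eq_case <- subsample_cells(fx$case, 60, seed = 1)
  eq_ctrl <- subsample_cells(fx$control, 60, seed = 1)
  cfg <- fast_cfg(epochs = 60, seed = 1)
  r1 <- sctiger:::single_run(eq_case, eq_ctrl, "G001", cfg, 6, NULL, seed = 9)
  r2 <- sctiger:::single_run(eq_case, eq_ctrl, "G001", cfg, 6, NULL, seed = 9)
  expect_identical(r1, r2)
})

test_that("gene-wise shuffling preserves per-gene marginals", {
  fx <- sig_fixture()
  sh <- sctiger:::shuffle_genewise(fx$case, seed = 3)
  for (g in rownames(fx$case$counts)[1:5])
    expect_equal(sort(sh$counts[g, ]), sort(fx$case$counts[g, ]),
                 ignore_attr = TRUE)
  # same seed, same shuffle
  sh2 <- sctiger:::shuffle_genewise(fx$case, seed = 3)
  expect_identical(sh$counts, sh2$counts)
})

test_that("negative binomial threshold matches a brute-force tail oracle", {
  # background counts with mean 2, variance 4 over a universe of 50
  counts <- rep(c(0, 1, 2, 3, 4), each = 10)
  counts <- counts + (2 - mean(counts))          # center on mean 2 exactly
  # construct an edge_freq_table carrying those counts
  tab <- data.frame(cause = paste0("c", seq_along(counts)),
                    target = "t", sign = "positive",
                    count = counts, modal_delay = 0L, goi = "t")
  ft <- structure(tab, class = c("edge_freq_table", "data.frame"),
                  R = 100L, is_background = TRUE,
                  universe_size = length(counts), targets = "t")
  alpha <- 0.05
  model <- fit_significance(ft, alpha = alpha)
  mu <- mean(counts); v <- var(counts)
  size <- mu^2 / (v - mu)
  # independent oracle: explicit tail summation over the NB pmf;
  # smallest m >= 1 with tail <= alpha (m = 0 has tail 1)
  tail_at <- function(m) 1 - sum(dnbinom(0:(m - 1), size = size, mu = mu))
  m_oracle <- 1
  while (tail_at(m_oracle) > alpha) m_oracle <- m_oracle + 1
  expect_equal(model$min_detections, m_oracle)
  expect_equal(model$family, "nbinom")
  # tail function agrees with the oracle
  for (m in 1:8) expect_equal(model$tail(m), tail_at(m), tolerance = 1e-10)
})

test_that("degenerate and boundary significance models", {
  empty <- structure(
    data.frame(cause = character(0), target = character(0),
               sign = character(0), count = integer(0),
               modal_delay = integer(0), goi = character(0)),
    class = c("edge_freq_table", "data.frame"),
    R = 10L, is_background = TRUE, universe_size = 20L, targets = "g")
  # all-zero background: any recurrent detection is significant
  m0 <- fit_significance(empty, 0.05)
  expect_equal(m0$min_detections, 1)
  # alpha = 1 lets everything through
  m1 <- fit_significance(empty, 1)
  expect_equal(m1$min_detections, 0)
  # variance <= mean falls back to Poisson
  tabp <- structure(
    data.frame(cause = paste0("c", 1:20), target = "t", sign = "positive",
               count = rep(1, 20), modal_delay = 0L, goi = "t"),
    class = c("edge_freq_table", "data.frame"),
    R = 10L, is_background = TRUE, universe_size = 20L, targets = "t")
  mp <- fit_significance(tabp, 0.05)
  expect_equal(mp$family, "poisson")
})

test_that("min_detections is non-increasing in alpha and family_wise is stricter", {
  counts <- c(rep(0, 40), rep(1, 6), rep(2, 3), 4)
  tab <- structure(
    data.frame(cause = paste0("c", seq_along(counts)), target = "t",
               sign = "positive", count = counts, modal_delay = 0L, goi = "t"),
    class = c("edge_freq_table", "data.frame"),
    R = 20L, is_background = TRUE, universe_size = length(counts),
    targets = "t")
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  md <- vapply(alphas, function(a) fit_significance(tab, a)$min_detections, 0L)
  expect_true(all(diff(md) <= 0))
  expect_gte(fit_significance(tab, 0.05, family_wise = TRUE)$min_detections,
             fit_significance(tab, 0.05)$min_detections)
})

test_that("significant_edges thresholds counts and resolves sign conflicts", {
  obs <- structure(
    data.frame(cause = c("a", "a", "b", "c", "c"),
               target = c("x", "y", "x", "z", "z"),
               sign = c("positive", "positive", "negative",
                        "positive", "negative"),
               count = c(10, 5, 6, 7, 3), modal_delay = c(1L, 0L, 2L, 1L, 1L),
               goi = "a"),
    class = c("edge_freq_table", "data.frame"),
    R = 10L, is_background = FALSE, universe_size = 40L, targets = "a")
  model <- structure(list(family = "degenerate", mean = 0,
                          dispersion = NA_real_, alpha = 0.05,
                          family_wise = FALSE, min_detections = 6L, R = 10L,
                          tail = function(m) ifelse(m <= 0, 1, 0),
                          universe_size = 40L),
                     class = "significance_model")
  g <- significant_edges(obs, model)
  k <- edge_key(g$edges)
  expect_true("a x" %in% k)      # clear pass
  expect_false("a y" %in% k)     # count below threshold
  expect_true("b x" %in% k)      # boundary: count == min_detections passes
  # conflicting signs: majority kept
  expect_equal(g$edges$sign[k == "c z"], "positive")
  # annotations present
  expect_true(all(c("count", "frequency", "p_tail") %in% names(g$edges)))
  # exact sign tie is dropped with a message
  obs2 <- obs; obs2$count <- c(10, 5, 6, 7, 7)
  expect_message(g2 <- significant_edges(obs2, model), "tie")
  expect_false(any(edge_key(g2$edges) == "c z"))
  # mismatched R errors
  model_bad <- model; model_bad$R <- 99L
  expect_error(significant_edges(obs, model_bad), "R=")
})

test_that("frequency_histogram tabulates counts and writes TSV", {
  obs <- structure(
    data.frame(cause = c("a", "b", "c"), target = c("x", "y", "z"),
               sign = "positive", count = c(2, 2, 5), modal_delay = 0L,
               goi = "a"),
    class = c("edge_freq_table", "data.frame"),
    R = 5L, is_background = FALSE, universe_size = 10L, targets = "a")
  path <- tempfile(fileext = ".tsv")
  df <- frequency_histogram(obs, path_tsv = path)
  expect_equal(df$n_edges[df$count == 2], 2)
  expect_equal(df$n_edges[df$count == 5], 1)
  expect_equal(sum(df$n_edges), 3)
  expect_true(file.exists(path))
})
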