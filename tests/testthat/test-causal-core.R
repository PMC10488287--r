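# helper: evaluate predictions of a network with given parameters
predict_net <- function(X, j, par, K, c, L, softmax = FALSE) {
  sctiger:::.addstcn_loss_grad(X, j, par, K, c, L, want_grad = FALSE,
                               att_softmax = softmax)$yhat
}

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  N <- 3; Tn <- 12
  X <- matrix(rnorm(N * Tn), N, Tn)
  cfg <- addstcn_config(kernel_size = 3, dilation_coef = 2, hidden_layers = 2)
  for (softmax in c(FALSE, TRUE)) {
    par <- sctiger:::init_params(N, cfg, 5) +
      rnorm(sctiger:::n_params(N, cfg), sd = 0.05)
    lg <- sctiger:::.addstcn_loss_grad(X, 2, par, 3, 2, 2, TRUE, softmax)
    eps <- 1e-6
    num <- vapply(seq_along(par), function(p) {
      pp <- par; pp[p] <- pp[p] + eps
      pm <- par; pm[p] <- pm[p] - eps
      (sctiger:::.addstcn_loss_grad(X, 2, pp, 3, 2, 2, FALSE, softmax)$loss -
       sctiger:::.addstcn_loss_grad(X, 2, pm, 3, 2, 2, FALSE, softmax)$loss) /
        (2 * eps)
    }, 0)
    expect_lt(max(abs(num - lg$grad)), 1e-6)
  }
})

test_that("receptive field matches 1 + (K-1) * sum(c^l) and the impulse oracle", {
  expect_equal(receptive_field(addstcn_config()), 64L)
  expect_equal(receptive_field(addstcn_config(kernel_size = 2, dilation_coef = 1,
                                              hidden_layers = 1)), 3L)
  # impulse oracle: last input position (in an exogenous channel) that can
  # affect the output at position t
  probe_rf <- function(K, c, L) {
    N <- 2; Tn <- 100
    cfg <- addstcn_config(kernel_size = K, dilation_coef = c, hidden_layers = L)
    par <- abs(sctiger:::init_params(N, cfg, 1)) + 0.5  # all-positive weights
    t_out <- 90
    base <- predict_net(matrix(0, N, Tn), 2, par, K, c, L)
    affected <- vapply(1:Tn, function(t_in) {
      X <- matrix(0, N, Tn); X[1, t_in] <- 1
      abs(predict_net(X, 2, par, K, c, L)[t_out] - base[t_out]) > 1e-12
    }, TRUE)
    t_out - min(which(affected)) + 1
  }
  expect_equal(probe_rf(4, 4, 2), 64)
  expect_equal(probe_rf(2, 1, 1), 3)
})

test_that("causality: outputs at t never depend on inputs after t", {
  set.seed(9)
  N <- 3; Tn <- 40
  X <- matrix(rnorm(N * Tn), N, Tn)
  cfg <- addstcn_config(kernel_size = 4, dilation_coef = 2, hidden_layers = 2)
  par <- rnorm(sctiger:::n_params(N, cfg), sd = 0.3)
  y0 <- predict_net(X, 2, par, 4, 2, 2)
  t_cut <- 25
  Xp <- X
  Xp[, (t_cut + 1):Tn] <- Xp[, (t_cut + 1):Tn] + 100  # perturb the future
  y1 <- predict_net(Xp, 2, par, 4, 2, 2)
  expect_equal(y0[1:t_cut], y1[1:t_cut], tolerance = 1e-10)
  # autoregressive channel is additionally shifted: perturbing the target
  # channel at t does not change the output at t
  Xs <- X; Xs[2, t_cut] <- Xs[2, t_cut] + 100
  y2 <- predict_net(Xs, 2, par, 4, 2, 2)
  expect_equal(y0[1:(t_cut - 1)], y2[1:(t_cut - 1)], tolerance = 1e-10)
  expect_equal(y0[t_cut], y2[t_cut], tolerance = 1e-10)
})

test_that("train_target fits a planted one-step dependency and is deterministic", {
  set.seed(5)
  Tn <- 150
  x1 <- rnorm(Tn)
  x2 <- c(0, 2 * x1[-Tn]) + rnorm(Tn, sd = 0.2)
  X <- rbind(cause = x1, target = x2, noise = rnorm(Tn))
  cfg <- fast_cfg(epochs = 300, seed = 3)
  tr <- train_target(X, "target", cfg)
  expect_lt(tr$loss_final, 0.2 * tr$loss_first)
  expect_equal(names(which.max(tr$attention[c("cause", "noise")])), "cause")
  # determinism given identical seed/config
  tr2 <- train_target(X, "target", cfg)
  expect_identical(tr$par, tr2$par)
  expect_identical(tr$loss_final, tr2$loss_final)
  # constant target trains to ~zero loss without error
  Xc <- rbind(a = rnorm(Tn), b = rep(0, Tn))
  trc <- train_target(Xc, "b", fast_cfg(epochs = 50))
  expect_lt(trc$loss_final, 1e-3)
  # non-finite input rejected
  Xn <- X; Xn[1, 1] <- NA
  expect_error(train_target(Xn, "target", cfg), "non-finite")
})

test_that("threshold_attention splits at the largest upper-half gap", {
  s <- c(a = 0.9, b = 0.8, c = 0.05, d = 0.04)
  th <- threshold_attention(s)
  expect_setequal(th$causes, c("a", "b"))
  expect_equal(th$tau, 0.8)
  # survivors renormalized by softmax, zeros elsewhere
  expect_equal(sum(th$renormalized), 1)
  expect_equal(unname(th$renormalized[c("c", "d")]), c(0, 0))
  # one dominant score
  th1 <- threshold_attention(c(x = 1.0, y = 0.01, z = 0.01))
  expect_equal(th1$causes, "x")
  # all equal: no gap, all retained
  the <- threshold_attention(c(p = 0.5, q = 0.5, r = 0.5))
  expect_setequal(the$causes, c("p", "q", "r"))
  # single input after exclusion -> empty candidate set
  expect_equal(length(threshold_attention(c(only = 1), exclude = "only")$causes), 0)
})

test_that("permutation-importance decision rule arithmetic", {
  # destroying little of the improvement (loss snaps back near first epoch)
  d1 <- pi_decision(1.0, 0.9, 0.25, pi_ratio = 0.8)
  expect_true(d1$accept)
  expect_equal(d1$delta_loss, 0.1)
  # permuted loss still far below the first-epoch level -> not relied upon
  d2 <- pi_decision(1.0, 0.3, 0.25, pi_ratio = 0.8)
  expect_false(d2$accept)
  expect_equal(d2$delta_loss, 0.7)
  # boundary: delta exactly 0.8 * ground loss accepts (rule is <=)
  d3 <- pi_decision(1.0, 1.0 - 0.8 * 0.25, 0.25, pi_ratio = 0.8)
  expect_equal(d3$delta_loss, 0.8 * 0.25)
  expect_true(d3$accept)
})

test_that("estimate_delay maps kernel taps to lags with most-recent = 0", {
  fake <- structure(list(target = 2, target_id = "t",
                         W0 = rbind(i = c(0.1, 0.2, 1.5, 0.3),
                                    t = c(1.5, 0.1, 0.1, 0.1))),
                    class = "trained_tcn")
  # argmax at tap 3 of 4 for an exogenous cause -> delay 1
  expect_equal(estimate_delay(fake, "i"), 1)
  # peak at the most recent tap -> delay 0
  fake$W0["i", ] <- c(0.1, 0.2, 0.3, 1.5)
  expect_equal(estimate_delay(fake, "i"), 0)
  # autoregressive channel is offset by one
  expect_equal(estimate_delay(fake, "t"), 3 + 1)
  # ties resolve to the smallest delay (most recent tap)
  fake$W0["i", ] <- c(1, 1, 1, 1)
  expect_equal(estimate_delay(fake, "i"), 0)
  # sign of the weight does not matter
  fake$W0["i", ] <- c(0.1, -2, 0.1, 0.1)
  expect_equal(estimate_delay(fake, "i"), 2)
})

test_that("planted lags are recovered through training", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    sys <- generate_lagged_system(
      n_genes = 5, t_len = 200,
      edges = data.frame(cause = 1, target = 2, lag = 3, sign = 1, effect = 2),
      seed = s)
    tr <- train_target(sys$X, "g02", fast_cfg(epochs = 300, seed = s))
    total <- total + 1
    if (estimate_delay(tr, "g01") == 3) hits <- hits + 1
  }
  expect_gte(hits / total, 0.8)
})

test_that("discover recovers a planted chain and respects max_steps", {
  sys <- generate_lagged_system(
    n_genes = 10, t_len = 200,
    edges = data.frame(cause = 1, target = 2, lag = 1, sign = 1, effect = 2),
    seed = 7)
  g <- discover(sys$X, cfg = fast_cfg(epochs = 400, seed = 7))
  key <- edge_key(g$edges)
  expect_true("g01 g02" %in% key)
  hit <- g$edges[key == "g01 g02", ]
  expect_equal(hit$sign, "positive")
  expect_equal(hit$delay, 1)
  # max_steps = 0 excludes all lag >= 1 edges
  g0 <- discover(sys$X, cfg = fast_cfg(epochs = 400, seed = 7), max_steps = 0)
  expect_false("g01 g02" %in% edge_key(g0$edges))
  # empty target set -> empty graph
  ge <- discover(sys$X, targets = character(0), cfg = fast_cfg(epochs = 10))
  expect_equal(nrow(ge$edges), 0)
})

test_that("row order permutes labels only", {
  sys <- generate_lagged_system(
    n_genes = 6, t_len = 120,
    edges = data.frame(cause = 1, target = 4, lag = 1, sign = -1, effect = 2),
    seed = 2)
  cfg <- fast_cfg(epochs = 200, seed = 9)
  g1 <- discover(sys$X, cfg = cfg)
  perm <- c(4, 2, 6, 1, 3, 5)
  Xp <- codiff_matrix(sys$X$X[perm, ])
  g2 <- discover(Xp, cfg = cfg)
  k1 <- sort(paste(g1$edges$cause, g1$edges$target, g1$edges$sign, g1$edges$delay))
  k2 <- sort(paste(g2$edges$cause, g2$edges$target, g2$edges$sign, g2$edges$delay))
  expect_identical(k1, k2)
})
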