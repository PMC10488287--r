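#' Generate a lagged causal system with known ground truth
#'
#' Vector-autoregressive-style construction: each planted edge contributes
#' `sign * effect * x_cause[t - lag]` to its target, plus Gaussian noise;
#' genes that are not targets of any edge are independent Gaussian noise.
#' With the default effect size 2 and unit noise, the signal-to-noise ratio
#' of a single-cause target is 4.
#'
#' @param n_genes number of series N.
#' @param t_len series length T.
#' @param edges data.frame with columns cause, target (indices or gene
#'   names), lag (>= 0 steps), sign (+1/-1 or "positive"/"negative"),
#'   effect (positive effect size). `NULL` plants no edges.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed; output is deterministic given the seed.
#' @return List with `X` (a `codiff_matrix`) and `truth` (the edge
#'   data.frame with gene names and numeric signs).
#' @export
generate_lagged_system <- function(n_genes = 10, t_len = 200, edges = NULL,
                                   noise_sd = 1, seed = 0) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(edges))
    edges <- data.frame(cause = integer(0), target = integer(0),
                        lag = integer(0), sign = numeric(0),
                        effect = numeric(0))
  to_idx <- function(v) if (is.character(v)) match(v, genes) else as.integer(v)
  ed <- data.frame(cause = to_idx(edges$cause), target = to_idx(edges$target),
                   lag = as.integer(edges$lag),
                   sign = if (is.character(edges$sign))
                     ifelse(edges$sign == "positive", 1, -1)
                   else sign(edges$sign),
                   effect = as.numeric(edges$effect))
  if (nrow(ed) > 0 && any(ed$lag >= t_len))
    stopf("planted lag >= series length")
  X <- with_seed(seed, {
    x <- matrix(rnorm(n_genes * t_len, sd = noise_sd), n_genes, t_len)
    if (nrow(ed) > 0) {
      for (t in seq_len(t_len)) {
        for (e in seq_len(nrow(ed))) {
          tl <- t - ed$lag[e]
          if (tl >= 1)
            x[ed$target[e], t] <- x[ed$target[e], t] +
              ed$sign[e] * ed$effect[e] * x[ed$cause[e], tl]
        }
      }
    }
    x
  })
  rownames(X) <- genes
  truth <- data.frame(cause = genes[ed$cause], target = genes[ed$target],
                      lag = ed$lag,
                      sign = ifelse(ed$sign >= 0, "positive", "negative"),
                      effect = ed$effect, stringsAsFactors = FALSE)
  list(X = codiff_matrix(X), truth = truth)
}

# random planted system used by tests/acceptance: n_edges edges with lags in
# lag_range, effect size giving SNR = effect^2 (unit-variance causes, unit
# noise); causes and targets disjoint so the system stays acyclic
random_planted_system <- function(n_genes = 10, t_len = 200, n_edges = 3,
                                  lag_range = 1:3, effect = 2, seed = 0) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  ed <- with_seed(derive_seed(seed, 1), {
    pool <- sample(n_genes)
    causes <- pool[seq_len(n_edges)]
    targets <- pool[n_edges + seq_len(n_edges)]
    data.frame(cause = causes, target = targets,
               lag = sample(lag_range, n_edges, replace = TRUE),
               sign = sample(c(1, -1), n_edges, replace = TRUE),
               effect = effect)
  })
  generate_lagged_system(n_genes, t_len, ed, noise_sd = 1,
                         seed = derive_seed(seed, 2))
}

logistic_ramp <- function(s, center = 0.5, width = 0.1) {
  1 / (1 + exp(-(s - center) / width))
}

# smooth random response curve on [0,1]: a seeded mixture of sinusoids,
# rescaled to [0, 1]. Wiggly (non-monotone) curves are essential: a monotone
# response is fully predictable from the target's own past, leaving no
# incentive for the network to attend to the driver.
response_curve <- function(seed, n_waves = 2, freqs = 1:2) {
  coefs <- with_seed(seed, list(a = rnorm(n_waves), ph = runif(n_waves, 0, 2 * pi),
                                fr = sample(rep(freqs, 2), n_waves)))
  function(s) {
    y <- rep(0, length(s))
    for (w in seq_len(n_waves))
      y <- y + coefs$a[w] * sin(2 * pi * coefs$fr[w] * s + coefs$ph[w])
    rng <- range(y)
    if (diff(rng) < 1e-12) return(rep(0.5, length(s)))
    (y - rng[1]) / diff(rng)
  }
}

#' Generate a paired case/control dataset with planted co-differential
#' structure
#'
#' Negative-binomial counts whose means follow smooth logistic ramps of a
#' latent cell position (the trajectory). "Responder" genes differ between
#' case and control along the trajectory with a planted lag structure
#' relative to a driver gene; "decoy" gene pairs share a trajectory-driven
#' mean in *both* conditions, so they are strongly correlated within each
#' condition but have uncorrelated case-minus-control profiles (the
#' false-positive pattern the co-differential construction is designed to
#' exclude).
#'
#' @param n_genes total genes (>= 2 + 2*n_responders + 2*n_decoy_pairs).
#' @param n_cells_case,n_cells_control cells per condition.
#' @param n_responders responder genes lag-coupled to the driver.
#' @param n_decoy_pairs decoy pairs planted.
#' @param n_markers trajectory marker genes whose means follow smooth curves
#'   of the latent position *identically in both conditions*. They make the
#'   trajectory recoverable by pseudotime in each condition (as cell-state
#'   programs do in real data) while contributing no co-differential
#'   structure.
#' @param nb_dispersion negative binomial dispersion (size = 1/dispersion).
#' @param base_mean baseline mean expression per gene.
#' @param amplitude multiplicative response amplitude of perturbed genes.
#' @param burst_weight fraction of the driver's activity signal contributed
#'   by the bursty (fine-scale) component; the remainder is the smooth
#'   program. Bursts are what make the planted edges *temporally*
#'   identifiable: a purely smooth response is predictable from the
#'   target's own past, leaving no conditional dependence on the driver.
#' @param seed integer seed.
#' @return List with `case`, `control` (`sctiger_matrix`), `truth`
#'   (driver, responders, per-responder lag fractions, decoy pairs) and
#'   `latent` (per-cell positions, per condition).
#' @export
generate_case_control <- function(n_genes = 60, n_cells_case = 150,
                                  n_cells_control = 150, n_responders = 3,
                                  n_decoy_pairs = 1, n_markers = 30,
                                  nb_dispersion = 0.5,
                                  base_mean = 30, amplitude = 6,
                                  burst_weight = 0.6, seed = 0) {
  need <- 1 + n_responders + 2 * n_decoy_pairs + n_markers
  if (n_genes < need)
    stopf("n_genes must be at least %d for the requested structure", need)
  genes <- sprintf("G%03d", seq_len(n_genes))
  driver <- genes[1]
  responders <- genes[1 + seq_len(n_responders)]
  decoys <- if (n_decoy_pairs > 0)
    matrix(genes[1 + n_responders + seq_len(2 * n_decoy_pairs)],
           ncol = 2, byrow = TRUE) else matrix(character(0), ncol = 2)
  markers <- if (n_markers > 0)
    genes[1 + n_responders + 2 * n_decoy_pairs + seq_len(n_markers)]
    else character(0)

  sim <- with_seed(seed, {
    s_case <- sort(runif(n_cells_case))
    s_ctrl <- sort(runif(n_cells_control))
    mu0 <- exp(rnorm(n_genes, log(base_mean), 0.3))
    # the regulator's targets are lowly expressed: the regime in which a
    # temporal-causal readout has power (the target's own noisy past
    # carries little information relative to the regulator's series).
    # The regulator itself stays at baseline abundance: a gene dominating
    # the per-cell depth would anti-couple to every other gene through
    # total-count normalization.
    mu0[match(responders, genes)] <- mu0[match(responders, genes)] * 0.3
    lags <- runif(n_responders, 0.04, 0.08)   # trajectory-fraction delays
    fsmooth <- response_curve(derive_seed(seed, 97))
    fburst <- response_curve(derive_seed(seed, 98), n_waves = 4, freqs = 2:3)
    fcurve <- function(s) (1 - burst_weight) * fsmooth(s) +
      burst_weight * fburst(s)
    # cell-state marker programs: gentle half-period arcs (monotone-ish);
    # abrupt multi-modal marker programs would fold the trajectory manifold
    mcurves <- lapply(seq_along(markers), function(q)
      response_curve(derive_seed(seed, 200 + q), n_waves = 1, freqs = 0.5))

    mean_for <- function(s, condition) {
      mu <- matrix(rep(mu0, length(s)), n_genes, length(s))
      rownames(mu) <- genes
      # driver and responders are condition-specific: near-silent in the
      # control condition and activated along the trajectory in the case
      # condition (the canonical activation pattern of perturbed programs)
      off <- 0.1
      mu[driver, ] <- mu0[match(driver, genes)] * off
      for (q in seq_len(n_responders))
        mu[responders[q], ] <- mu0[match(responders[q], genes)] * off
      if (condition == "case") {
        mu[driver, ] <- mu0[match(driver, genes)] *
          (off + amplitude * fcurve(s))
        for (q in seq_len(n_responders)) {
          rq <- fcurve(pmax(s - lags[q], 0))
          mu[responders[q], ] <- mu0[match(responders[q], genes)] *
            (off + amplitude * rq)
        }
      }
      # decoys: identical strong trajectory response in BOTH conditions
      if (nrow(decoys) > 0) {
        rampd <- logistic_ramp(s, 0.5, 0.1)
        for (p in seq_len(nrow(decoys))) {
          for (g in decoys[p, ])
            mu[g, ] <- mu0[match(g, genes)] * (1 + 2 * amplitude * rampd)
        }
      }
      # markers: per-gene smooth state curves, shared by both conditions
      for (q in seq_along(markers))
        mu[markers[q], ] <- mu0[match(markers[q], genes)] *
          (1 + amplitude * mcurves[[q]](s))
      mu
    }
    draw <- function(mu) {
      cnt <- matrix(rnbinom(length(mu), size = 1 / nb_dispersion, mu = mu),
                    nrow(mu), ncol(mu))
      rownames(cnt) <- genes
      cnt
    }
    mc <- draw(mean_for(s_case, "case"))
    mk <- draw(mean_for(s_ctrl, "control"))
    colnames(mc) <- sprintf("case_c%03d", seq_len(n_cells_case))
    colnames(mk) <- sprintf("ctrl_c%03d", seq_len(n_cells_control))
    list(case = mc, control = mk, s_case = s_case, s_ctrl = s_ctrl,
         lags = lags)
  })

  list(case = expression_matrix(sim$case, "case"),
       control = expression_matrix(sim$control, "control"),
       truth = list(driver = driver, responders = responders,
                    lag_fractions = sim$lags, decoy_pairs = decoys,
                    markers = markers),
       latent = list(case = sim$s_case, control = sim$s_ctrl))
}

#' Inject artificial dropout zeros
#'
#' Raises the matrix-wide zero fraction to `target_total_zero_fraction` by
#' replacing uniformly sampled nonzero entries with zeros. Existing zeros and
#' surviving entries are untouched.
#'
#' @param m `sctiger_matrix` of raw counts.
#' @param target_total_zero_fraction desired matrix-wide zero fraction; must
#'   be at least the current fraction.
#' @param seed integer seed.
#' @return The matrix with additional zeros.
#' @export
inject_dropout <- function(m, target_total_zero_fraction, seed = 0) {
  assert_matrix(m)
  x <- m$counts
  size <- length(x)
  cur <- sum(x == 0) / size
  if (target_total_zero_fraction < cur)
    stopf("target zero fraction (%.4f) below current fraction (%.4f)",
          target_total_zero_fraction, cur)
  n_new <- floor(target_total_zero_fraction * size) - sum(x == 0)
  if (n_new <= 0) return(m)
  nz <- which(x != 0)
  kill <- with_seed(seed, sample(nz, n_new))
  x[kill] <- 0
  expression_matrix(x, m$condition, normalized = m$normalized)
}
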