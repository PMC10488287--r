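#' Configuration of the temporal causal discovery engine
#'
#' Hyperparameters of the per-target attention-based dilated
#' depthwise-separable temporal convolutional networks and of the
#' permutation-importance validation step. Defaults follow the published
#' settings: kernel size 4, dilation coefficient 4, two hidden layers,
#' learning rate 1e-2, 5000 Adam epochs, permutation-importance ratio 0.8.
#'
#' @param kernel_size convolution kernel size K (>= 2).
#' @param dilation_coef dilation coefficient c; layer l uses dilation c^l.
#' @param hidden_layers number of hidden layers L (>= 1).
#' @param epochs Adam training epochs.
#' @param learning_rate Adam learning rate.
#' @param pi_ratio acceptance ratio of the permutation-importance rule
#'   (accept a candidate cause iff `delta_loss <= pi_ratio * ground_loss`).
#' @param pi_shuffles number of independent time-shuffles averaged in the
#'   permutation-importance loss. A single shuffle makes the decision rule
#'   high-variance (one draw can overshoot or undershoot the destroyed-loss
#'   level); the default averages 5.
#' @param standardize if `TRUE` (default) each input series is z-scored
#'   before training. Without this, high-variance series dominate the
#'   shared pointwise combination and spuriously attract attention and
#'   permutation importance regardless of temporal relevance.
#' @param att_softmax if `TRUE` (default) the attention vector competes
#'   through a softmax (scaled so the uniform weight is 1) before
#'   multiplying the input series, which concentrates attention on
#'   genuinely predictive inputs; `FALSE` multiplies the raw scores.
#' @param seed integer seed governing weight initialization and shuffles.
#' @param use_gpu ignored placeholder (CPU implementation); accepted so
#'   configurations mentioning it remain valid.
#' @return An `addstcn_config` list.
#' @export
addstcn_config <- function(kernel_size = 4, dilation_coef = 4,
                           hidden_layers = 2, epochs = 5000,
                           learning_rate = 1e-2, pi_ratio = 0.8,
                           pi_shuffles = 5, standardize = TRUE,
                           att_softmax = TRUE, seed = 0,
                           use_gpu = FALSE) {
  stopifnot(kernel_size >= 2, dilation_coef >= 1, hidden_layers >= 1,
            epochs >= 1, learning_rate > 0, pi_ratio > 0, pi_ratio <= 1,
            pi_shuffles >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 dilation_coef = as.integer(dilation_coef),
                 hidden_layers = as.integer(hidden_layers),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 pi_ratio = pi_ratio,
                 pi_shuffles = as.integer(pi_shuffles),
                 standardize = isTRUE(standardize),
                 att_softmax = isTRUE(att_softmax),
                 seed = seed, use_gpu = isTRUE(use_gpu)),
            class = "addstcn_config")
}

#' Receptive field of the configured architecture
#'
#' Number of past input positions (including the current one) that can
#' influence one output position: `1 + (K - 1) * sum(c^l, l = 0..L)`.
#'
#' @param cfg an [addstcn_config()].
#' @return Integer receptive field in pseudotime steps.
#' @export
receptive_field <- function(cfg) {
  K <- cfg$kernel_size; c <- cfg$dilation_coef; L <- cfg$hidden_layers
  1L + (K - 1L) * sum(c^(0:L))
}

n_params <- function(N, cfg) {
  K <- cfg$kernel_size; L <- cfg$hidden_layers
  N + (L + 1) * N * K + (L + 1) * N + L + N + 1
}

# deterministic initial parameter vector: attention at 1, PReLU slopes 0.25,
# kernels and pointwise weights small Gaussians, biases 0. Each channel's
# random draws come from a seed derived from its NAME, so permuting the row
# order of the input permutes the initialization with it.
init_params <- function(N, cfg, seed, names = NULL) {
  K <- cfg$kernel_size; L <- cfg$hidden_layers
  if (is.null(names)) names <- seq_len(N)
  draws <- lapply(seq_len(N), function(i)
    with_seed(derive_seed(seed, name_hash(names[i])), {
      list(W = rnorm((L + 1) * K, sd = 0.1), v = rnorm(1, sd = 0.1))
    }))
  a <- rep(1, N)
  # layer-major, channel-major within layer: W[l][i*K + k]
  W <- unlist(lapply(0:L, function(l)
    unlist(lapply(draws, function(d) d$W[l * K + 1:K]))))
  b <- rep(0, (L + 1) * N)
  alpha <- rep(0.25, L)
  v <- vapply(draws, function(d) d$v, 0)
  c(a, W, b, alpha, v, 0)
}

# z-score rows (constant rows are centered only), then orient each row so
# its skewness is nonnegative. The orientation makes training invariant to
# a joint negation of all series -- i.e. to swapping which condition is
# "case" -- since which condition is subtracted from which is arbitrary.
standardize_rows <- function(Xm) {
  mu <- rowMeans(Xm)
  sdv <- apply(Xm, 1, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(Xm, 1, mu, "-"), 1, sdv, "/")
  flip <- rowSums(z^3) < 0
  z[flip, ] <- -z[flip, , drop = FALSE]
  z
}

param_slices <- function(N, cfg) {
  K <- cfg$kernel_size; L <- cfg$hidden_layers
  list(a = 1:N,
       W0 = N + 1:(N * K),
       v = (N + (L + 1) * N * K + (L + 1) * N + L) + 1:N)
}

#' Train one per-target network
#'
#' Fits the network predicting series `j` from the past of all series with
#' full-batch Adam on the mean-squared-error loss. The autoregressive channel
#' (`i = j`) only sees values up to `t - 1`; exogenous channels see values up
#' to `t`. Records the loss at the first epoch and the final (ground) loss.
#'
#' @param X a `codiff_matrix` (or plain genes-by-positions matrix).
#' @param j target gene id or row index.
#' @param cfg an [addstcn_config()].
#' @return A `trained_tcn`: target, attention scores, first-layer kernels,
#'   losses, predictions and the full parameter vector.
#' @export
train_target <- function(X, j, cfg = addstcn_config()) {
  Xm <- if (inherits(X, "codiff_matrix")) X$X else as.matrix(X)
  N <- nrow(Xm); Tn <- ncol(Xm)
  if (N < 1 || Tn < 2) stopf("need at least 1 series of length >= 2")
  if (any(!is.finite(Xm))) stopf("input series contain non-finite values")
  jj <- if (is.character(j)) match(j, rownames(Xm)) else as.integer(j)
  if (is.na(jj) || jj < 1 || jj > N) stopf("target '%s' not found", as.character(j))
  if (Tn <= receptive_field(cfg))
    warnf("series length %d does not exceed the receptive field (%d)",
          Tn, receptive_field(cfg))
  if (cfg$standardize) Xm <- standardize_rows(Xm)
  # seeds from gene NAMES so that permuting row order changes nothing
  # but labels
  par0 <- init_params(N, cfg,
                      derive_seed(cfg$seed, name_hash(rownames(Xm)[jj] %||% jj)),
                      names = rownames(Xm))
  fit <- .addstcn_fit(Xm, jj, par0, cfg$kernel_size, cfg$dilation_coef,
                      cfg$hidden_layers, cfg$epochs, cfg$learning_rate,
                      cfg$att_softmax)
  sl <- param_slices(N, cfg)
  W0 <- matrix(fit$par[sl$W0], nrow = N, ncol = cfg$kernel_size, byrow = TRUE)
  rownames(W0) <- rownames(Xm)
  att <- abs(as.numeric(fit$attention))
  names(att) <- rownames(Xm)
  structure(list(target = jj, target_id = rownames(Xm)[jj],
                 attention = att, W0 = W0,
                 loss_first = fit$loss_first, loss_final = fit$loss_final,
                 yhat = as.numeric(fit$yhat), par = as.numeric(fit$par),
                 cfg = cfg, n = N, t_len = Tn),
            class = "trained_tcn")
}

#' @export
print.trained_tcn <- function(x, ...) {
  cat(sprintf("<trained_tcn> target '%s': first-epoch loss %.4g, ground loss %.4g\n",
              x$target_id, x$loss_first, x$loss_final))
  invisible(x)
}

# evaluate the trained network's loss on a (possibly modified) input
# matrix; the matrix must already be on the training scale (standardized
# when the config says so)
eval_loss <- function(trained, Xm) {
  cfg <- trained$cfg
  .addstcn_loss_grad(Xm, trained$target, trained$par, cfg$kernel_size,
                     cfg$dilation_coef, cfg$hidden_layers,
                     want_grad = FALSE, att_softmax = cfg$att_softmax)$loss
}

#' Select potential causes by attention-gap thresholding
#'
#' Sorts the attention scores in decreasing order and places the threshold
#' `tau` at the largest gap between consecutive scores; indices scoring at or
#' above `tau` are the potential causes. When all scores are (numerically)
#' equal there is no gap and all indices are retained. Scores below the
#' threshold are zeroed and the survivors renormalized by softmax.
#'
#' @param scores named numeric vector of nonnegative attention scores.
#' @param exclude indices or names to exclude (typically the target itself).
#' @return List with `causes` (names/indices retained), `tau`, and
#'   `renormalized` (softmax over survivors, zeros elsewhere).
#' @export
threshold_attention <- function(scores, exclude = NULL) {
  s <- scores
  if (!is.null(exclude)) {
    drop_idx <- if (is.character(exclude)) match(exclude, names(s)) else exclude
    s <- s[-drop_idx[!is.na(drop_idx)]]
  }
  if (length(s) == 0)
    return(list(causes = character(0), tau = NA_real_,
                renormalized = numeric(0)))
  ord <- order(-s)
  ss <- s[ord]
  gaps <- -diff(ss)
  # only gaps in the upper half of the sorted scores can define the
  # threshold: a single low outlier must not retain the whole bulk
  half <- ceiling(length(gaps) / 2)
  gaps_h <- gaps[seq_len(half)]
  out <- numeric(length(s)); names(out) <- names(s)
  if (length(gaps_h) == 0 || max(gaps_h) <= 1e-12) {
    keep <- seq_along(s)          # all equal: no gap, retain everything
    tau <- unname(min(s))
  } else {
    cut <- which.max(gaps_h)      # first largest gap in the upper half
    tau <- unname(ss[cut])
    keep <- which(s >= tau)
  }
  w <- exp(s[keep] - max(s[keep]))
  out[keep] <- w / sum(w)
  causes <- if (!is.null(names(s))) names(s)[keep] else keep
  list(causes = causes, tau = tau, renormalized = out)
}

#' Permutation-importance decision rule
#'
#' Pure arithmetic of the causal validation rule: a potential cause is
#' accepted as a true cause iff `delta_loss <= pi_ratio * (loss_first_epoch
#' - ground_loss)`, where `delta_loss = loss_first_epoch - loss_permuted`.
#' Shuffling a true cause must push the loss most of the way back to (or
#' beyond) the untrained level, i.e. destroy at least `1 - pi_ratio` of the
#' training improvement; a channel whose shuffling leaves most of the
#' improvement intact was not relied on and is rejected.
#'
#' @param loss_first_epoch network loss at the first training epoch.
#' @param loss_permuted loss of the trained network on the input with the
#'   candidate cause time-shuffled.
#' @param ground_loss final training loss of the fitted network.
#' @param pi_ratio acceptance ratio (default 0.8).
#' @return List with `accept` (logical) and `delta_loss`.
#' @export
pi_decision <- function(loss_first_epoch, loss_permuted, ground_loss,
                        pi_ratio = 0.8) {
  delta <- loss_first_epoch - loss_permuted
  list(accept = delta <= pi_ratio * (loss_first_epoch - ground_loss),
       delta_loss = delta)
}

#' Validate a potential cause by permutation importance
#'
#' Shuffles the candidate's series in time (destroying its temporal
#' structure), re-evaluates the trained network, and applies [pi_decision()].
#'
#' @param trained a `trained_tcn`.
#' @param X the input `codiff_matrix` (or matrix) the network was trained on.
#' @param i candidate cause (gene id or row index).
#' @param seed integer seed for the shuffle(s).
#' @return List with `accept`, `delta_loss`, `loss_permuted`, `cause`,
#'   `target`.
#' @export
permutation_importance <- function(trained, X, i, seed = 0) {
  Xm <- if (inherits(X, "codiff_matrix")) X$X else as.matrix(X)
  ii <- if (is.character(i)) match(i, rownames(Xm)) else as.integer(i)
  if (is.na(ii)) stopf("candidate '%s' not found", as.character(i))
  cfg <- trained$cfg
  if (cfg$standardize) Xm <- standardize_rows(Xm)
  losses <- numeric(cfg$pi_shuffles)
  for (s in seq_len(cfg$pi_shuffles)) {
    perm <- with_seed(derive_seed(seed, name_hash(rownames(Xm)[ii] %||% ii) + s),
                      sample(ncol(Xm)))
    Xp <- Xm
    Xp[ii, ] <- Xm[ii, perm]
    losses[s] <- eval_loss(trained, Xp)
  }
  dec <- pi_decision(trained$loss_first, mean(losses), trained$loss_final,
                     cfg$pi_ratio)
  list(accept = dec$accept, delta_loss = dec$delta_loss,
       loss_permuted = mean(losses),
       cause = rownames(Xm)[ii] %||% ii, target = trained$target_id)
}

#' Read the cause-to-target delay off the trained kernels
#'
#' The delay equals the lag of the highest-magnitude first-layer kernel tap
#' for the cause channel: the most recent tap maps to delay 0 for an
#' exogenous cause and delay 1 for the autoregressive channel (whose input is
#' pre-shifted by one step). Ties are resolved toward the smallest delay.
#'
#' @param trained a `trained_tcn`.
#' @param i cause gene id or row index.
#' @return Non-negative integer delay in pseudotime steps.
#' @export
estimate_delay <- function(trained, i) {
  ii <- if (is.character(i)) match(i, rownames(trained$W0)) else as.integer(i)
  w <- abs(trained$W0[ii, ])
  K <- length(w)
  k_star <- max(which(w == max(w)))   # ties -> most recent tap -> smallest delay
  (K - k_star) + as.integer(ii == trained$target)
}

# regulation sign read at the estimated delay: correlation between the
# cause series and the target series shifted back by `delay` steps (the
# plain correlation of the two co-differential vectors when delay = 0)
lagged_sign <- function(x_i, x_j, delay = 0) {
  Tn <- length(x_i)
  if (delay > 0 && Tn - delay >= 3) {
    a <- x_i[1:(Tn - delay)]
    b <- x_j[(1 + delay):Tn]
    if (sd(a) > 0 && sd(b) > 0) return(regulation_sign(a, b))
  }
  regulation_sign(x_i, x_j)
}

#' Discover a temporal causal graph
#'
#' For each target: train its network, select potential causes by attention
#' thresholding, validate each by permutation importance, read the delay off
#' the kernels and assign the regulation sign from the correlation of the two
#' series. Self-loops are excluded unless `self_loops = TRUE`. Edges with
#' delay greater than `max_steps` are dropped when `max_steps` is set.
#'
#' @param X a `codiff_matrix` or genes-by-positions matrix.
#' @param targets gene ids (or indices) to model as targets; defaults to all.
#' @param cfg an [addstcn_config()].
#' @param max_steps optional maximum delay allowed for a reported edge.
#' @param self_loops allow `i == j` edges (default FALSE).
#' @return A `causal_graph`: list with `edges` data.frame (cause, target,
#'   sign, delay, attention, delta_loss) and `genes`.
#' @export
discover <- function(X, targets = NULL, cfg = addstcn_config(),
                     max_steps = NULL, self_loops = FALSE) {
  Xm <- if (inherits(X, "codiff_matrix")) X$X else as.matrix(X)
  if (is.null(rownames(Xm))) rownames(Xm) <- paste0("gene", seq_len(nrow(Xm)))
  genes <- rownames(Xm)
  targets <- if (is.null(targets)) genes
             else if (is.numeric(targets)) genes[targets] else targets
  missing <- setdiff(targets, genes)
  if (length(missing) > 0) stopf("target(s) not in X: %s",
                                 paste(missing, collapse = ", "))
  if (length(targets) > 0 && ncol(Xm) <= receptive_field(cfg))
    warnf_once("series length %d does not exceed the receptive field (%d)",
               ncol(Xm), receptive_field(cfg))
  rows <- list()
  for (tg in targets) {
    tr <- suppressWarnings(train_target(Xm, tg, cfg))
    excl <- if (self_loops) NULL else tg
    th <- threshold_attention(tr$attention, exclude = excl)
    for (cand in th$causes) {
      if (sd(Xm[cand, ]) == 0 || sd(Xm[tg, ]) == 0) next
      pi <- permutation_importance(tr, Xm, cand, seed = cfg$seed)
      if (!pi$accept) next
      delay <- estimate_delay(tr, cand)
      if (!is.null(max_steps) && delay > max_steps) next
      rows[[length(rows) + 1]] <- data.frame(
        cause = cand, target = tg,
        sign = lagged_sign(Xm[cand, ], Xm[tg, ], delay),
        delay = delay,
        attention = unname(tr$attention[cand]),
        delta_loss = pi$delta_loss,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(cause = character(0), target = character(0),
                    sign = character(0), delay = integer(0),
                    attention = numeric(0), delta_loss = numeric(0),
                    stringsAsFactors = FALSE)
  causal_graph(edges, genes)
}

#' @rdname discover
#' @param edges data.frame of validated edges.
#' @param genes character vector of node names.
#' @export
causal_graph <- function(edges, genes) {
  stopifnot(all(c("cause", "target", "sign", "delay") %in% names(edges)))
  if (nrow(edges) > 0 &&
      !all(c(edges$cause, edges$target) %in% genes))
    stopf("edge endpoints must be nodes of the graph")
  structure(list(edges = edges, genes = genes), class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("<causal_graph> %d genes, %d validated edges\n",
              length(x$genes), nrow(x$edges)))
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 10))
  invisible(x)
}
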