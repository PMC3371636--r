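# Approximate forward-backward Gibbs sampling on compressed blocks.  All
# observations inside a block are assumed to share one hidden state ("weak"
# state paths that switch state inside a block are ignored); the error this
# introduces is controlled by the analytic bound at the bottom of this file.

#' Joint Gaussian log-likelihood of a block from its moments
#'
#' Computes `log prod_{o in block} N(o; mean, variance)` in constant time
#' from the stored count, first and second moment:
#' `-(n/2) log(2 pi v) - (sum2 - 2 mean sum1 + n mean^2) / (2 v)`.
#'
#' @param block List with `count`, `sum1`, `sum2` (vectors are accepted and
#'   treated elementwise).
#' @param mean,variance Emission parameters; `variance > 0`.
#' @return Log-likelihood (vector if the block fields are vectors).
#' @export
block_emission_loglik <- function(block, mean, variance) {
  if (any(variance <= 0)) stop("variance must be strictly positive")
  n <- block$count
  -(n / 2) * log(2 * pi * variance) -
    (block$sum2 - 2 * mean * block$sum1 + n * mean^2) / (2 * variance)
}

#' Block forward recursion
#'
#' Forward variables on a compressed chromosome, restricted to state paths
#' that are constant within each block: block t contributes its joint
#' emission likelihood times `a_ii^(n_t - 1)` self-transitions, with a
#' single between-block transition `a_ji` linking consecutive blocks.  The
#' first block starts from `pi_i * a_ii^(n_1 - 1)`.
#'
#' @param hmm A `gaussian_hmm`.
#' @param blocks Block list (fields `count`, `sum1`, `sum2`).
#' @return List with `alpha` (T' x N scaled forward table), `loglik` (log
#'   probability of the observation sequence under the block-constant path
#'   family), and `ops` (executed inner multiply-adds).
#' @export
block_forward <- function(hmm, blocks) {
  if (length(blocks$count) < 1) stop("block sequence must be nonempty")
  E <- matrix(block_emission_matrix(blocks, hmm$means, hmm$variances),
              nrow = length(blocks$count))
  fwd_block_cpp(hmm$A, hmm$pi, E, as.integer(blocks$count))
}

#' Sample a block-constant state path
#'
#' Draws one state per block backward from the block forward table (last
#' block proportional to the forward row; earlier blocks proportional to
#' `alpha_t(i) * a_{i, s_{t+1}}`), then expands each block's state to all
#' its observations.
#'
#' @inheritParams block_forward
#' @param expand If `FALSE`, return the per-block states instead of the
#'   per-observation expansion.
#' @return Integer state vector (per observation, or per block).
#' @export
sample_block_path <- function(hmm, blocks, expand = TRUE) {
  f <- block_forward(hmm, blocks)
  q <- sample_path_cpp(f$alpha, hmm$A)
  if (expand) rep(q, blocks$count) else q
}

#' Parameter draw from block-level sufficient statistics
#'
#' Accumulates per-state emission statistics from block moments and
#' transition counts as `(n - 1)` self-transitions per block plus one
#' between-block transition per adjacent pair (cross-chromosome junctions
#' excluded; non-self transitions hidden inside a block are ignored by
#' construction), then draws parameters exactly as the uncompressed
#' conjugate updates do.
#'
#' @param blocks_list List of per-chromosome block lists.
#' @param block_states List of per-chromosome integer vectors, one state per
#'   block.
#' @param hyper An `hmm_hyperparameters`.
#' @param variances Current emission variances.
#' @return A `gaussian_hmm` drawn from the conditional posteriors.
#' @export
block_parameter_update <- function(blocks_list, block_states, hyper,
                                   variances) {
  N <- hyper$N
  n <- S <- SS <- numeric(N)
  trans <- matrix(0, N, N)
  init <- numeric(N)
  for (ci in seq_along(blocks_list)) {
    b <- blocks_list[[ci]]
    q <- block_states[[ci]]
    stopifnot(length(q) == length(b$count))
    for (i in seq_len(N)) {
      sel <- q == i
      n[i] <- n[i] + sum(b$count[sel])
      S[i] <- S[i] + sum(b$sum1[sel])
      SS[i] <- SS[i] + sum(b$sum2[sel])
      trans[i, i] <- trans[i, i] + sum(b$count[sel] - 1L)
    }
    if (length(q) > 1) {
      from <- q[-length(q)]; to <- q[-1]
      for (k in seq_along(from))
        trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
    }
    init[q[1]] <- init[q[1]] + 1
  }
  em <- draw_emission_params(n, S, SS, hyper, variances)
  tr <- draw_transitions(trans, init, hyper)
  gaussian_hmm(tr$A, tr$pi, em$means, em$variances,
               ordered = hyper$order_means)
}

#' Approximate forward-backward Gibbs sampling on compressed blocks
#'
#' Compresses the track once ([kd_compress()] plus [merge_blocks()]), then
#' runs `M` iterations of block-path sampling and block-level parameter
#' updates.  With `w = 0` the compression is the identity and the chain is
#' identical to [run_fbg()] under the same seed.  With `w = "auto"` the
#' width is chosen by L-method knee detection on the default
#' `0.25 sigma_D ... 4 sigma_D` grid.
#'
#' @inheritParams run_fbg
#' @param w Width in observation units, or `"auto"`.
#' @param delta Per-level width shrink factor of the compression.
#' @return An `fbg_chain`; `width_used` and `gamma` record the compression
#'   actually applied.
#' @export
run_approx_fbg <- function(track, hyper, w = "auto", M = 100, hmm0 = NULL,
                           seed = NULL, delta = 1.25, posterior_window = 10) {
  if (identical(w, "auto")) {
    curve <- compression_curve(track, default_width_grid(track$sigma_D), delta)
    w <- select_width_lmethod(curve)$w
  }
  if (!is.null(seed)) set.seed(seed)
  ct <- compress_track(track, w, delta)
  run_chain_engine(ct$blocks, track, hmm0, hyper, M, posterior_window,
                   model_kind = "approximate", width_used = w)
}

# ---------------------------------------------------------------------------
# Error bound for the weak-state-path approximation.

#' Analytic bound on the ignored weak-state-path mass
#'
#' For a symmetric Gaussian HMM (self-transition `t`, shared variance
#' `sigma2`, minimal mean separation `d`) and a block of `n` observations
#' whose value range keeps a margin `tau >= 0` from the decision midpoints
#' toward the neighboring state means, the total probability of all
#' length-`n` state paths relative to the block-constant paths is at most
#'
#' `alpha * ((1 + r c)^(n-1) + (N - 1) c^(2 n / N) (1 + r)^(n-1))`
#'
#' where r is the transition odds `(1 - t) / t` and
#' `c = exp(-d tau / (2 sigma2))`.  A value close
#' to 1 means the block-constant restriction loses almost no mass.
#'
#' @param t Self-transition probability, in (0, 1).
#' @param d Minimal separation between state means, > 0.
#' @param sigma2 Shared emission variance, > 0.
#' @param tau Margin from the block's value range to the neighboring
#'   decision midpoints; must be >= 0 for the bound to apply.
#' @param alpha Bound on the prefix-posterior ratio
#'   `max_j P(q_i = j | prefix) / P(q_i = s_x | prefix)`, >= 1.
#' @param n Block length, >= 1.
#' @param N State count, >= 2.
#' @return The bound (a number >= 1).
#' @export
lemma1_bound <- function(t, d, sigma2, tau, alpha = 1, n, N) {
  stopifnot(t > 0, t < 1, d > 0, sigma2 > 0, alpha >= 1, n >= 1, N >= 2)
  if (tau < 0) stop("the bound requires margin tau >= 0")
  r <- (1 - t) / t
  cc <- exp(-d * tau / (2 * sigma2))
  alpha * ((1 + r * cc)^(n - 1) + (N - 1) * cc^(2 * n / N) * (1 + r)^(n - 1))
}

#' Enumerated weak-state-path ratio
#'
#' Brute-force counterpart of [lemma1_bound()]: enumerates all `N^n` partial
#' state paths over a block of raw observations under a symmetric HMM and
#' returns the ratio of the total path mass to the mass of the
#' block-constant paths, weighting the first state by a given prefix
#' posterior.
#'
#' @param means Length-N state means of the symmetric HMM.
#' @param sigma2 Shared emission variance.
#' @param t Self-transition probability (non-self transitions get
#'   `(1 - t)/(N - 1)` each).
#' @param prefix_posterior Length-N distribution of the state entering the
#'   block.
#' @param block_obs Raw observations of the block (length `n`).
#' @return The enumerated ratio, >= 1.
#' @export
weak_path_ratio_oracle <- function(means, sigma2, t, prefix_posterior,
                                   block_obs) {
  N <- length(means)
  n <- length(block_obs)
  if (N^n > 1e6) stop("enumeration too large (N^n > 1e6)")
  A <- matrix((1 - t) / (N - 1), N, N); diag(A) <- t
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  logw <- log(prefix_posterior[paths[, 1]]) +
    emission_logdensity(block_obs[1], means[paths[, 1]], sigma2)
  if (n > 1) {
    for (k in 2:n) {
      logw <- logw + log(A[cbind(paths[, k - 1], paths[, k])]) +
        emission_logdensity(block_obs[k], means[paths[, k]], sigma2)
    }
  }
  const <- rowSums(paths != paths[, 1]) == 0
  m <- max(logw)
  sum(exp(logw - m)) / sum(exp(logw[const] - m))
}
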