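#' Conjugate prior hyperparameters for a Gaussian HMM
#'
#' Standard conjugate prior family: Normal priors on the emission means
#' (`mu_i ~ N(mu_mean_i, mu_var_i)`, with `mu_var` the prior *variance*),
#' Gamma priors on the emission precisions
#' (`1/sigma_i^2 ~ Gamma(shape = prec_shape_i, rate = prec_rate_i)`), and
#' Dirichlet priors on the initial distribution and each row of the
#' transition matrix.
#'
#' @param mu_mean,mu_var Length-N prior means and variances for the emission
#'   means.
#' @param prec_shape,prec_rate Length-N shapes and rates of the Gamma priors
#'   on the emission precisions.
#' @param dirichlet_A N x N matrix of positive Dirichlet parameters; row i is
#'   the prior for row i of the transition matrix.  Defaults to all ones.
#' @param dirichlet_pi Length-N positive Dirichlet parameters for the initial
#'   distribution.  Defaults to all ones.
#' @param order_means If `TRUE`, constrain sampled means to be non-decreasing
#'   (prevents label switching in multi-state copy-number models).
#' @return An object of class `hmm_hyperparameters`.
#' @export
hyperparameters <- function(mu_mean, mu_var, prec_shape, prec_rate,
                            dirichlet_A = NULL, dirichlet_pi = NULL,
                            order_means = FALSE) {
  N <- length(mu_mean)
  if (is.null(dirichlet_A)) dirichlet_A <- matrix(1, N, N)
  if (is.null(dirichlet_pi)) dirichlet_pi <- rep(1, N)
  dirichlet_A <- as.matrix(dirichlet_A)
  stopifnot(length(mu_var) == N, length(prec_shape) == N,
            length(prec_rate) == N, nrow(dirichlet_A) == N,
            ncol(dirichlet_A) == N, length(dirichlet_pi) == N)
  if (any(c(mu_var, prec_shape, prec_rate, dirichlet_A, dirichlet_pi) <= 0))
    stop("variances, shapes, rates and Dirichlet parameters must be positive")
  structure(list(N = N, mu_mean = as.numeric(mu_mean),
                 mu_var = as.numeric(mu_var),
                 prec_shape = as.numeric(prec_shape),
                 prec_rate = as.numeric(prec_rate),
                 dirichlet_A = unname(dirichlet_A),
                 dirichlet_pi = as.numeric(dirichlet_pi),
                 order_means = isTRUE(order_means)),
            class = "hmm_hyperparameters")
}

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g[which.max(shape)] <- 1  # degenerate underflow guard
  g / sum(g)
}

#' Enforce the mean-ordering constraint
#'
#' Accepts a draw of the joint mean vector only if it is non-decreasing;
#' otherwise redraws up to `max_retries` times and finally falls back to
#' sorting the last draw.  Rejection leaves the posterior truncated to the
#' ordered region; the fallback is recorded so chains can report it.
#'
#' @param draw_fun Function of no arguments returning a fresh joint draw of
#'   the mean vector.
#' @param first Optional already-drawn proposal to consider first.
#' @param max_retries Retry cap before the sort fallback.
#' @return List with `means`, `method` ("accept", "rejection", or
#'   "sort_fallback"), and `tries`.
#' @export
enforce_mean_ordering <- function(draw_fun, first = NULL, max_retries = 100) {
  m <- if (is.null(first)) draw_fun() else first
  if (!is.unsorted(m)) return(list(means = m, method = "accept", tries = 0L))
  for (k in seq_len(max_retries)) {
    m <- draw_fun()
    if (!is.unsorted(m)) return(list(means = m, method = "rejection", tries = k))
  }
  list(means = sort(m), method = "sort_fallback", tries = max_retries)
}

# Sufficient statistics (per state: count n, sum S, sum of squares SS) drive
# the emission update whether they come from raw observations or from block
# moments.
draw_emission_params <- function(n, S, SS, hyper, variances) {
  N <- hyper$N
  draw_mu <- function() {
    post_var <- 1 / (1 / hyper$mu_var + n / variances)
    post_mean <- (hyper$mu_mean / hyper$mu_var + S / variances) * post_var
    stats::rnorm(N, post_mean, sqrt(post_var))
  }
  if (hyper$order_means) {
    res <- enforce_mean_ordering(draw_mu)
    mu <- res$means
    ordering <- res$method
  } else {
    mu <- draw_mu()
    ordering <- "none"
  }
  # precision update uses the mean drawn in this scan
  sq <- SS - 2 * mu * S + n * mu^2
  sq <- pmax(sq, 0)
  prec <- stats::rgamma(N, shape = hyper$prec_shape + n / 2,
                        rate = hyper$prec_rate + sq / 2)
  list(means = mu, variances = 1 / prec, ordering = ordering)
}

#' Draw emission parameters from their conjugate posteriors
#'
#' Given a state path, draws each state's mean from its Normal posterior
#' (conditioning on the current variance) and then each precision from its
#' Gamma posterior (conditioning on the newly drawn mean).  States with no
#' assigned observations draw from the prior.
#'
#' @param obs Numeric observation vector (single chromosome) or list of
#'   vectors.
#' @param path Integer state path matching `obs` in shape.
#' @param hyper An `hmm_hyperparameters`.
#' @param variances Current emission variances (used in the mean update).
#' @return List with `means`, `variances`, and `ordering` (how the ordering
#'   constraint, if any, was satisfied).
#' @export
sample_emission_parameters <- function(obs, path, hyper, variances) {
  o <- unlist(obs, use.names = FALSE)
  q <- unlist(path, use.names = FALSE)
  stopifnot(length(o) == length(q))
  N <- hyper$N
  n <- S <- SS <- numeric(N)
  for (i in seq_len(N)) {
    oi <- o[q == i]
    n[i] <- length(oi); S[i] <- sum(oi); SS[i] <- sum(oi^2)
  }
  draw_emission_params(n, S, SS, hyper, variances)
}

draw_transitions <- function(trans_counts, init_counts, hyper) {
  N <- hyper$N
  A <- t(vapply(seq_len(N), function(i)
    rdirichlet1(hyper$dirichlet_A[i, ] + trans_counts[i, ]), numeric(N)))
  pi <- rdirichlet1(hyper$dirichlet_pi + init_counts)
  list(A = A, pi = pi)
}

count_path_transitions <- function(paths, N) {
  trans <- matrix(0, N, N)
  init <- numeric(N)
  for (q in paths) {
    init[q[1]] <- init[q[1]] + 1
    if (length(q) > 1) {
      from <- q[-length(q)]; to <- q[-1]
      for (k in seq_along(from))
        trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
    }
  }
  list(trans = trans, init = init)
}

#' Draw the transition matrix and initial distribution
#'
#' Pools transition counts over chromosomes -- cross-chromosome junctions are
#' never counted -- and draws each row of A from its Dirichlet posterior.
#' The initial-distribution posterior receives one first-state count per
#' chromosome (the forward recursion restarts at `pi` on each chromosome).
#'
#' @param paths List of integer state paths, one per chromosome (a single
#'   vector is treated as one chromosome).
#' @param hyper An `hmm_hyperparameters`.
#' @return List with `A` and `pi`.
#' @export
sample_transition_rows <- function(paths, hyper) {
  if (!is.list(paths)) paths <- list(paths)
  cnt <- count_path_transitions(paths, hyper$N)
  draw_transitions(cnt$trans, cnt$init, hyper)
}

#' Sample a state path exactly from its posterior
#'
#' Forward-backward sampling: computes scaled forward variables, draws the
#' final state proportional to `P(q_T, O | theta)`, then walks backward
#' drawing `q_t` proportional to `P(q_t, O_1..t | theta) * a_{q_t, q_{t+1}}`.
#' The result is an exact draw from `P(Q | O, theta)`.
#'
#' @inheritParams forward
#' @return Integer vector of 1-based states.
#' @export
sample_state_path <- function(hmm, obs) {
  check_obs(obs)
  f <- forward(hmm, obs)
  sample_path_cpp(f$alpha, hmm$A)
}

#' Initial HMM parameters from the priors
#'
#' `"mean"` (the default used by the samplers) initializes every parameter
#' at its prior expectation: means at `mu_mean`, variances at the prior
#' mean of `sigma^2` (`prec_rate / (prec_shape - 1)`, or
#' `prec_rate / prec_shape` for shapes at or below 1), and Dirichlet rows
#' at their normalized weights.  Deterministic and data-independent.
#' `"draw"` samples every parameter from its prior instead; with diffuse
#' priors such starts can land chains in a poorly-mixing merged-state mode,
#' which is why it is not the default.
#'
#' @param hyper An `hmm_hyperparameters`.
#' @param method `"mean"` or `"draw"`.
#' @return A `gaussian_hmm`.
#' @export
initial_parameters <- function(hyper, method = c("mean", "draw")) {
  method <- match.arg(method)
  N <- hyper$N
  if (method == "mean") {
    mu <- if (hyper$order_means) sort(hyper$mu_mean) else hyper$mu_mean
    v <- ifelse(hyper$prec_shape > 1,
                hyper$prec_rate / (hyper$prec_shape - 1),
                hyper$prec_rate / hyper$prec_shape)
    A <- hyper$dirichlet_A / rowSums(hyper$dirichlet_A)
    pi <- hyper$dirichlet_pi / sum(hyper$dirichlet_pi)
    return(gaussian_hmm(A, pi, mu, v, ordered = hyper$order_means))
  }
  draw_mu <- function() stats::rnorm(N, hyper$mu_mean, sqrt(hyper$mu_var))
  mu <- if (hyper$order_means) enforce_mean_ordering(draw_mu)$means else draw_mu()
  prec <- stats::rgamma(N, hyper$prec_shape, hyper$prec_rate)
  tr <- draw_transitions(matrix(0, N, N), numeric(N), hyper)
  gaussian_hmm(tr$A, tr$pi, mu, 1 / prec, ordered = hyper$order_means)
}

# ---------------------------------------------------------------------------
# Chain engine.  Both the exact and the approximate sampler run through this
# block-level engine; exact FBG is the special case of all-singleton blocks,
# for which the block forward recursion *is* the standard forward recursion
# and the block statistics are the raw sufficient statistics.

block_emission_matrix <- function(blocks, means, variances) {
  n <- blocks$count
  vapply(seq_along(means), function(i) {
    -(n / 2) * log(2 * pi * variances[i]) -
      (blocks$sum2 - 2 * means[i] * blocks$sum1 + n * means[i]^2) /
        (2 * variances[i])
  }, numeric(length(n)))
}

run_chain_engine <- function(blocks_list, track, hmm0, hyper, M,
                             posterior_window, model_kind, width_used,
                             keep_paths = FALSE) {
  stopifnot(M >= 1)
  N <- hyper$N
  theta <- if (is.null(hmm0)) initial_parameters(hyper) else hmm0
  stopifnot(theta$N == N)
  draws <- vector("list", M)
  paths_kept <- if (keep_paths) vector("list", M) else NULL
  ordering_fallbacks <- 0L
  ops <- 0
  for (m in seq_len(M)) {
    # 1. sample one state per block, per chromosome
    states <- vector("list", length(blocks_list))
    for (ci in seq_along(blocks_list)) {
      b <- blocks_list[[ci]]
      E <- matrix(block_emission_matrix(b, theta$means, theta$variances),
                  nrow = length(b$count))
      f <- fwd_block_cpp(theta$A, theta$pi, E, as.integer(b$count))
      ops <- ops + f$ops
      states[[ci]] <- sample_path_cpp(f$alpha, theta$A)
    }
    # 2. block sufficient statistics
    n <- S <- SS <- numeric(N)
    trans <- matrix(0, N, N)
    init <- numeric(N)
    for (ci in seq_along(blocks_list)) {
      b <- blocks_list[[ci]]
      q <- states[[ci]]
      for (i in seq_len(N)) {
        sel <- q == i
        n[i] <- n[i] + sum(b$count[sel])
        S[i] <- S[i] + sum(b$sum1[sel])
        SS[i] <- SS[i] + sum(b$sum2[sel])
        # (count - 1) self-transitions inside every block of that state
        trans[i, i] <- trans[i, i] + sum(b$count[sel] - 1L)
      }
      if (length(q) > 1) {
        from <- q[-length(q)]; to <- q[-1]
        for (k in seq_along(from))
          trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
      }
      init[q[1]] <- init[q[1]] + 1
    }
    # 3. parameter draws: mu -> sigma^2 -> A -> pi
    em <- draw_emission_params(n, S, SS, hyper, theta$variances)
    if (identical(em$ordering, "sort_fallback"))
      ordering_fallbacks <- ordering_fallbacks + 1L
    tr <- draw_transitions(trans, init, hyper)
    theta <- gaussian_hmm(tr$A, tr$pi, em$means, em$variances,
                          ordered = hyper$order_means)
    draws[[m]] <- theta
    if (keep_paths) paths_kept[[m]] <- states
  }
  window <- min(posterior_window, M)
  marg <- NULL
  if (!is.null(track)) {
    marg <- lapply(track$observations, function(o)
      matrix(0, length(o), N))
    for (m in (M - window + 1):M) {
      th <- draws[[m]]
      for (ci in seq_along(track$observations)) {
        marg[[ci]] <- marg[[ci]] +
          posterior_marginals(th, track$observations[[ci]])
      }
    }
    marg <- lapply(marg, function(g) g / window)
    names(marg) <- track$chromosomes
  }
  total_blocks <- sum(vapply(blocks_list, function(b) length(b$count), 0L))
  total_obs <- sum(vapply(blocks_list, function(b) sum(b$count), 0))
  structure(list(draws = draws, M = M, burnin = M - window,
                 posterior_window = window,
                 posterior_mean_marginals = marg,
                 model_kind = model_kind, width_used = width_used,
                 gamma = total_blocks / total_obs,
                 total_blocks = total_blocks, total_obs = total_obs,
                 ops_per_iteration = ops / M,
                 ordering_fallbacks = ordering_fallbacks,
                 block_paths = paths_kept),
            class = "fbg_chain")
}

#' @export
print.fbg_chain <- function(x, ...) {
  cat(sprintf("FBG chain (%s): M = %d draws, %d blocks / %d obs (gamma = %.3g)\n",
              x$model_kind, x$M, x$total_blocks, x$total_obs, x$gamma))
  if (!is.na(x$width_used)) cat(sprintf("  width w = %.4g\n", x$width_used))
  invisible(x)
}

#' Final parameter draw of a chain
#' @param chain An `fbg_chain`.
#' @return The `gaussian_hmm` of the last iteration.
#' @export
last_draw <- function(chain) chain$draws[[chain$M]]

singleton_blocks <- function(obs) {
  list(start = seq_along(obs), count = rep(1L, length(obs)),
       sum1 = as.numeric(obs), sum2 = as.numeric(obs)^2)
}

#' Exact forward-backward Gibbs sampling
#'
#' Alternates exact state-path draws (forward-backward sampling, per
#' chromosome, with parameters pooled across chromosomes) and conjugate
#' parameter draws for `M` iterations.  Internally this is the block-chain
#' engine run on all-singleton blocks, for which the block recursion reduces
#' exactly to the standard forward recursion.
#'
#' @param track An `observation_track`.
#' @param hyper An `hmm_hyperparameters`.
#' @param M Number of Gibbs iterations.
#' @param hmm0 Optional initial `gaussian_hmm`; defaults to a draw from the
#'   priors.
#' @param seed Optional integer seed; the whole chain is reproducible given
#'   it.
#' @param posterior_window Number of trailing draws over which per-probe
#'   posterior marginals are averaged (default 10).
#' @return An `fbg_chain` with elements `draws` (list of `gaussian_hmm`),
#'   `posterior_mean_marginals` (per-chromosome T x N matrices),
#'   `model_kind`, `gamma`, and bookkeeping fields.
#' @export
run_fbg <- function(track, hyper, M = 100, hmm0 = NULL, seed = NULL,
                    posterior_window = 10) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(track$observations, singleton_blocks)
  run_chain_engine(blocks, track, hmm0, hyper, M, posterior_window,
                   model_kind = "exact", width_used = NA_real_)
}
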