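#' Construct a Gaussian-emission hidden Markov model
#'
#' Bundles the full parameter set of an N-state HMM with univariate Gaussian
#' emissions: the transition matrix `A`, the initial distribution `pi`, and
#' per-state emission means and variances.
#'
#' @param A N x N row-stochastic transition matrix.
#' @param pi Length-N initial state distribution.
#' @param means Length-N emission means, in observation units (log2 ratios).
#' @param variances Length-N emission variances, strictly positive.
#' @param ordered If `TRUE`, require `means` to be non-decreasing (the
#'   label-switching constraint used for multi-state copy-number models).
#' @return An object of class `gaussian_hmm`.
#' @examples
#' gaussian_hmm(A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'              pi = c(0.5, 0.5), means = c(0, 1), variances = c(0.1, 0.1))
#' @export
gaussian_hmm <- function(A, pi, means, variances, ordered = FALSE) {
  A <- as.matrix(A)
  N <- length(means)
  stopifnot(N >= 1, nrow(A) == N, ncol(A) == N, length(pi) == N,
            length(variances) == N)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("rows of A must be nonnegative and sum to 1 (tolerance 1e-9)")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be nonnegative and sum to 1 (tolerance 1e-9)")
  if (any(variances <= 0))
    stop("all emission variances must be strictly positive")
  if (ordered && is.unsorted(means))
    stop("means must be non-decreasing when ordered = TRUE")
  structure(list(N = N, A = unname(A), pi = unname(as.numeric(pi)),
                 means = unname(as.numeric(means)),
                 variances = unname(as.numeric(variances)),
                 ordered = isTRUE(ordered)),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM with %d state(s)\n", x$N))
  cat("  means:     ", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  variances: ", paste(signif(x$variances, 4), collapse = ", "), "\n")
  cat("  A diag:    ", paste(signif(diag(x$A), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Construct an observation track
#'
#' An ordered set of per-chromosome real-valued observation sequences
#' (typically log2 ratios of probe intensities), with optional probe
#' positions.  The pooled standard deviation `sigma_D` of all observations is
#' cached; compression widths are conventionally expressed as multiples of it.
#'
#' @param values Numeric vector (single chromosome) or named list of numeric
#'   vectors, one per chromosome, in genome order.
#' @param positions Optional integer positions, same shape as `values`.
#' @return An object of class `observation_track` with elements
#'   `chromosomes`, `observations` (named list), `positions`, `sigma_D`.
#' @export
observation_track <- function(values, positions = NULL) {
  if (is.numeric(values)) values <- list(`1` = values)
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  if (!is.null(positions) && is.numeric(positions)) positions <- list(positions)
  lens <- lengths(values)
  if (any(lens < 1)) stop("every chromosome needs at least one observation")
  all_o <- unlist(values, use.names = FALSE)
  if (!all(is.finite(all_o))) stop("all observations must be finite")
  if (!is.null(positions) && !identical(unname(lengths(positions)), unname(lens)))
    stop("positions must match observations in shape")
  structure(list(chromosomes = names(values),
                 observations = lapply(values, as.numeric),
                 positions = positions,
                 sigma_D = stats::sd(all_o)),
            class = "observation_track")
}

#' @export
print.observation_track <- function(x, ...) {
  cat(sprintf("Observation track: %d chromosome(s), %d probes, sigma_D = %.4g\n",
              length(x$chromosomes), sum(lengths(x$observations)), x$sigma_D))
  invisible(x)
}

#' Total number of observations in a track
#' @param track An `observation_track`.
#' @return Integer probe count.
#' @export
track_length <- function(track) sum(lengths(track$observations))

#' Gaussian log-density of a single observation
#'
#' @param value Observation.
#' @param mean Emission mean.
#' @param variance Emission variance (> 0).
#' @return `log N(value; mean, variance)`.
#' @export
emission_logdensity <- function(value, mean, variance) {
  if (any(variance <= 0)) stop("variance must be strictly positive")
  -0.5 * log(2 * pi * variance) - (value - mean)^2 / (2 * variance)
}

check_obs <- function(obs) {
  if (length(obs) < 1) stop("observation sequence must be nonempty")
  invisible(obs)
}

#' Forward recursion and log-likelihood
#'
#' Runs the scaled forward algorithm.  Scaling (renormalizing each row of the
#' forward table and accumulating the log normalizers) makes the computation
#' immune to underflow for sequences of any practical length.
#'
#' @param hmm A `gaussian_hmm`.
#' @param obs Numeric observation vector.
#' @return List with `alpha` (T x N matrix, row t proportional to
#'   `P(q_t = i, O_1..t | theta)` and normalized to sum 1) and `loglik`
#'   (`log P(O | theta)`).
#' @export
forward <- function(hmm, obs) {
  check_obs(obs)
  fwd_raw_cpp(hmm$A, hmm$pi, hmm$means, hmm$variances, as.numeric(obs))
}

#' Sequence log-likelihood under an HMM
#' @inheritParams forward
#' @return `log P(O | theta)`.
#' @export
loglikelihood <- function(hmm, obs) forward(hmm, obs)$loglik

#' Most likely state path (Viterbi)
#'
#' Log-domain Viterbi decoding; ties are broken toward the lowest state
#' index so the result is deterministic.
#'
#' @inheritParams forward
#' @return Integer vector of 1-based state indices, length `length(obs)`.
#' @export
viterbi <- function(hmm, obs) {
  check_obs(obs)
  viterbi_raw_cpp(hmm$A, hmm$pi, hmm$means, hmm$variances, as.numeric(obs))
}

#' Per-position posterior state distributions
#'
#' Computes `P(q_t = i | O, theta)` by the scaled forward-backward
#' recursions.
#'
#' @inheritParams forward
#' @return T x N matrix; each row sums to 1.
#' @export
posterior_marginals <- function(hmm, obs) {
  check_obs(obs)
  obs <- as.numeric(obs)
  alpha <- fwd_raw_cpp(hmm$A, hmm$pi, hmm$means, hmm$variances, obs)$alpha
  beta <- bwd_raw_cpp(hmm$A, hmm$means, hmm$variances, obs)
  g <- alpha * beta
  g / rowSums(g)
}

#' Apply a per-sequence HMM operation across a track
#'
#' Convenience mapper: runs `fun(hmm, obs)` on every chromosome of a track.
#'
#' @param hmm A `gaussian_hmm`.
#' @param track An `observation_track`.
#' @param fun One of [forward()], [viterbi()], [posterior_marginals()], or any
#'   function with that signature.
#' @return Named list of per-chromosome results.
#' @export
track_apply <- function(hmm, track, fun) {
  lapply(track$observations, function(o) fun(hmm, o))
}
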