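# Generators for the self-contained benchmark experiments: sampling from a
# known HMM, and a CGH-like template with aberrant regions at fixed
# theoretical log-ratios plus Gaussian noise.

#' Sample an observation sequence from a Gaussian HMM
#'
#' @param hmm A `gaussian_hmm`.
#' @param T Sequence length.
#' @param seed Optional integer seed.
#' @return List with `track` (single-chromosome `observation_track`) and
#'   `path` (integer generating states).
#' @export
sample_hmm_sequence <- function(hmm, T, seed = NULL) {
  stopifnot(T >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- integer(T)
  q[1] <- sample.int(hmm$N, 1, prob = hmm$pi)
  for (t in seq_len(T)[-1])
    q[t] <- sample.int(hmm$N, 1, prob = hmm$A[q[t - 1], ])
  o <- stats::rnorm(T, hmm$means[q], sqrt(hmm$variances[q]))
  list(track = observation_track(o), path = q)
}

#' Specification of the CGH template simulator
#'
#' Defaults reproduce the standard benchmark template: three chromosomes of
#' 500, 750 and 1000 probes; 10 aberrant regions of 11-20 probes in the
#' small chromosome and 15 regions of 11-25 probes in each larger one, each
#' independently a gain or a loss with probability 1/2; theoretical
#' log-ratios -1 (loss), 0 (neutral), 0.58 (gain) with additive `N(0,
#' noise_sd)` noise.  The signal-to-noise ratio is `0.58 / noise_sd`.
#'
#' @param chrom_sizes Probe counts per chromosome.
#' @param n_regions Aberrant regions per chromosome.
#' @param region_size_min,region_size_max Per-chromosome probe-length
#'   bounds of a region.
#' @param levels Named theoretical log-ratios for loss, neutral, gain.
#' @param noise_sd Standard deviation of the additive noise, > 0.
#' @return An object of class `cgh_template_spec`.
#' @export
cgh_template_spec <- function(chrom_sizes = c(500, 750, 1000),
                              n_regions = c(10, 15, 15),
                              region_size_min = c(11, 11, 11),
                              region_size_max = c(20, 25, 25),
                              levels = c(loss = -1, neutral = 0, gain = 0.58),
                              noise_sd = 0.2) {
  stopifnot(length(n_regions) == length(chrom_sizes),
            length(region_size_min) == length(chrom_sizes),
            length(region_size_max) == length(chrom_sizes),
            all(region_size_min <= region_size_max),
            noise_sd > 0,
            all(c("loss", "neutral", "gain") %in% names(levels)))
  structure(list(chrom_sizes = chrom_sizes, n_regions = n_regions,
                 region_size_min = region_size_min,
                 region_size_max = region_size_max,
                 levels = levels, noise_sd = noise_sd,
                 snr = unname(levels["gain"] / noise_sd)),
            class = "cgh_template_spec")
}

place_regions <- function(size, k, len_min, len_max, max_tries = 10000) {
  taken <- logical(size)
  out <- vector("list", k)
  for (r in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(len_min:len_max, 1)
      if (len > size) next
      s <- sample.int(size - len + 1, 1)
      if (!any(taken[s:(s + len - 1)])) {
        taken[s:(s + len - 1)] <- TRUE
        out[[r]] <- c(s, s + len - 1)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place non-overlapping aberrant regions")
  }
  out
}

#' Simulate a CGH-like probe track with known aberrations
#'
#' Places the specified number of non-overlapping aberrant regions uniformly
#' at random in each chromosome (rejection sampling with a retry cap), each
#' independently a gain or a loss with probability 1/2, sets the
#' theoretical level per probe and adds Gaussian noise.
#'
#' @param spec A [cgh_template_spec()].
#' @param seed Optional integer seed.
#' @return List with `track` (`observation_track`) and `labels`
#'   (per-chromosome character vectors in loss/neutral/gain).
#' @export
simulate_cgh_template <- function(spec = cgh_template_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  values <- labels <- vector("list", length(spec$chrom_sizes))
  for (ci in seq_along(spec$chrom_sizes)) {
    size <- spec$chrom_sizes[ci]
    lab <- rep("neutral", size)
    regions <- place_regions(size, spec$n_regions[ci],
                             spec$region_size_min[ci],
                             spec$region_size_max[ci])
    for (reg in regions) {
      cls <- if (stats::runif(1) < 0.5) "gain" else "loss"
      lab[reg[1]:reg[2]] <- cls
    }
    mu <- unname(spec$levels[lab])
    values[[ci]] <- mu + stats::rnorm(size, 0, spec$noise_sd)
    labels[[ci]] <- lab
  }
  names(values) <- names(labels) <- paste0("chr", seq_along(values))
  list(track = observation_track(values), labels = labels)
}

#' Model and hyperparameter presets
#'
#' Returns the model configurations used in the standard experiments:
#' \describe{
#'   \item{`two_state`}{The 2-state benchmark HMM (`A` diagonal 0.9, means
#'     0 and 1, variances 0.1, uniform start) with its informative
#'     conjugate priors.}
#'   \item{`cgh4_template`}{4-state arrayCGH model (loss, neutral, single
#'     gain, multiple gain) with the template-simulation priors and the
#'     mean-ordering constraint.}
#'   \item{`cgh4_hbl2`}{The 4-state variant tuned for a noisy annotated
#'     cell-line profile (tighter prior variances, heavier precision
#'     shapes).}
#'   \item{`gbm3`}{3-state model with non-informative, data-scale-dependent
#'     priors; because the prior means and precision shapes scale with the
#'     pooled standard deviation, `hyper` is returned as a function of
#'     `sigma_D`.}
#'   \item{`snp3`}{3-state SNP-array model with strong self-transition
#'     Dirichlet priors (total weight l = 5000 per row, diagonal fraction
#'     0.99 for the neutral state and 0.95 otherwise).}
#' }
#'
#' @param name One of `"two_state"`, `"cgh4_template"`, `"cgh4_hbl2"`,
#'   `"gbm3"`, `"snp3"`.
#' @return List with `n_states`, `hmm` (a `gaussian_hmm` for `two_state`,
#'   otherwise `NULL`), and `hyper` (an `hmm_hyperparameters`, or a
#'   function of `sigma_D` for `gbm3`).
#' @export
preset <- function(name = c("two_state", "cgh4_template", "cgh4_hbl2",
                            "gbm3", "snp3")) {
  name <- match.arg(name)
  switch(name,
    two_state = list(
      n_states = 2L,
      hmm = gaussian_hmm(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                         pi = c(0.5, 0.5), means = c(0, 1),
                         variances = c(0.1, 0.1)),
      hyper = hyperparameters(mu_mean = c(0, 1), mu_var = c(0.5, 0.5),
                              prec_shape = c(4, 4), prec_rate = c(1, 1),
                              order_means = TRUE)),
    cgh4_template = list(
      n_states = 4L,
      hmm = NULL,
      hyper = hyperparameters(mu_mean = c(-0.5, 0, 0.58, 1),
                              mu_var = c(0.5, 0.001, 1.0, 1.0),
                              prec_shape = c(10, 100, 5, 5),
                              prec_rate = rep(1, 4),
                              order_means = TRUE)),
    cgh4_hbl2 = list(
      n_states = 4L,
      hmm = NULL,
      hyper = hyperparameters(mu_mean = c(-0.5, 0, 0.58, 1),
                              mu_var = c(0.2, 0.1, 0.2, 0.2),
                              prec_shape = c(15, 20, 10, 10),
                              prec_rate = rep(1, 4),
                              order_means = TRUE)),
    gbm3 = list(
      n_states = 3L,
      hmm = NULL,
      hyper = function(sigma_D) {
        hyperparameters(mu_mean = c(-sigma_D / 2, 0, sigma_D / 2),
                        mu_var = c(0.2, 0.1, 0.2),
                        prec_shape = rep(1 / sigma_D^2, 3),
                        prec_rate = rep(1, 3),
                        dirichlet_pi = c(1, 9, 1),
                        order_means = TRUE)
      }),
    snp3 = {
      l <- 5000
      a_diag <- c(0.95, 0.99, 0.95)
      dirA <- t(vapply(1:3, function(i) {
        row <- rep((1 - a_diag[i]) / 2, 3)
        row[i] <- a_diag[i]
        l * row
      }, numeric(3)))
      list(
        n_states = 3L,
        hmm = NULL,
        hyper = hyperparameters(mu_mean = c(-0.66, 0, 0.54),
                                mu_var = rep(0.001, 3),
                                prec_shape = c(12, 30, 25),
                                prec_rate = rep(1, 3),
                                dirichlet_A = dirA,
                                dirichlet_pi = c(1, 9, 1),
                                order_means = TRUE))
    })
}
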