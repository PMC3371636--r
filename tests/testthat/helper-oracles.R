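# Brute-force oracles: explicit enumeration over all N^T state paths.
# Deliberately structured nothing like the package recursions.

enum_paths <- function(N, T) {
  as.matrix(expand.grid(rep(list(seq_len(N)), T)))
}

# log P(Q, O | theta) for one explicit path
enum_path_logprob <- function(hmm, obs, q) {
  lp <- log(hmm$pi[q[1]]) +
    dnorm(obs[1], hmm$means[q[1]], sqrt(hmm$variances[q[1]]), log = TRUE)
  if (length(obs) > 1) {
    for (t in 2:length(obs)) {
      lp <- lp + log(hmm$A[q[t - 1], q[t]]) +
        dnorm(obs[t], hmm$means[q[t]], sqrt(hmm$variances[q[t]]), log = TRUE)
    }
  }
  lp
}

enum_all_logprobs <- function(hmm, obs) {
  paths <- enum_paths(hmm$N, length(obs))
  lp <- apply(paths, 1, function(q) enum_path_logprob(hmm, obs, q))
  list(paths = paths, logprobs = lp)
}

enum_loglik <- function(hmm, obs) {
  lp <- enum_all_logprobs(hmm, obs)$logprobs
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

enum_viterbi <- function(hmm, obs) {
  e <- enum_all_logprobs(hmm, obs)
  e$paths[which.max(e$logprobs), ]
}

enum_posteriors <- function(hmm, obs) {
  e <- enum_all_logprobs(hmm, obs)
  w <- exp(e$logprobs - max(e$logprobs))
  w <- w / sum(w)
  T <- length(obs)
  g <- matrix(0, T, hmm$N)
  for (t in seq_len(T)) for (i in seq_len(hmm$N))
    g[t, i] <- sum(w[e$paths[, t] == i])
  g
}

# exact posterior path distribution P(Q | O, theta) as a named vector
enum_path_posterior <- function(hmm, obs) {
  e <- enum_all_logprobs(hmm, obs)
  w <- exp(e$logprobs - max(e$logprobs))
  w <- w / sum(w)
  names(w) <- apply(e$paths, 1, paste, collapse = "")
  w
}

random_hmm <- function(N, spread = 2) {
  A <- matrix(rgamma(N * N, 1), N)
  A <- A / rowSums(A)
  pi <- rgamma(N, 1); pi <- pi / sum(pi)
  gaussian_hmm(A, pi, means = sort(runif(N, -spread, spread)),
               variances = runif(N, 0.05, 0.5))
}

relerr <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

two_state_toy <- function() {
  gaussian_hmm(matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE),
               c(0.6, 0.4), c(-0.5, 0.8), c(0.3, 0.2))
}
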