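test_that("block emission likelihood equals the uncompressed product", {
  set.seed(10)
  for (rep in 1:20) {
    o <- rnorm(sample(1:30, 1), runif(1, -1, 1), 0.5)
    b <- list(count = length(o), sum1 = sum(o), sum2 = sum(o^2))
    mu <- runif(1, -1, 1); v <- runif(1, 0.05, 1)
    direct <- sum(emission_logdensity(o, mu, v))
    expect_lt(relerr(block_emission_loglik(b, mu, v), direct), 1e-9)
  }
  # singleton block reduces to the plain log-density
  b1 <- list(count = 1, sum1 = 0.4, sum2 = 0.16)
  expect_equal(block_emission_loglik(b1, 0.1, 0.2),
               emission_logdensity(0.4, 0.1, 0.2))
  # centered block: cross term vanishes
  o <- c(-1, 0, 1) + 2
  bc <- list(count = 3, sum1 = sum(o), sum2 = sum(o^2))
  expect_equal(block_emission_loglik(bc, 2, 0.5),
               -(3 / 2) * log(2 * pi * 0.5) - (sum(o^2) - 3 * 4) / (2 * 0.5))
  expect_error(block_emission_loglik(b1, 0, 0), "positive")
})

test_that("block forward on singletons equals the raw forward recursion", {
  set.seed(20)
  for (rep in 1:100) {
    N <- sample(2:3, 1)
    hmm <- random_hmm(N)
    o <- rnorm(sample(5:50, 1), 0, 1)
    bf <- block_forward(hmm, kdFBG:::singleton_blocks(o))
    expect_lt(relerr(bf$loglik, loglikelihood(hmm, o)), 1e-9)
  }
})

test_that("block forward matches restricted path enumeration", {
  # two blocks, two states: only the four block-constant path families count
  hmm <- two_state_toy()
  o1 <- c(0.1, -0.3, 0.2); o2 <- c(0.9, 1.1)
  blocks <- list(count = c(3L, 2L),
                 sum1 = c(sum(o1), sum(o2)), sum2 = c(sum(o1^2), sum(o2^2)))
  direct <- 0
  for (i in 1:2) for (j in 1:2) {
    q <- c(rep(i, 3), rep(j, 2))
    direct <- direct + exp(enum_path_logprob(hmm, c(o1, o2), q))
  }
  expect_lt(relerr(block_forward(hmm, blocks)$loglik, log(direct)), 1e-9)
  # one state, one block: pi = 1, a11 = 1 -> just the block emission
  one <- gaussian_hmm(matrix(1), 1, 0.2, 0.3)
  bl <- list(count = 4L, sum1 = 1, sum2 = 2)
  expect_equal(block_forward(one, bl)$loglik,
               block_emission_loglik(bl, 0.2, 0.3))
})

test_that("block path sampling matches the exact sampler on singletons", {
  set.seed(30)
  hmm <- two_state_toy()
  obs <- c(-0.2, 0.5, 0.1)
  truth <- enum_path_posterior(hmm, obs)
  blocks <- kdFBG:::singleton_blocks(obs)
  ndraw <- 20000
  draws <- replicate(ndraw,
    paste(sample_block_path(hmm, blocks), collapse = ""))
  freq <- table(factor(draws, levels = names(truth))) / ndraw
  se <- sqrt(truth * (1 - truth) / ndraw)
  expect_true(all(abs(freq - truth) <= 3 * se + 1e-12))
})

test_that("single-block sampling follows pi * a^(n-1) * emission", {
  set.seed(31)
  hmm <- two_state_toy()
  o <- rnorm(4, 0.5, 0.4)
  bl <- list(count = 4L, sum1 = sum(o), sum2 = sum(o^2))
  wts <- hmm$pi * diag(hmm$A)^3 *
    exp(block_emission_loglik(bl, hmm$means, hmm$variances))
  pr <- wts / sum(wts)
  draws <- replicate(20000, sample_block_path(hmm, bl, expand = FALSE))
  f1 <- mean(draws == 1)
  expect_lt(abs(f1 - pr[1]), 3 * sqrt(pr[1] * (1 - pr[1]) / 20000))
  # expansion assigns the block state to every observation
  expect_length(sample_block_path(hmm, bl), 4)
  # deterministic chain
  det <- gaussian_hmm(diag(2), c(1, 0), c(0, 1), c(0.1, 0.1))
  expect_equal(sample_block_path(det, kdFBG:::singleton_blocks(rnorm(5))),
               rep(1, 5))
})

test_that("block parameter updates use the stated sufficient statistics", {
  hyper <- hyperparameters(mu_mean = c(0, 1), mu_var = c(0.5, 0.5),
                           prec_shape = c(4, 4), prec_rate = c(1, 1))
  # blocks sized (3, 2) with states (1, 2): transitions 1->1 twice (inside
  # the first block), 1->2 once (between blocks), 2->2 once
  o <- c(0.1, -0.1, 0.2, 1.1, 0.9)
  blocks <- list(count = c(3L, 2L), sum1 = c(sum(o[1:3]), sum(o[4:5])),
                 sum2 = c(sum(o[1:3]^2), sum(o[4:5]^2)))
  set.seed(55)
  th <- block_parameter_update(list(blocks), list(c(1L, 2L)), hyper,
                               c(0.1, 0.1))
  # manual draw with hand-counted statistics and the same RNG stream
  set.seed(55)
  em <- kdFBG:::draw_emission_params(n = c(3, 2), S = c(sum(o[1:3]), sum(o[4:5])),
                                     SS = c(sum(o[1:3]^2), sum(o[4:5]^2)),
                                     hyper, c(0.1, 0.1))
  tr <- kdFBG:::draw_transitions(matrix(c(2, 1, 0, 1), 2, byrow = TRUE),
                                 c(1, 0), hyper)
  expect_identical(th$means, em$means)
  expect_identical(th$variances, em$variances)
  expect_identical(th$A, tr$A)
  expect_identical(th$pi, tr$pi)
  # all-singleton blocks give exactly the raw-path statistics
  set.seed(56)
  th1 <- block_parameter_update(list(kdFBG:::singleton_blocks(o)),
                                list(c(1L, 1L, 1L, 2L, 2L)), hyper,
                                c(0.1, 0.1))
  set.seed(56)
  em1 <- sample_emission_parameters(o, c(1, 1, 1, 2, 2), hyper, c(0.1, 0.1))
  tr1 <- sample_transition_rows(list(c(1, 1, 1, 2, 2)), hyper)
  expect_identical(th1$means, em1$means)
  expect_identical(th1$A, tr1$A)
})

test_that("zero width reproduces the exact chain bit for bit", {
  p <- preset("two_state")
  sim <- sample_hmm_sequence(p$hmm, 300, seed = 60)
  exact <- run_fbg(sim$track, p$hyper, M = 8, seed = 61)
  approx <- run_approx_fbg(sim$track, p$hyper, w = 0, M = 8, seed = 61)
  expect_identical(exact$draws, approx$draws)
  expect_equal(approx$gamma, 1)
})

test_that("automatic width selection runs and is recorded", {
  p <- preset("two_state")
  sim <- sample_hmm_sequence(p$hmm, 800, seed = 70)
  ch <- run_approx_fbg(sim$track, p$hyper, w = "auto", M = 5, seed = 71)
  expect_true(is.finite(ch$width_used) && ch$width_used > 0)
  expect_lt(ch$gamma, 1)
  expect_equal(ch$model_kind, "approximate")
})

test_that("per-iteration work scales with the number of blocks", {
  p <- preset("two_state")
  sim <- sample_hmm_sequence(p$hmm, 5000, seed = 80)
  ops <- sapply(c(0, 0.5, 1.5) * sim$track$sigma_D, function(w) {
    ch <- run_approx_fbg(sim$track, p$hyper, w = w, M = 3, seed = 81)
    c(ch$ops_per_iteration, ch$total_blocks)
  })
  # measured multiply-adds per iteration, relative to block count
  per_block <- ops[1, ] / ops[2, ]
  expect_lt(max(per_block) / min(per_block), 1.2)
})

test_that("the weak-path bound evaluates correctly in closed form", {
  # the worked setting: t = 0.9, d = 1, sigma^2 = 0.1, tau = 0.25, n = 10
  val <- lemma1_bound(t = 0.9, d = 1, sigma2 = 0.1, tau = 0.25, alpha = 1,
                      n = 10, N = 2)
  r <- 1 / 9; cc <- exp(-1.25)
  expect_equal(val, (1 + r * cc)^9 + cc^10 * (1 + r)^9, tolerance = 1e-12)
  expect_equal(val, 1.3259, tolerance = 1e-4)  # epsilon about 1/3
  # n = 1: only the second term differs from alpha
  expect_equal(lemma1_bound(0.9, 1, 0.1, 0.5, 1, n = 1, N = 3),
               1 + 2 * exp(-0.5 / 0.2)^(2 / 3))
  # tau -> infinity: bound approaches alpha
  expect_equal(lemma1_bound(0.9, 1, 0.1, 1e6, 1.5, n = 5, N = 2), 1.5,
               tolerance = 1e-9)
  expect_error(lemma1_bound(0.9, 1, 0.1, -0.1, 1, 5, 2), "tau")
})

test_that("the bound dominates the enumerated ratio whenever tau >= 0", {
  set.seed(90)
  for (rep in 1:100) {
    N <- sample(2:3, 1)
    n <- sample(1:8, 1)
    t <- runif(1, 0.6, 0.95)
    sigma2 <- runif(1, 0.05, 0.3)
    gap <- runif(1, 0.8, 2)
    means <- seq(0, by = gap, length.out = N)
    sx <- sample(N, 1)
    # decision region of sx, shrunk by a target margin
    lo <- if (sx == 1) -Inf else (means[sx - 1] + means[sx]) / 2
    hi <- if (sx == N) Inf else (means[sx] + means[sx + 1]) / 2
    margin <- runif(1, 0, gap / 4)
    obs <- runif(n, max(lo + margin, means[sx] - gap),
                 min(hi - margin, means[sx] + gap))
    tau <- min(min(obs) - lo, hi - max(obs))
    rho <- rgamma(N, 1); rho <- rho / sum(rho)
    alpha <- max(rho) / rho[sx]
    ratio <- weak_path_ratio_oracle(means, sigma2, t, rho, obs)
    bound <- lemma1_bound(t, gap, sigma2, tau, alpha, n, N)
    expect_gte(ratio, 1)
    expect_lte(ratio, bound * (1 + 1e-9))
  }
})

test_that("the oracle hits its analytic corner cases", {
  # n = 1: every path is constant
  expect_equal(weak_path_ratio_oracle(c(0, 1), 0.1, 0.9, c(0.5, 0.5), 0.2), 1)
  # a block far from all non-dominant means: weak paths vanish
  r <- weak_path_ratio_oracle(c(0, 50), 0.1, 0.9, c(0.99, 0.01),
                              rnorm(5, 0, 0.1))
  expect_lt(r - 1, 1e-6)
  expect_error(weak_path_ratio_oracle(c(0, 1, 2), 0.1, 0.9,
                                      rep(1 / 3, 3), rnorm(20)), "too large")
})
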