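test_that("full posterior equals the naive per-sample product of densities", {
  set.seed(6)
  y1 <- rnorm(10)
  y2 <- rnorm(10, sd = 1.3)
  l <- segment_stats(y1); r <- segment_stats(y2)
  beta <- 0.7
  for (s in c(0.5, 1, 2)) for (d in c(0.4, 1, 3)) {
    naive <- sum(dnorm(y1, 0, s, log = TRUE)) +
      sum(dnorm(y2, 0, sqrt(d) * s, log = TRUE)) +
      (-log(beta) - abs(d - 1) / beta) +   # Laplace(1, beta) prior on delta
      (-log(s))                            # Jeffreys prior on sigma0
    expect_equal(log_full_posterior(s, d, l, r, beta), naive,
                 tolerance = 1e-12)
  }
})

test_that("at delta = 1 the posterior reduces to the pooled-variance density", {
  l <- list(n = 7, ss = 5.5); r <- list(n = 9, ss = 11.2)
  beta <- 2
  s <- 1.3
  pooled <- -0.5 * 16 * log(2 * pi * s^2) - (5.5 + 11.2) / (2 * s^2) -
    log(s) - log(beta)
  expect_equal(log_full_posterior(s, 1, l, r, beta), pooled,
               tolerance = 1e-12)
  # symmetry under swapping equally sized segments at delta = 1
  a <- list(n = 5, ss = 3.1); b <- list(n = 5, ss = 8.4)
  expect_equal(log_full_posterior(1.7, 1, a, b, beta),
               log_full_posterior(1.7, 1, b, a, beta))
})

test_that("H0 supremum matches a 1-D numerical maximization oracle", {
  set.seed(7)
  for (i in 1:100) {
    l <- list(n = sample(2:5000, 1), ss = runif(1, 0.1, 5000))
    r <- list(n = sample(2:5000, 1), ss = runif(1, 0.1, 5000))
    beta <- runif(1, 0.01, 2)
    s0 <- sup_h0(l, r, beta)
    s_bar <- sqrt((l$ss + r$ss) / (l$n + r$n))
    opt <- optimize(function(u) log_full_posterior(exp(u), 1, l, r, beta),
                    log(s_bar) + c(log(1e-3), log(1e3)),
                    maximum = TRUE, tol = 1e-12)
    expect_lt(abs(s0$logdens - opt$objective), 1e-8)
  }
})

test_that("H0 supremum obeys exact scale equivariance and the spot formula", {
  l <- list(n = 1, ss = 1); r <- list(n = 1, ss = 1)
  expect_equal(sup_h0(l, r, 1)$sigma0, sqrt(2 / 3))

  a <- list(n = 40, ss = 37); b <- list(n = 60, ss = 81)
  s1 <- sup_h0(a, b, 0.5)
  cc <- 3.7
  s2 <- sup_h0(list(n = 40, ss = 37 * cc^2), list(n = 60, ss = 81 * cc^2), 0.5)
  expect_equal(s2$sigma0, s1$sigma0 * cc, tolerance = 1e-12)
  expect_equal(s2$logdens, s1$logdens - (40 + 60 + 1) * log(cc),
               tolerance = 1e-10)
})

test_that("MH draws stay positive and reproduce the posterior mean of delta", {
  set.seed(8)
  y1 <- rnorm(5000); y2 <- rnorm(5000, sd = sqrt(2))
  l <- segment_stats(y1); r <- segment_stats(y2)
  d <- mh_sample(l, r, beta = 1, seed = 5)
  expect_true(all(d$sigma0 > 0))
  expect_true(all(d$delta > 0))
  expect_gt(mean(d$delta), 1.8)
  expect_lt(mean(d$delta), 2.2)
  # against the quadrature oracle
  qm <- quad_delta_mean(l$n, l$ss, r$n, r$ss, beta = 1)
  expect_lt(abs(mean(d$delta) - qm) / qm, 0.05)
})

test_that("delta draws match the quadrature marginal CDF in Kolmogorov distance", {
  set.seed(12)
  a <- rnorm(500); b <- rnorm(500, sd = sqrt(1.5))
  l <- segment_stats(a); r <- segment_stats(b)
  cdf <- quad_delta_cdf(l$n, l$ss, r$n, r$ss, beta = 1)
  d <- mh_sample(l, r, beta = 1, n_samples = 2e5, n_burn = 10000, seed = 6)
  xs <- sort(d$delta)
  ks <- max(abs(seq_along(xs) / length(xs) - cdf(xs)))
  expect_lt(ks, 0.05)
})

test_that("the e-value is a probability and is exactly scale invariant", {
  set.seed(9)
  y1 <- rnorm(800); y2 <- rnorm(800, sd = 1.4)
  l <- segment_stats(y1); r <- segment_stats(y2)
  e1 <- fbst_evidence(l, r, beta = 1, n_samples = 3000, n_burn = 3000,
                      seed = 11)
  expect_gte(e1$ev_h0, 0)
  expect_lte(e1$ev_h0, 1)
  # same seed, both segments scaled: the whole chain scales with the data,
  # so the e-value is identical, not merely close
  cc <- 9
  e2 <- fbst_evidence(list(n = l$n, ss = l$ss * cc^2),
                      list(n = r$n, ss = r$ss * cc^2),
                      beta = 1, n_samples = 3000, n_burn = 3000, seed = 11)
  expect_equal(e1$ev_h0, e2$ev_h0)
})

test_that("e-value agrees with the quadrature oracle on a reference problem", {
  set.seed(10)
  a <- rnorm(1000); b <- rnorm(1000, sd = 1.2)
  l <- segment_stats(a); r <- segment_stats(b)
  res <- fbst_evidence(l, r, beta = 1, seed = 13)
  qev <- quad_ev_h0(l$n, l$ss, r$n, r$ss, 1, res$sup_h0_logdens)
  expect_lt(abs(res$ev_h0 - qev), 0.05)
})

test_that("degenerate segments are rejected", {
  expect_error(fbst_evidence(list(n = 10, ss = 0), list(n = 10, ss = 1), 1),
               "degenerate")
  expect_error(sup_h0(list(n = 10, ss = 0), list(n = 10, ss = 0), 1),
               "degenerate")
  expect_error(log_full_posterior(-1, 1, list(n = 1, ss = 1),
                                  list(n = 1, ss = 1), 1), "positive")
})
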