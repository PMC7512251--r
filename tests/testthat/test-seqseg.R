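test_that("signals shorter than nmin are returned whole", {
  set.seed(20)
  res <- seqseg(rnorm(50), nmin = 100, seed = 1)
  expect_equal(res$changepoints, numeric(0))
  expect_equal(nrow(res$segments), 1)
  expect_equal(res$segments$start, 1)
  expect_equal(res$segments$end, 50)
})

test_that("segments always tile the signal exactly", {
  specs <- list(
    piecewise_spec(boundaries = numeric(0), sigmas = 1, n = 1500),
    piecewise_spec(700, c(1, 3), n = 1400),
    piecewise_spec(c(800, 1600, 2400), c(1, 2, 0.5, 1.5), n = 3000),
    piecewise_spec(c(2000, 5000), c(1, 2, 1), n = 8000)
  )
  for (i in seq_along(specs)) {
    sig <- simulate_piecewise(specs[[i]], seed = 30 + i)
    res <- seqseg(sig, beta = 1, alpha = 0.05, nmin = 300,
                  n_samples = 2000, n_burn = 2000, seed = 40 + i)
    segs <- res$segments
    expect_equal(segs$start[1], 1)
    expect_equal(segs$end[nrow(segs)], specs[[i]]$n)
    if (nrow(segs) > 1) {
      expect_equal(segs$start[-1], head(segs$end, -1) + 1)
    }
    expect_equal(nrow(segs), length(res$changepoints) + 1)
    expect_true(all(diff(res$changepoints) > 0))
  }
})

test_that("a fixed master seed makes the whole recursion reproducible", {
  sig <- simulate_piecewise(piecewise_spec(1000, c(1, 2), n = 2500), seed = 50)
  a <- seqseg(sig, beta = 1, alpha = 0.01, nmin = 400,
              n_samples = 2000, n_burn = 2000, seed = 99)
  b <- seqseg(sig, beta = 1, alpha = 0.01, nmin = 400,
              n_samples = 2000, n_burn = 2000, seed = 99)
  expect_identical(a$changepoints, b$changepoints)
  expect_identical(a$evidences, b$evidences)
})

test_that("the changepoint set is exactly invariant under amplitude scaling", {
  sig <- simulate_piecewise(piecewise_spec(c(1200, 2400), c(1, 2.5, 1),
                                           n = 3600), seed = 60)
  a <- seqseg(sig$samples, beta = 1, alpha = 0.01, nmin = 400,
              n_samples = 2000, n_burn = 2000, seed = 7)
  b <- seqseg(sig$samples * 37, beta = 1, alpha = 0.01, nmin = 400,
              n_samples = 2000, n_burn = 2000, seed = 7)
  expect_identical(a$changepoints, b$changepoints)
})

test_that("variance_equal_test agrees with its own e-value and with truth", {
  set.seed(70)
  # equal variances: should not reject
  stops <- vapply(1:10, function(s) {
    set.seed(500 + s)
    out <- variance_equal_test(rnorm(2000), rnorm(2000), beta = 1,
                               alpha = 0.01, n_samples = 4000,
                               n_burn = 4000, seed = s)
    expect_equal(out$reject_h0, out$fbst$ev_h0 < 0.01)
    !out$reject_h0
  }, logical(1))
  expect_gte(mean(stops), 0.9)
  # a fourfold variance change: should reject
  splits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    out <- variance_equal_test(rnorm(1000), rnorm(1000, sd = 2), beta = 1,
                               alpha = 0.01, n_samples = 4000,
                               n_burn = 4000, seed = s)
    out$reject_h0
  }, logical(1))
  expect_gte(mean(splits), 0.9)
  # degenerate half: judged equal, flagged
  out <- variance_equal_test(numeric(100), rnorm(100), beta = 1)
  expect_false(out$reject_h0)
  expect_true(out$fbst$degenerate)
})

test_that("strong variance changes are localized within 300 samples", {
  # the two large-ratio changes of the benchmark profile
  hits12 <- 0; hits15 <- 0; n_seeds <- 10
  for (s in 1:n_seeds) {
    sig <- benchmark_signal(700 + s)
    res <- seqseg(sig, beta = 1, alpha = 0.01, nmin = 1000, seed = 800 + s)
    cp <- res$changepoints
    if (length(cp) && min(abs(cp - 12000)) <= 300) hits12 <- hits12 + 1
    if (length(cp) && min(abs(cp - 15000)) <= 300) hits15 <- hits15 + 1
  }
  expect_gte(hits12 / n_seeds, 0.8)
  expect_gte(hits15 / n_seeds, 0.8)
})

test_that("stationary noise is rarely segmented at audio-scale priors", {
  falses <- vapply(1:10, function(s) {
    sig <- simulate_piecewise(
      piecewise_spec(boundaries = numeric(0), sigmas = 1, n = 20000),
      seed = 1000 + s)
    res <- seqseg(sig, beta = 3e-5, alpha = 0.01, nmin = 1000,
                  seed = 1100 + s)
    length(res$changepoints) == 0
  }, logical(1))
  expect_gte(mean(falses), 0.9)
})

test_that("smaller alpha never yields more changepoints (fixed seeds)", {
  ok <- vapply(1:6, function(s) {
    sig <- benchmark_signal(1200 + s)
    lo <- seqseg(sig, beta = 1, alpha = 0.01, nmin = 1000, seed = 1300 + s)
    hi <- seqseg(sig, beta = 1, alpha = 0.1, nmin = 1000, seed = 1300 + s)
    length(lo$changepoints) <= length(hi$changepoints)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("an all-zero signal yields no changepoints", {
  res <- seqseg(numeric(5000), beta = 1, nmin = 1000, seed = 1)
  expect_equal(res$changepoints, numeric(0))
  expect_equal(res$n_tests, 0L)
})

test_that("results serialize to JSON and CSV with a config echo", {
  sig <- simulate_piecewise(piecewise_spec(1000, c(1, 2), n = 2000), seed = 2)
  res <- seqseg(sig, beta = 1, alpha = 0.01, nmin = 400,
                n_samples = 2000, n_burn = 2000, seed = 3)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_segmentation(res, jp, cp)
  rec <- jsonlite::read_json(jp)
  expect_equal(rec$config$beta, 1)
  expect_equal(rec$config$seed, 3)
  expect_equal(unlist(rec$changepoint_index), res$changepoints)
  tab <- read.csv(cp)
  expect_equal(tab$changepoint_index, res$changepoints)
})
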