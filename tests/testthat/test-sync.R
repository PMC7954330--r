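test_that("FFT cross-correlation matches the direct-sum oracle to 1e-10", {
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(2000)
    y <- 0.4 * x + rnorm(2000)
    cc <- cross_correlation(x, y, 1000, 0.1)
    expect_lt(max(abs(cc$ccf - bf_ccf(x, y, 1000, 0.1))), 1e-10)
  }
})

test_that("autocorrelation at zero lag is exactly one", {
  set.seed(2)
  x <- cumsum(rnorm(4000))
  cc <- cross_correlation(x, x, 1000, 0.2)
  expect_equal(cc$ccf[cc$lags == 0], 1, tolerance = 1e-9)
})

test_that("a delayed copy peaks at a positive lag equal to the delay", {
  set.seed(3)
  fs <- 1000
  x <- as.numeric(stats::filter(rnorm(6000), rep(1, 20) / 20, sides = 2))
  x[is.na(x)] <- 0
  d <- 10L   # samples = 10 ms
  y <- c(rep(0, d), x[seq_len(length(x) - d)])
  cc <- cross_correlation(x, y, fs, 0.1)
  expect_equal(cc$lags[which.max(cc$ccf)], d / fs, tolerance = 1e-9)
})

test_that("cross-correlation rejects constant and mismatched inputs", {
  expect_error(cross_correlation(rep(1, 1000), rnorm(1000), 1000, 0.1),
               "constant")
  expect_error(cross_correlation(rnorm(1000), rnorm(999), 1000, 0.1),
               "equal length")
  expect_error(cross_correlation(rnorm(100), rnorm(100), 1000, 0.1),
               "twice the maximum lag")
})

test_that("ccf is invariant to positive rescaling of either channel", {
  set.seed(4)
  x <- rnorm(3000); y <- rnorm(3000) + 0.3 * x
  a <- cross_correlation(x, y, 1000, 0.1)$ccf
  b <- cross_correlation(17.3 * x, y, 1000, 0.1)$ccf
  c3 <- cross_correlation(x, y * 0.002, 1000, 0.1)$ccf
  expect_lt(max(abs(a - b)), 1e-9)
  expect_lt(max(abs(a - c3)), 1e-9)
})

test_that("lowess smoothing reproduces lines and constants, damps spikes", {
  lags <- seq(-1, 1, by = 0.001)
  line <- 0.2 + 0.1 * lags
  expect_equal(lowess_smooth(lags, line, 0.02), line, tolerance = 1e-8)
  const <- rep(0.3, length(lags))
  expect_equal(lowess_smooth(lags, const, 0.02), const, tolerance = 1e-10)
  spike <- numeric(length(lags)); spike[1001] <- 1
  sm <- lowess_smooth(lags, spike, 0.012)   # window covers ~24 points
  expect_lt(max(sm), 0.5)
  expect_error(lowess_smooth(lags, spike, 0.0005), "minimum usable span")
})

test_that("identical channels score 1 at zero lag", {
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(400 * 500), rep(1, 25) / 25, sides = 2))
  x[is.na(x)] <- 0
  rec <- structure(list(sampling_rate = 500, duration = 400, ca3 = x,
                        ca1 = x, condition = "test", seed = 5,
                        metadata = list()),
                   class = "recording")
  res <- sync_score(rec, sync_params(analysis_rate = 500))
  expect_equal(res$score, 1, tolerance = 1e-6)
  expect_identical(res$score_lag, 0)
})

test_that("deterministically coupled channels score above 0.9", {
  spec <- perfect_coupling_spec()
  scores <- vapply(1:10, function(s) {
    r <- simulate_recording(spec, 320, seed = s, sampling_rate = 500)
    sync_score(r$recording, sync_params(analysis_rate = 500),
               window = c(10, 310))$score
  }, numeric(1))
  expect_gt(mean(scores), 0.9)
})

test_that("independent popspike channels score below 0.15", {
  spec <- make_condition("low_ca")
  scores <- vapply(1:10, function(s) {
    r <- simulate_recording(spec, 600, seed = 100 + s, sampling_rate = 500)
    sync_score(r$recording, sync_params(analysis_rate = 500))$score
  }, numeric(1))
  expect_lt(max(scores), 0.15)
})

test_that("swapping channels mirrors the lag axis and keeps the score", {
  spec <- condition_spec("sym", coupling_delay = 0, coupling_jitter_sd = 0)
  r <- simulate_recording(spec, 320, seed = 42, sampling_rate = 500)$recording
  a <- sync_score(r, sync_params(analysis_rate = 500),
                  override_min_duration = TRUE)
  swapped <- r
  swapped$ca3 <- r$ca1; swapped$ca1 <- r$ca3
  b <- suppressWarnings(sync_score(swapped, sync_params(analysis_rate = 500),
                                   override_min_duration = TRUE))
  expect_equal(a$ccf, rev(b$ccf), tolerance = 1e-9)
  expect_equal(a$score, b$score, tolerance = 1e-6)
})

test_that("mean score decreases as coupling failure rises", {
  means <- vapply(c(0, 0.5, 1), function(fp) {
    spec <- condition_spec("mono", coupling_failure_prob = fp)
    mean(vapply(1:50, function(s) {
      r <- simulate_recording(spec, 310, seed = 1000 * fp + s,
                              sampling_rate = 500)
      suppressWarnings(sync_score(r$recording,
                                  sync_params(analysis_rate = 500),
                                  window = c(5, 310),
                                  override_min_duration = TRUE))$score
    }, numeric(1)))
  }, numeric(1))
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])
})

test_that("short recordings are refused unless overridden", {
  spec <- make_condition("low_ca")
  r <- simulate_recording(spec, 60, seed = 1, sampling_rate = 500)$recording
  expect_error(sync_score(r, sync_params(analysis_rate = 500)),
               "shorter than the minimum")
  expect_warning(sync_score(r, sync_params(analysis_rate = 500),
                            override_min_duration = TRUE),
                 "shorter than the minimum")
})

test_that("population mean score under defaults sits in the reported band", {
  spec <- make_condition("synaptic_blockers")
  scores <- vapply(1:25, function(s) {
    r <- simulate_recording(spec, 600, seed = 7000 + s, sampling_rate = 1000)
    sync_score(r$recording)$score
  }, numeric(1))
  expect_gt(mean(scores), 0.47 - 0.17)
  expect_lt(mean(scores), 0.47 + 0.17)
})
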