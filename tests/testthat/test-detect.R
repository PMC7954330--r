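test_that("featureless traces yield an empty event table", {
  set.seed(1)
  fs <- 500
  empty <- detect_events(rnorm(20 * fs, sd = 0.05), fs)
  expect_s3_class(empty, "event_table")
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(detect_events(rep(0, 20 * fs), fs)), 0L)
  expect_error(detect_events(rnorm(5 * fs), fs), "10 s")
})

test_that("embedded templates are recovered with exact counts and onsets", {
  fs <- 1000
  x <- numeric(60 * fs)
  onsets <- c(10, 25, 40)
  durs <- c(0.8, 1.1, 1.4)
  amps <- c(2, 3, 2.5)
  for (i in 1:3) {
    w <- fieldsync:::event_waveform(durs[i], amps[i], 0.36, fs)
    idx <- onsets[i] * fs + seq_along(w)
    x[idx] <- x[idx] + w
  }
  set.seed(5)
  x <- x + rnorm(length(x), sd = 0.003)
  det <- detect_events(x, fs, detection_params(min_threshold_mv = 0.72))
  dd <- det[det$kind == "discharge", ]
  expect_identical(nrow(dd), 3L)
  expect_lt(max(abs(dd$onset_s - onsets)), 0.02)
  expect_lt(max(abs((dd$offset_s - dd$onset_s) - durs)), 0.03)
  expect_equal(dd$peak_mv, amps, tolerance = 0.02)
})

test_that("detection recovers generator events at default SNR (F1 >= 0.95)", {
  spec <- make_condition("synaptic_blockers")
  f1 <- vapply(1:10, function(s) {
    r <- simulate_recording(spec, 600, seed = 300 + s, sampling_rate = 1000)
    det <- detect_events(r$recording$ca3, 1000)
    tr <- r$truth$events
    tr3 <- tr[tr$channel == "CA3" & tr$kind == "discharge", ]
    dd <- det[det$kind == "discharge", ]
    m <- match_events(tr3, dd)
    tp <- sum(!is.na(m))
    2 * tp / (2 * tp + (nrow(dd) - tp) + sum(is.na(m)))
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})

test_that("scaling the trace scales every detected amplitude", {
  spec <- make_condition("synaptic_blockers")
  r <- simulate_recording(spec, 120, seed = 9, sampling_rate = 1000)
  x <- r$recording$ca3
  a <- detect_events(x, 1000)
  b <- detect_events(3 * x, 1000)
  expect_identical(nrow(a), nrow(b))
  expect_equal(b$peak_mv, 3 * a$peak_mv, tolerance = 1e-9)
})

test_that("detect -> reconstruct -> detect is stable (idempotence)", {
  spec <- make_condition("synaptic_blockers")
  r <- simulate_recording(spec, 180, seed = 13, sampling_rate = 1000)
  det1 <- detect_events(r$recording$ca3, 1000)
  dd <- det1[det1$kind == "discharge", ]
  x <- numeric(length(r$recording$ca3))
  for (i in seq_len(nrow(dd))) {
    w <- fieldsync:::event_waveform(dd$offset_s[i] - dd$onset_s[i],
                                    dd$peak_mv[i], 0.36, 1000)
    i0 <- floor(dd$onset_s[i] * 1000) + 1L
    idx <- i0:min(i0 + length(w) - 1L, length(x))
    x[idx] <- x[idx] + w[seq_along(idx)]
  }
  det2 <- detect_events(x, 1000,
                        detection_params(min_threshold_mv = 0.72))
  d2 <- det2[det2$kind == "discharge", ]
  expect_identical(nrow(d2), nrow(dd))
  m <- match_events(dd, d2, tol = 0.2)
  expect_false(anyNA(m))
  expect_lt(max(abs(d2$onset_s[m] - dd$onset_s)), 0.05)
})

test_that("burst grouping matches the brute-force scan on random tables", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:100, 1)
    onsets <- sort(runif(n, 0, 400))
    dur <- pmin(runif(n, 0.3, 1.2), c(diff(onsets), Inf) - 0.05)
    keep <- dur > 0.25
    tab <- data.frame(channel = sample(c("CA3", "CA1"), sum(keep), TRUE),
                      onset_s = onsets[keep], offset_s = (onsets + dur)[keep],
                      peak_mv = runif(sum(keep), 1, 3),
                      kind = sample(c("discharge", "population_spike"),
                                    sum(keep), TRUE, prob = c(0.9, 0.1)),
                      burst_id = NA_integer_)
    tab <- as_event_table(tab)
    got <- group_bursts(tab)
    want <- bf_group_bursts(tab, 4, 4)
    # identical partition (ids may differ only by relabeling)
    expect_identical(is.na(got$burst_id), is.na(want$burst_id))
    expect_identical(as.integer(factor(got$burst_id)),
                     as.integer(factor(want$burst_id)))
  }
})

test_that("a regular 2-s train forms one burst at 0.5 Hz", {
  onsets <- seq(0, by = 2, length.out = 15)
  tab <- as_event_table(data.frame(
    channel = "CA3", onset_s = onsets, offset_s = onsets + 1,
    peak_mv = 2, kind = "discharge", burst_id = NA_integer_))
  g <- group_bursts(tab)
  expect_identical(length(unique(g$burst_id)), 1L)
  s <- summarize_events(g, 60)
  expect_identical(s$n_bursts, 1L)
  expect_equal(s$intraburst_frequency_mean, 0.5, tolerance = 1e-9)
  expect_equal(s$burst_duration_mean, 29, tolerance = 1e-9)  # 28 s + last event
})

test_that("isolated events are never grouped", {
  onsets <- seq(0, by = 10, length.out = 8)
  tab <- as_event_table(data.frame(
    channel = "CA3", onset_s = onsets, offset_s = onsets + 1,
    peak_mv = 2, kind = "discharge", burst_id = NA_integer_))
  expect_true(all(is.na(group_bursts(tab)$burst_id)))
})

test_that("detected burst count matches ground truth on a bursting slice", {
  spec <- condition_spec("b1", burst_probability = 1)
  for (s in c(2, 6)) {
    r <- simulate_recording(spec, 600, seed = s, sampling_rate = 1000)
    truth_b <- length(unique(na.omit(
      r$truth$events$burst_id[r$truth$events$channel == "CA3"])))
    det <- group_bursts(detect_events(r$recording$ca3, 1000))
    got_b <- length(unique(na.omit(det$burst_id)))
    expect_identical(got_b, truth_b)
  }
})

test_that("summaries compute the documented arithmetic", {
  tab <- as_event_table(data.frame(
    channel = "CA3", onset_s = c(5, 30), offset_s = c(6, 31.2),
    peak_mv = c(2, 3), kind = "discharge", burst_id = NA_integer_))
  s <- summarize_events(tab, 60)
  expect_equal(s$mean_duration, 1.1)
  expect_equal(s$rate, 2)
  expect_equal(s$mean_amplitude, 2.5)
  empty <- summarize_events(as_event_table(fieldsync:::empty_events()), 60)
  expect_identical(empty$n_events, 0L)
  expect_identical(empty$rate, 0)
  expect_error(summarize_events(tab, -1), "positive")
})
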