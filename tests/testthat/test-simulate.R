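test_that("identical (spec, duration, seed) give bit-identical recordings", {
  spec <- make_condition("synaptic_blockers")
  a <- simulate_recording(spec, 60, seed = 1, sampling_rate = 500)
  b <- simulate_recording(spec, 60, seed = 1, sampling_rate = 500)
  expect_identical(a$recording$ca3, b$recording$ca3)
  expect_identical(a$recording$ca1, b$recording$ca1)
  expect_identical(a$truth$events, b$truth$events)
  c3 <- simulate_recording(spec, 60, seed = 2, sampling_rate = 500)
  expect_false(identical(a$recording$ca3, c3$recording$ca3))
})

test_that("recording channels share length round(duration x rate) and are finite", {
  spec <- make_condition("synaptic_blockers")
  r <- simulate_recording(spec, 33.3, seed = 5, sampling_rate = 500)$recording
  expect_length(r$ca3, round(33.3 * 500))
  expect_length(r$ca1, length(r$ca3))
  expect_true(all(is.finite(r$ca3)) && all(is.finite(r$ca1)))
  expect_error(simulate_recording(spec, -5, seed = 1), "positive")
  expect_error(simulate_events(spec, 60), "seed")
})

test_that("renewal process hits the nominal event rate (Monte Carlo)", {
  spec <- condition_spec("nb", burst_probability = 0)
  counts <- vapply(1:200, function(s) {
    tr <- simulate_events(spec, 600, seed = s)
    sum(tr$events$channel == "CA3" & tr$events$kind == "discharge")
  }, numeric(1))
  expected <- 2.36 * 10
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("ground-truth statistics match the spec parameters (renewal calibration)", {
  spec <- make_condition("synaptic_blockers")
  pop <- simulate_population(spec, 200, 600, seed = 11, events_only = TRUE)
  durs <- c(); fs <- c(); bds <- c(); bursting <- 0
  for (tr in pop) {
    e <- tr$events
    s3 <- e[e$channel == "CA3" & e$kind == "discharge" & is.na(e$burst_id), ]
    durs <- c(durs, s3$offset_s - s3$onset_s)
    gt <- e[e$channel == "CA3" & !is.na(e$burst_id), ]
    if (nrow(gt)) {
      bursting <- bursting + 1
      for (b in unique(gt$burst_id)) {
        bb <- gt[gt$burst_id == b, ]
        bds <- c(bds, max(bb$offset_s) - min(bb$onset_s))
        fs <- c(fs, (nrow(bb) - 1) / (max(bb$onset_s) - min(bb$onset_s)))
      }
    }
  }
  expect_lt(abs(mean(durs) - 1.07), 3 * sd(durs) / sqrt(length(durs)))
  expect_lt(abs(mean(fs) - 0.52), 3 * sd(fs) / sqrt(length(fs)) + 0.01)
  expect_lt(abs(mean(bds) - 35.61), 3 * sd(bds) / sqrt(length(bds)) + 1)
  p <- bursting / 200
  expect_lt(abs(p - 0.48), 3 * sqrt(0.48 * 0.52 / 200))
})

test_that("mean CA1/CA3 event-count ratio decreases with coupling failure", {
  ratios <- vapply(c(0, 0.5, 1), function(fp) {
    spec <- condition_spec("cpl", coupling_failure_prob = fp,
                           popspike_rate_ca1 = 0)
    mean(vapply(1:50, function(s) {
      e <- simulate_events(spec, 600, seed = round(1e4 * fp) + s)$events
      sum(e$channel == "CA1") / max(1, sum(e$channel == "CA3" &
                                            e$kind == "discharge"))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(ratios[1], ratios[2])
  expect_gt(ratios[2], ratios[3])
  expect_lt(ratios[3], 0.02)
})

test_that("ground truth is conserved into the rendered trace via detection", {
  # every truth discharge appears exactly once in a near-noiseless render
  spec <- condition_spec("clean", noise_sd = 1e-4, wander_sd = 0,
                         popspike_rate_ca3 = 0, popspike_rate_ca1 = 0,
                         slice_amplitude_cv = 0)
  r <- simulate_recording(spec, 300, seed = 3, sampling_rate = 1000)
  det <- detect_events(r$recording$ca3, 1000,
                       detection_params(min_threshold_mv = 2 *
                                          spec$duration_ref_mv))
  tr <- r$truth$events
  tr3 <- tr[tr$channel == "CA3" & tr$kind == "discharge", ]
  dd <- det[det$kind == "discharge", ]
  m <- match_events(tr3, dd)
  expect_false(anyNA(m))
  expect_identical(length(unique(m)), nrow(tr3))
  expect_identical(nrow(dd), nrow(tr3))
  # durations recovered within a few samples in the noise-free limit
  expect_lt(max(abs((dd$offset_s[m] - dd$onset_s[m]) -
                      (tr3$offset_s - tr3$onset_s))), 0.02)
})

test_that("block model truncates discharges and records the onset", {
  spec <- make_condition("cd2_15uM")
  pop <- simulate_population(spec, 150, 600, seed = 17, events_only = TRUE)
  onsets <- vapply(pop, function(t) t$block_onset, numeric(1))
  expect_true(all(is.finite(onsets)))
  frac0 <- mean(onsets == 0)
  expect_lt(abs(frac0 - 10 / 22), 3 * sqrt(frac0 * (1 - frac0) / 150))
  for (tr in pop[1:20]) {
    disc <- tr$events[tr$events$kind == "discharge", ]
    if (nrow(disc)) expect_lt(max(disc$onset_s), tr$block_onset)
  }
  # immediate block means no discharges at all
  imm <- pop[onsets == 0][1:5]
  for (tr in imm)
    expect_identical(sum(tr$events$kind == "discharge"), 0L)
})

test_that("intracellular current scales linearly with driving force", {
  spec0 <- condition_spec("ipsc0", ipsc_noise_sd = 0)
  r <- simulate_recording(spec0, 120, seed = 23, sampling_rate = 1000)
  it70 <- simulate_intracellular(spec0, r$recording, r$truth, -70, seed = 1)
  it35 <- simulate_intracellular(spec0, r$recording, r$truth, -35, seed = 1)
  it0 <- simulate_intracellular(spec0, r$recording, r$truth, 0, seed = 1)
  expect_true(all(it0$current == 0))
  expect_true(all(it0$peak_pre_noise == 0))
  expect_equal(it35$current, it70$current / 2, tolerance = 1e-12)
  expect_equal(mean(abs(it35$peak_pre_noise)),
               mean(abs(it70$peak_pre_noise)) / 2, tolerance = 1e-12)
  # inward current at a negative holding potential
  expect_lt(min(it70$current), 0)
})

test_that("SLA presets produce regular trains at the nominal frequency", {
  spec <- make_condition("4ap")
  tr <- simulate_events(spec, 600, seed = 31)
  e3 <- tr$events[tr$events$channel == "CA3", ]
  gaps <- diff(e3$onset_s)
  expect_equal(1 / median(gaps), 0.36, tolerance = 0.03)
  expect_equal(stats::sd(gaps) / mean(gaps), 0.1, tolerance = 0.06)
})

test_that("population generation is reproducible with distinct slices", {
  spec <- make_condition("synaptic_blockers")
  p1 <- simulate_population(spec, 5, 60, seed = 7, events_only = TRUE)
  p2 <- simulate_population(spec, 5, 60, seed = 7, events_only = TRUE)
  for (i in 1:5) expect_identical(p1[[i]]$events, p2[[i]]$events)
  expect_false(identical(p1[[1]]$events, p1[[2]]$events))
  expect_error(simulate_population(spec, 0, 60, seed = 1), "n_slices")
})

test_that("mean-preserving truncated draws hit their targets", {
  set.seed(61)
  x <- fieldsync:::rtnorm_mean(5e4, 4.09, 2.60, 0)
  expect_true(all(x > 0))
  expect_equal(mean(x), 4.09, tolerance = 0.03)
  y <- fieldsync:::rtnorm_mean(5e4, 0.52, 0.28, 0.30)
  expect_true(all(y > 0.30))
  expect_equal(mean(y), 0.52, tolerance = 0.005)
})

test_that("event waveform width above the reference level equals the duration", {
  for (A in c(1.5, 2.5, 5)) for (D in c(0.5, 1.07, 1.8)) {
    w <- fieldsync:::event_waveform(D, A, 0.36, 2000)
    expect_equal(sum(abs(w) >= 0.36) / 2000, D, tolerance = 0.01)
    expect_equal(max(abs(w)), A, tolerance = 1e-4)
    expect_lte(max(w), 0)   # negative-going deflection
  }
})
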