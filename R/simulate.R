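# Synthetic paired CA3/CA1 field-potential generator with ground truth.
#
# A recording is an event train rendered through waveform templates plus a
# two-band noise model.  The event train is the scientific content: a
# renewal process of single discharges, a per-slice burst trait, CA3->CA1
# coupling with delay/jitter/failure, independent population spikes,
# regular SLA trains, and a latency-to-block drug model.

# ---- waveform templates -----------------------------------------------------

# Discharge template: sharp deflection built from a difference of two
# exponentials (rise time constant `tau_r`, decay solved per event).  The
# nominal event duration D is defined as the width of the waveform above
# the reference level `ref` (mV): the decay constant is solved so the
# template, scaled to peak amplitude A, crosses `ref` exactly at t = D.
# This makes the generator's duration convention commensurable with
# detection boundaries placed at a fixed crossing level.
discharge_tau <- function(D, A, ref, tau_r = 0.02) {
  if (A <= 1.2 * ref) A <- 1.2 * ref   # degenerate: keep template well-formed
  shape_at <- function(tau_d, t) {
    tpk <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
    gpk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
    (exp(-t / tau_d) - exp(-t / tau_r)) / gpk
  }
  f <- function(tau_d) A * shape_at(tau_d, D) - ref
  lo <- max(D / 40, 1.05 * tau_r)
  hi <- 20 * D
  if (f(lo) > 0) return(lo)
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9)$root
}

# Render one event template sampled at `fs`; returns the waveform from the
# event onset until it has decayed to ref/20 (support end).  Negative-going
# (extracellular field discharges deflect downward).
event_waveform <- function(D, A, ref, fs, tau_r = 0.02) {
  tau_d <- discharge_tau(D, A, ref, tau_r)
  tpk <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
  gpk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  t_end <- D + tau_d * log(20)
  t <- seq(0, t_end, by = 1 / fs)
  -A * (exp(-t / tau_d) - exp(-t / tau_r)) / gpk
}

# ---- event-train generation -------------------------------------------------

#' Simulate the ground-truth event train for one slice
#'
#' Generates the annotated event train (no trace rendering): background
#' single discharges from a refractory renewal process, bursts if the
#' slice carries the bursting trait, CA3→CA1 coupled copies, independent
#' population spikes, and the drug block. Cheap enough for Monte-Carlo
#' calibration checks over hundreds of seeds.
#'
#' @param spec a [condition_spec()].
#' @param duration recording length in seconds.
#' @param seed integer RNG seed (required for reproducibility).
#' @param slice_effect optional slice-level amplitude factor (shared by
#'   both channels); drawn from the spec's log-normal random effect when
#'   `NULL`.
#' @return A `ground_truth` object: `$events` (an `event_table`),
#'   `$bursting`, `$block_onset` (s; 0 = immediate, `NA` = no block),
#'   `$slice_effect`.
#' @export
simulate_events <- function(spec, duration, seed, slice_effect = NULL) {
  stopifnot(inherits(spec, "condition_spec"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation", call. = FALSE)
  with_seed(seed, {
    if (is.null(slice_effect))
      slice_effect <- rlnorm_ms(1, 1, spec$slice_amplitude_cv)

    block_onset <- NA_real_
    if (spec$has_block) {
      block_onset <- if (stats::runif(1) < spec$block_immediate_prob) 0
        else 60 * rtnorm_mean(1, spec$block_delay_mean, spec$block_delay_sd, 0)
    }

    ca3 <- empty_events()
    bursting <- FALSE
    if (spec$sla_frequency > 0) {
      ca3 <- gen_sla_train(spec, duration)
    } else if (spec$discharge_rate > 0) {
      bursting <- stats::runif(1) < spec$burst_probability
      bg <- gen_background(spec, duration)
      bu <- if (bursting) gen_bursts(spec, duration) else empty_events()
      if (nrow(bu)) {
        # background singles are suppressed around bursts
        keep <- rep(TRUE, nrow(bg))
        for (b in unique(bu$burst_id)) {
          lo <- min(bu$onset_s[bu$burst_id == b])
          hi <- max(bu$offset_s[bu$burst_id == b])
          # margin wide enough that no background single can be grouped
          # into the burst by the 4-s onset-gap convention
          keep <- keep & !(bg$onset_s > lo - 4.5 & bg$onset_s < hi + 4.5)
        }
        bg <- bg[keep, , drop = FALSE]
      }
      ca3 <- rbind(bg, bu)
      bursting <- bursting && nrow(bu) > 0
    }
    ca3$channel <- rep("CA3", nrow(ca3))

    ca1 <- couple_to_ca1(spec, ca3)

    # amplitude scaling: condition scale x slice random effect
    ca3$peak_mv <- ca3$peak_mv * spec$amplitude_scale_ca3 * slice_effect
    ca1$peak_mv <- ca1$peak_mv * spec$amplitude_scale_ca1 * slice_effect

    # drug block truncates discharges (population spikes persist)
    if (!is.na(block_onset)) {
      ca3 <- ca3[ca3$onset_s < block_onset, , drop = FALSE]
      ca1 <- ca1[ca1$onset_s < block_onset, , drop = FALSE]
    }

    ps3 <- gen_popspikes(spec, duration, spec$popspike_rate_ca3, "CA3",
                         ca3, slice_effect * spec$amplitude_scale_ca3)
    ps1 <- gen_popspikes(spec, duration, spec$popspike_rate_ca1, "CA1",
                         ca1, slice_effect * spec$amplitude_scale_ca1)

    ev <- rbind(ca3, ca1, ps3, ps1)
    ev <- ev[order(ev$channel, ev$onset_s), , drop = FALSE]
    rownames(ev) <- NULL
    structure(
      list(events = as_event_table(ev), bursting = bursting,
           block_onset = block_onset, slice_effect = slice_effect,
           duration = duration, condition = spec$name, seed = seed),
      class = "ground_truth")
  })
}

#' @noRd
empty_events <- function() {
  data.frame(channel = character(0), onset_s = numeric(0),
             offset_s = numeric(0), peak_mv = numeric(0),
             kind = character(0), burst_id = integer(0),
             stringsAsFactors = FALSE)
}

#' @noRd
make_events <- function(channel, onset, dur, amp, kind, burst_id = NA_integer_) {
  n <- length(onset)
  if (n == 0L) return(empty_events())
  data.frame(channel = rep(channel, n), onset_s = onset,
             offset_s = onset + dur, peak_mv = amp,
             kind = rep(kind, length.out = n),
             burst_id = rep(burst_id, length.out = n),
             stringsAsFactors = FALSE)
}

# background single discharges: exponential gaps above a refractory floor,
# mean gap set so the overall rate equals discharge_rate
#' @noRd
gen_background <- function(spec, duration) {
  mean_gap <- 60 / spec$discharge_rate
  exp_mean <- mean_gap - spec$discharge_refractory
  if (exp_mean <= 0)
    stop("discharge_rate incompatible with the refractory floor",
         call. = FALSE)
  onsets <- numeric(0)
  t <- stats::runif(1, 0, mean_gap)   # stationary-ish start
  while (t < duration - 0.5) {
    onsets <- c(onsets, t)
    t <- t + spec$discharge_refractory + stats::rexp(1, 1 / exp_mean)
  }
  n <- length(onsets)
  dur <- pmin(draw_durations(spec, n), spec$discharge_refractory - 0.1)
  amp <- draw_amp(n, spec$discharge_amplitude_mean_ca3,
                  spec$discharge_amplitude_sd_ca3,
                  spec$discharge_amplitude_min)
  make_events("CA3", onsets, dur, amp, "discharge")
}

#' @noRd
draw_durations <- function(spec, n) {
  rtnorm_mean(n, spec$discharge_duration_mean, spec$discharge_duration_sd,
              spec$discharge_duration_min)
}

#' @noRd
draw_amp <- function(n, mean, sd, minimum) {
  pmax(rlnorm_ms(n, mean, sd), minimum)
}

# bursts: Poisson-like onsets within a bursting slice; each burst is a
# large-amplitude leader followed by a train at the drawn intraburst
# frequency for the drawn burst duration
#' @noRd
gen_bursts <- function(spec, duration) {
  out <- list()
  id <- 0L
  rate <- spec$burst_rate / 60
  t <- stats::rexp(1, rate)
  while (t < duration - 10) {
    id <- id + 1L
    B <- rtnorm_mean(1, spec$burst_duration_mean, spec$burst_duration_sd,
                     spec$burst_duration_min)
    f <- rtnorm_mean(1, spec$intraburst_frequency_mean,
                     spec$intraburst_frequency_sd,
                     spec$intraburst_frequency_min)
    if (t + B > duration - 2) break   # only bursts that fit entirely
    K <- max(2L, round((B - spec$discharge_duration_mean) * f))
    onsets <- t + (0:K) / f
    n <- length(onsets)
    cap <- 1 / f - 0.35
    dur <- pmin(draw_durations(spec, n), cap)
    amp <- draw_amp(n, spec$discharge_amplitude_mean_ca3,
                    spec$discharge_amplitude_sd_ca3,
                    spec$discharge_amplitude_min)
    amp[1] <- amp[1] * spec$burst_leader_amplitude_factor
    out[[id]] <- make_events("CA3", onsets, dur, amp, "discharge", id)
    t <- max(onsets + dur) + 10 + stats::rexp(1, rate)
  }
  do.call(rbind, c(out, list(empty_events())))
}

# regular SLA train (bicuculline / 4-AP regimes)
#' @noRd
gen_sla_train <- function(spec, duration) {
  base <- 1 / spec$sla_frequency
  onsets <- numeric(0)
  t <- stats::runif(1, 0, base)
  while (t < duration - 1.5) {
    onsets <- c(onsets, t)
    gap <- base * (1 + stats::rnorm(1, 0, spec$sla_jitter_frac))
    t <- t + max(gap, 0.5 * base)
  }
  n <- length(onsets)
  cap <- base - 0.35
  dur <- pmin(rtnorm_mean(n, spec$sla_duration_mean, spec$sla_duration_sd,
                          0.25), cap)
  amp <- draw_amp(n, spec$discharge_amplitude_mean_ca3,
                  spec$discharge_amplitude_sd_ca3,
                  spec$discharge_amplitude_min)
  make_events("CA3", onsets, dur, amp, "discharge")
}

# CA3 -> CA1 coupling: each CA3 discharge is copied with probability
# 1 - coupling_failure_prob at lag coupling_delay + jitter; the CA1 copy
# keeps the source event's base amplitude rescaled to the CA1 channel mean
# and decorrelated by a per-event log-normal factor, with its own duration.
#' @noRd
couple_to_ca1 <- function(spec, ca3) {
  disc <- ca3[ca3$kind == "discharge", , drop = FALSE]
  if (!nrow(disc)) return(empty_events())
  keep <- stats::runif(nrow(disc)) >= spec$coupling_failure_prob
  disc <- disc[keep, , drop = FALSE]
  if (!nrow(disc)) return(empty_events())
  n <- nrow(disc)
  onset <- disc$onset_s + spec$coupling_delay +
    stats::rnorm(n, 0, spec$coupling_jitter_sd)
  ratio <- spec$discharge_amplitude_mean_ca1 / spec$discharge_amplitude_mean_ca3
  amp <- pmax(disc$peak_mv * ratio * rlnorm_ms(n, 1, spec$coupling_amplitude_cv),
              spec$discharge_amplitude_min * ratio)
  ord <- order(onset)
  onset <- onset[ord]; amp <- amp[ord]
  burst_id <- disc$burst_id[ord]
  # cap durations so consecutive CA1 copies never overlap
  next_gap <- c(diff(onset), Inf)
  dur <- pmin(draw_durations(spec, n)[ord], next_gap - 0.15)
  dur <- pmax(dur, 0.05)
  make_events("CA1", onset, dur, amp, "discharge", burst_id)
}

# independent population spikes; candidates colliding with existing
# same-channel events are rejected at emission
#' @noRd
gen_popspikes <- function(spec, duration, rate_per_min, channel, existing,
                          scale) {
  if (rate_per_min <= 0) return(empty_events())
  n <- stats::rpois(1, rate_per_min * duration / 60)
  if (n == 0L) return(empty_events())
  onsets <- sort(stats::runif(n, 0, duration - 0.2))
  amp <- draw_amp(n, spec$popspike_amplitude_mean, spec$popspike_amplitude_sd,
                  spec$popspike_amplitude_min) * scale
  ok <- rep(TRUE, n)
  if (nrow(existing)) {
    for (i in seq_len(n)) {
      ok[i] <- !any(onsets[i] < existing$offset_s + 0.3 &
                      onsets[i] + spec$popspike_duration >
                        existing$onset_s - 0.3)
    }
  }
  # reject collisions among the popspikes themselves
  if (any(ok)) {
    sel <- which(ok)
    last_end <- -Inf
    for (i in sel) {
      if (onsets[i] < last_end + 0.2) ok[i] <- FALSE
      else last_end <- onsets[i] + spec$popspike_duration
    }
  }
  make_events(channel, onsets[ok], spec$popspike_duration, amp[ok],
              "population_spike")
}

# ---- trace rendering --------------------------------------------------------

#' Simulate a paired CA3/CA1 field-potential recording
#'
#' Draws the ground-truth event train with [simulate_events()] and renders
#' it into voltage traces: each event contributes a negative-going
#' difference-of-exponentials deflection whose width above the spec's
#' reference level equals its nominal duration, on top of a two-band noise
#' floor (broadband Gaussian noise low-passed at `noise_cutoff`, plus a
#' slow per-channel baseline wander low-passed at `wander_cutoff`).
#' Identical `(spec, duration, seed)` give bit-identical output.
#'
#' @inheritParams simulate_events
#' @param sampling_rate sampling rate in Hz (default 10000, the raw
#'   acquisition rate; cohort analyses typically use 2000, ample for a
#'   <100 Hz signal band).
#' @return A list with elements `recording` (class `recording`) and
#'   `truth` (class `ground_truth`).
#' @examples
#' r <- simulate_recording(make_condition("synaptic_blockers"), 60, seed = 1,
#'                         sampling_rate = 1000)
#' r$recording
#' head(r$truth$events)
#' @export
simulate_recording <- function(spec, duration, seed, sampling_rate = 10000,
                               slice_effect = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (sampling_rate <= 4 * spec$noise_cutoff)
    stop("sampling_rate must exceed 4x the noise cutoff", call. = FALSE)
  truth <- simulate_events(spec, duration, seed, slice_effect)
  n <- round(duration * sampling_rate)
  ev <- truth$events
  with_seed(child_seed(seed, 7777L), {
    ca3 <- render_channel(ev[ev$channel == "CA3", , drop = FALSE], n,
                          sampling_rate, spec)
    ca1 <- render_channel(ev[ev$channel == "CA1", , drop = FALSE], n,
                          sampling_rate, spec)
    ca3 <- ca3 + gen_noise(n, sampling_rate, spec)
    ca1 <- ca1 + gen_noise(n, sampling_rate, spec)
  })
  rec <- structure(
    list(sampling_rate = sampling_rate, duration = duration,
         ca3 = ca3, ca1 = ca1, condition = spec$name, seed = seed,
         metadata = list(slice_effect = truth$slice_effect,
                         block_onset = truth$block_onset)),
    class = "recording")
  list(recording = rec, truth = truth)
}

#' @noRd
render_channel <- function(ev, n, fs, spec) {
  x <- numeric(n)
  if (!nrow(ev)) return(x)
  ref <- spec$duration_ref_mv
  for (i in seq_len(nrow(ev))) {
    D <- ev$offset_s[i] - ev$onset_s[i]
    w <- event_waveform(D, ev$peak_mv[i], ref, fs)
    i0 <- floor(ev$onset_s[i] * fs) + 1L
    idx <- i0:min(i0 + length(w) - 1L, n)
    if (i0 <= n) x[idx] <- x[idx] + w[seq_along(idx)]
  }
  x
}

# broadband floor + slow wander, each scaled to its exact target SD so the
# noise level is seed-independent
#' @noRd
gen_noise <- function(n, fs, spec) {
  out <- numeric(n)
  if (spec$noise_sd > 0) {
    z <- gaussian_lowpass(stats::rnorm(n), fs, spec$noise_cutoff)
    out <- out + z * (spec$noise_sd / stats::sd(z))
  }
  if (spec$wander_sd > 0) {
    wfs <- max(40 * spec$wander_cutoff, 20)
    nw <- max(ceiling(n / fs * wfs) + 2L, 64L)
    zw <- gaussian_lowpass(stats::rnorm(nw), wfs, spec$wander_cutoff)
    zw <- zw * (spec$wander_sd / stats::sd(zw))
    t_full <- (seq_len(n) - 1L) / fs
    out <- out + stats::approx(x = (seq_len(nw) - 1L) / wfs, y = zw,
                               xout = t_full, rule = 2)$y
  }
  out
}

#' Simulate an independent cohort of slices
#'
#' Child seeds are derived deterministically from `seed` via the
#' documented hash, so cohorts are reproducible and individual slices can
#' be regenerated in isolation.
#'
#' @inheritParams simulate_recording
#' @param n_slices number of independent slices (>= 1).
#' @param events_only if `TRUE`, skip trace rendering and return only
#'   ground truth (fast Monte-Carlo mode).
#' @return List of length `n_slices`; elements as in
#'   [simulate_recording()] (or `ground_truth` objects when
#'   `events_only = TRUE`).
#' @export
simulate_population <- function(spec, n_slices, duration, seed,
                                sampling_rate = 10000, events_only = FALSE) {
  if (!is.numeric(n_slices) || n_slices < 1)
    stop("n_slices must be >= 1", call. = FALSE)
  lapply(seq_len(n_slices), function(i) {
    s <- child_seed(seed, i)
    if (events_only) simulate_events(spec, duration, s)
    else simulate_recording(spec, duration, s, sampling_rate)
  })
}

# ---- intracellular channel --------------------------------------------------

#' Simulate the intracellular synaptic-current trace for a recording
#'
#' One synaptic current transient per CA1 ground-truth discharge: a
#' biexponential conductance time course with per-event peak conductance
#' drawn from the spec's log-normal (calibrated so the peak-current
#' distribution at a -70 mV holding potential has mean 51.60 pA), scaled
#' by the linear driving force `holding_potential - reversal_potential`.
#' Pre-noise, the peak current is exactly proportional to the driving
#' force and identically zero at the reversal potential.
#'
#' @param spec a [condition_spec()].
#' @param recording the companion [simulate_recording()] recording.
#' @param truth its ground truth.
#' @param holding_potential clamp potential, mV.
#' @param seed RNG seed.
#' @param reversal_potential reversal potential of the underlying
#'   conductance, mV (default 0, the nicotinic-response reversal).
#' @return An `intracellular_trace`: `$current` (pA), `$sampling_rate`,
#'   `$holding_potential`, `$reversal_potential`, `$peak_times` (s, one
#'   per CA1 discharge) and `$peak_pre_noise` (pA).
#' @export
simulate_intracellular <- function(spec, recording, truth,
                                   holding_potential = -70, seed,
                                   reversal_potential = 0) {
  stopifnot(inherits(recording, "recording"), inherits(truth, "ground_truth"))
  if (!is.finite(holding_potential))
    stop("holding_potential must be finite", call. = FALSE)
  fs <- recording$sampling_rate
  n <- length(recording$ca1)
  ev <- truth$events
  ev <- ev[ev$channel == "CA1" & ev$kind == "discharge", , drop = FALSE]
  drive <- holding_potential - reversal_potential   # mV; nS * mV = pA
  tau_r <- spec$ipsc_rise; tau_d <- spec$ipsc_decay
  tpk <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
  gpk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  t_w <- seq(0, tpk + 6 * tau_d, by = 1 / fs)
  shape <- (exp(-t_w / tau_d) - exp(-t_w / tau_r)) / gpk
  with_seed(seed, {
    g <- rlnorm_ms(max(nrow(ev), 1L), spec$ipsc_g_mean, spec$ipsc_g_sd)
    cur <- numeric(n)
    pk_t <- pk_v <- numeric(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[i] * fs) + 1L
      if (i0 > n) next
      idx <- i0:min(i0 + length(shape) - 1L, n)
      cur[idx] <- cur[idx] + g[i] * drive * shape[seq_along(idx)]
      pk_t[i] <- ev$onset_s[i] + tpk
      pk_v[i] <- g[i] * drive
    }
    if (spec$ipsc_noise_sd > 0) {
      z <- gaussian_lowpass(stats::rnorm(n), fs, min(300, fs / 4))
      cur <- cur + z * (spec$ipsc_noise_sd / stats::sd(z))
    }
  })
  structure(
    list(sampling_rate = fs, current = cur,
         holding_potential = holding_potential,
         reversal_potential = reversal_potential,
         peak_times = pk_t, peak_pre_noise = pk_v),
    class = "intracellular_trace")
}

#' Measure synaptic-current amplitudes at the known transient peaks
#'
#' Reads the (noisy) current trace at each transient's conductance-peak
#' time — the same event-locked measurement a patch-clamp analysis makes.
#' At the reversal potential the returned values scatter around zero.
#'
#' @param itrace an `intracellular_trace`.
#' @return Numeric vector of signed peak currents (pA).
#' @export
ipsc_peak_amplitudes <- function(itrace) {
  stopifnot(inherits(itrace, "intracellular_trace"))
  idx <- pmin(pmax(round(itrace$peak_times * itrace$sampling_rate) + 1L, 1L),
              length(itrace$current))
  itrace$current[idx]
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %.0f s at %g Hz (seed %d)\n",
              x$condition, x$duration, x$sampling_rate, x$seed))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<ground_truth> %s: %d events (%d CA3 / %d CA1)%s%s\n",
              x$condition, nrow(ev), sum(ev$channel == "CA3"),
              sum(ev$channel == "CA1"),
              if (isTRUE(x$bursting)) ", bursting slice" else "",
              if (!is.na(x$block_onset))
                sprintf(", block at %.1f s", x$block_onset) else ""))
  invisible(x)
}
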