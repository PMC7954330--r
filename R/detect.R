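# Event detection in single-channel field traces, burst grouping, and the
# summary statistics reported per condition.

#' Event table constructor / validator
#'
#' An `event_table` is a data.frame with columns `channel`, `onset_s`,
#' `offset_s`, `peak_mv`, `kind` (`discharge` or `population_spike`) and
#' `burst_id` (integer or `NA`), sorted by onset within channel, with no
#' overlapping events within a channel. The same schema is used for
#' ground truth and detections so the two can be diffed directly.
#'
#' @param df data.frame with the columns above.
#' @return The validated `event_table`.
#' @export
as_event_table <- function(df) {
  need <- c("channel", "onset_s", "offset_s", "peak_mv", "kind", "burst_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$channel, df$onset_s), need, drop = FALSE]
  rownames(df) <- NULL
  if (any(df$offset_s <= df$onset_s))
    stop("event onsets must precede offsets", call. = FALSE)
  if (any(df$peak_mv < 0))
    stop("peak amplitudes must be nonnegative", call. = FALSE)
  for (ch in unique(df$channel)) {
    o <- df[df$channel == ch, ]
    if (nrow(o) > 1L && any(o$onset_s[-1L] < o$offset_s[-nrow(o)] - 1e-9))
      stop("overlapping events within channel ", ch, call. = FALSE)
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Detection parameters
#'
#' @param threshold_k detection threshold in multiples of the robust
#'   (MAD-based) deviation of the baseline-subtracted trace.
#' @param min_threshold_mv absolute floor on the detection threshold
#'   (mV); keeps the threshold physiologically meaningful on very quiet
#'   recordings, where a MAD-only threshold would collapse to zero.
#' @param merge_gap supra-threshold excursions closer than this (s) are
#'   merged into one event.
#' @param min_duration events at least this long (s) are discharges.
#' @param popspike_max_duration events shorter than this (s) are
#'   population spikes; events shorter than 0.02 s are discarded as noise.
#' @param burst_min_events minimum run length for a burst.
#' @param burst_max_gap maximum onset-to-onset spacing (s) within a burst.
#' @param baseline_window running-median baseline window (s); must be
#'   long compared to a discharge burst, or the median dives toward the
#'   event level inside bursts and distorts the residual.
#' @return A `detection_params` object.
#' @export
detection_params <- function(threshold_k = 5, min_threshold_mv = 0.65,
                             merge_gap = 0.2, min_duration = 0.2,
                             popspike_max_duration = 0.1,
                             burst_min_events = 4, burst_max_gap = 4,
                             baseline_window = 90) {
  p <- list(threshold_k = threshold_k, min_threshold_mv = min_threshold_mv,
            merge_gap = merge_gap, min_duration = min_duration,
            popspike_max_duration = popspike_max_duration,
            burst_min_events = burst_min_events, burst_max_gap = burst_max_gap,
            baseline_window = baseline_window)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, TRUE)))
    stop("all detection parameters must be positive", call. = FALSE)
  if (popspike_max_duration >= min_duration)
    stop("popspike_max_duration must be below min_duration", call. = FALSE)
  structure(p, class = "detection_params")
}

# Running-median baseline evaluated on a coarse (20 Hz) grid and
# interpolated back to the full rate: the baseline is by construction
# slower than any event, so the coarse median is statistically identical
# to the full-rate running median at a fraction of the cost.
#' @noRd
running_baseline <- function(trace, sampling_rate, window_s) {
  n <- length(trace)
  step <- max(1L, as.integer(floor(sampling_rate / 20)))
  idx <- seq(1L, n, by = step)
  coarse <- trace[idx]
  k <- as.integer(round(window_s * sampling_rate / step))
  k <- min(k, length(coarse) - 1L)
  if (k %% 2L == 0L) k <- k + 1L
  if (k < 3L) return(rep(stats::median(trace), n))
  med <- stats::runmed(coarse, k, endrule = "median")
  if (step == 1L) return(med)
  stats::approx(x = idx, y = med, xout = seq_len(n), rule = 2)$y
}

#' Detect epileptiform events in a single-channel field trace
#'
#' Baseline is a running median (robust to dense bursting); the threshold
#' is `threshold_k` times the MAD-based deviation of the residual (with an
#' absolute floor); supra-threshold excursions of `|trace - baseline|` are
#' extended to their half-threshold crossings, merged across gaps shorter
#' than `merge_gap`, and classified by duration: under 0.02 s discarded,
#' under `popspike_max_duration` population spikes, otherwise discharges.
#'
#' @param trace numeric voltage trace (mV), at least 10 s long.
#' @param sampling_rate Hz.
#' @param params a [detection_params()].
#' @param channel label stored in the output table.
#' @return An [as_event_table()] of detections (`burst_id` all `NA`; see
#'   [group_bursts()]).
#' @export
detect_events <- function(trace, sampling_rate, params = detection_params(),
                          channel = "CA3") {
  n <- length(trace)
  if (n < 10 * sampling_rate)
    stop("trace must be at least 10 s long", call. = FALSE)
  if (stats::sd(trace) == 0) return(as_event_table(empty_events()))
  baseline <- running_baseline(trace, sampling_rate, params$baseline_window)
  resid <- trace - baseline
  d <- abs(resid)
  # discharge-free deviation estimate: the lower quartile of 10-s-chunk
  # MADs, so that even slices spending much of the record in bursts
  # contribute quiet segments; chunks are long enough to carry the full
  # slow-wander band, which is part of the background deviation
  nchunk <- max(1L, floor(n / (10 * sampling_rate)))
  chunk <- rep(seq_len(nchunk), each = ceiling(n / nchunk), length.out = n)
  sigma <- stats::quantile(vapply(split(resid, chunk), stats::mad, numeric(1)),
                           0.25, names = FALSE)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::mad(resid)
  thr <- max(params$threshold_k * sigma, params$min_threshold_mv)
  half <- thr / 2
  # boundary detection on a lightly smoothed envelope so that brief noise
  # excursions through the half-threshold do not truncate shallow decays;
  # peak amplitudes are read from the raw residual
  denv <- gaussian_lowpass(d, sampling_rate, min(40, sampling_rate / 4))
  r <- rle(denv >= half)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (!length(cand)) return(as_event_table(empty_events()))
  seg <- cbind(starts[cand], ends[cand])
  # merge half-threshold segments across short gaps, then keep merged
  # regions that reach the full threshold
  gap_samp <- params$merge_gap * sampling_rate
  merged <- list(seg[1, ])
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      last <- merged[[length(merged)]]
      if (seg[i, 1] - last[2] < gap_samp)
        merged[[length(merged)]] <- c(last[1], seg[i, 2])
      else merged[[length(merged) + 1L]] <- seg[i, ]
    }
  }
  m <- do.call(rbind, merged)
  reach <- vapply(seq_len(nrow(m)),
                  function(i) max(d[m[i, 1]:m[i, 2]]) >= thr, TRUE)
  m <- m[reach, , drop = FALSE]
  if (!nrow(m)) return(as_event_table(empty_events()))
  onset <- (m[, 1] - 1L) / sampling_rate
  offset <- (m[, 2] - 1L) / sampling_rate
  dur <- offset - onset
  peak <- vapply(seq_len(nrow(m)),
                 function(i) max(d[m[i, 1]:m[i, 2]]), numeric(1))
  keep <- dur >= 0.02
  kind <- ifelse(dur < params$popspike_max_duration,
                 "population_spike", "discharge")
  as_event_table(make_events(channel, onset[keep], dur[keep], peak[keep],
                             kind[keep]))
}

#' Group discharges into bursts
#'
#' Maximal runs of at least `burst_min_events` discharges whose
#' consecutive onsets are separated by less than `burst_max_gap` share a
#' `burst_id` (per channel). Population spikes are never burst members.
#'
#' @param table an [as_event_table()].
#' @param params a [detection_params()].
#' @return The table with `burst_id` filled in.
#' @export
group_bursts <- function(table, params = detection_params()) {
  stopifnot(inherits(table, "event_table"))
  if (!nrow(table)) return(table)
  table$burst_id <- NA_integer_
  next_id <- 1L
  for (ch in unique(table$channel)) {
    idx <- which(table$channel == ch & table$kind == "discharge")
    if (length(idx) < params$burst_min_events) next
    onsets <- table$onset_s[idx]
    new_run <- c(TRUE, diff(onsets) >= params$burst_max_gap)
    run_id <- cumsum(new_run)
    for (rid in unique(run_id)) {
      members <- idx[run_id == rid]
      if (length(members) >= params$burst_min_events) {
        table$burst_id[members] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  table
}

#' Summarize an event table the way condition results are reported
#'
#' Single-discharge statistics (duration, amplitude, rate) are computed
#' over discharges outside bursts; the rate is per minute of non-burst
#' time, since bursts occupy recording time during which background
#' singles cannot occur. Burst statistics: duration = last offset - first
#' onset; intraburst frequency = (n - 1) over the onset-to-onset span,
#' the unbiased train-rate estimator for a regular train. In SLA mode the
#' regular train frequency is estimated as the inverse of the median
#' inter-onset interval of all discharges (a mode-robust estimator for a
#' jittered regular train).
#'
#' @param table an [as_event_table()] (run [group_bursts()] first if burst
#'   statistics are wanted).
#' @param duration recording duration (s).
#' @param sla if `TRUE`, also estimate the regular-SLA train frequency.
#' @return An `event_summary` list; `n = 0` fields are zero/`NA` for an
#'   empty table.
#' @export
summarize_events <- function(table, duration, sla = FALSE) {
  stopifnot(inherits(table, "event_table"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  disc <- table[table$kind == "discharge", , drop = FALSE]
  singles <- disc[is.na(disc$burst_id), , drop = FALSE]
  ps <- table[table$kind == "population_spike", , drop = FALSE]

  bursts <- data.frame()
  if (any(!is.na(disc$burst_id))) {
    bursts <- do.call(rbind, lapply(split(disc[!is.na(disc$burst_id), ],
                                          disc$burst_id[!is.na(disc$burst_id)]),
      function(b) {
        dur <- max(b$offset_s) - min(b$onset_s)
        # train frequency from the onset span: unbiased for a regular train
        span <- max(b$onset_s) - min(b$onset_s)
        data.frame(n_events = nrow(b), duration = dur,
                   intraburst_frequency = if (span > 0)
                     (nrow(b) - 1) / span else NA_real_)
      }))
  }
  burst_time <- if (nrow(bursts)) sum(bursts$duration) else 0
  nonburst_min <- (duration - burst_time) / 60

  sdur <- singles$offset_s - singles$onset_s
  out <- list(
    n_events = nrow(disc),
    n_singles = nrow(singles),
    mean_duration = if (nrow(singles)) mean(sdur) else NA_real_,
    sd_duration = if (nrow(singles) > 1) stats::sd(sdur) else NA_real_,
    rate = if (nonburst_min > 0) nrow(singles) / nonburst_min else NA_real_,
    mean_amplitude = if (nrow(singles)) mean(singles$peak_mv) else NA_real_,
    sd_amplitude = if (nrow(singles) > 1) stats::sd(singles$peak_mv)
                   else NA_real_,
    n_bursts = nrow(bursts),
    burst_duration_mean = if (nrow(bursts)) mean(bursts$duration) else NA_real_,
    burst_duration_sd = if (nrow(bursts) > 1) stats::sd(bursts$duration)
                        else NA_real_,
    intraburst_frequency_mean = if (nrow(bursts))
      mean(bursts$intraburst_frequency) else NA_real_,
    intraburst_frequency_sd = if (nrow(bursts) > 1)
      stats::sd(bursts$intraburst_frequency) else NA_real_,
    n_popspikes = nrow(ps),
    popspike_rate = nrow(ps) / (duration / 60),
    sla_frequency = NA_real_,
    duration = duration
  )
  if (sla && nrow(disc) >= 3) {
    gaps <- diff(sort(disc$onset_s))
    out$sla_frequency <- 1 / stats::median(gaps)
  }
  structure(out, class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat("<event_summary>\n")
  cat(sprintf("  single discharges: n = %d, duration %s s, rate %.2f /min\n",
              x$n_singles, fmt_ms(x$mean_duration, x$sd_duration), x$rate))
  cat(sprintf("  amplitude %s mV\n", fmt_ms(x$mean_amplitude, x$sd_amplitude)))
  if (x$n_bursts > 0)
    cat(sprintf("  bursts: n = %d, duration %s s, intraburst %s Hz\n",
                x$n_bursts, fmt_ms(x$burst_duration_mean, x$burst_duration_sd),
                fmt_ms(x$intraburst_frequency_mean, x$intraburst_frequency_sd)))
  if (!is.na(x$sla_frequency))
    cat(sprintf("  SLA frequency %.3f Hz\n", x$sla_frequency))
  cat(sprintf("  population spikes: n = %d (%.2f /min)\n",
              x$n_popspikes, x$popspike_rate))
  invisible(x)
}
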