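# Cohort-level parameter recovery: run the full detection pipeline over a
# simulated population and pool the condition statistics the way they are
# reported (single-discharge duration and rate, burst duration, intraburst
# frequency, bursting fraction).

#' Detector-based recovery of condition statistics over a cohort
#'
#' Simulates `n_slices` independent slices, runs [detect_events()] and
#' [group_bursts()] on the CA3 channel of each, and pools the recovered
#' statistics. This is the calibration study that checks the generator
#' and detector against the condition parameters they encode.
#'
#' @param n_slices cohort size.
#' @param duration slice duration, s.
#' @param seed cohort seed.
#' @param condition preset name (default the spontaneous-discharge
#'   regime in synaptic blockers aCSF).
#' @param sampling_rate Hz.
#' @param detection a [detection_params()].
#' @param sla pass `TRUE` for regular-SLA conditions to recover the
#'   train frequency instead of burst statistics.
#' @return A list of pooled vectors: `single_durations` (s),
#'   `single_amplitudes` (mV), `rates` (per-slice, min⁻¹),
#'   `burst_durations` (s), `intraburst_frequencies` (Hz), `bursting`
#'   (per-slice logical), `sla_frequencies` (per-slice, Hz).
#' @export
cohort_recovery <- function(n_slices, duration, seed,
                            condition = "synaptic_blockers",
                            sampling_rate = 1000,
                            detection = detection_params(), sla = FALSE) {
  spec <- make_condition(condition)
  out <- list(single_durations = numeric(0), single_amplitudes = numeric(0),
              rates = numeric(0), burst_durations = numeric(0),
              intraburst_frequencies = numeric(0), bursting = logical(0),
              sla_frequencies = numeric(0))
  for (i in seq_len(n_slices)) {
    r <- simulate_recording(spec, duration, child_seed(seed, i),
                            sampling_rate)
    det <- group_bursts(detect_events(r$recording$ca3, sampling_rate,
                                      detection), detection)
    disc <- det[det$kind == "discharge", , drop = FALSE]
    singles <- disc[is.na(disc$burst_id), , drop = FALSE]
    out$single_durations <- c(out$single_durations,
                              singles$offset_s - singles$onset_s)
    out$single_amplitudes <- c(out$single_amplitudes, singles$peak_mv)
    sm <- summarize_events(det, duration, sla = sla)
    out$rates <- c(out$rates, sm$rate)
    out$bursting <- c(out$bursting, sm$n_bursts > 0)
    if (sm$n_bursts > 0) {
      bd <- disc[!is.na(disc$burst_id), , drop = FALSE]
      for (b in unique(bd$burst_id)) {
        bb <- bd[bd$burst_id == b, ]
        out$burst_durations <- c(out$burst_durations,
                                 max(bb$offset_s) - min(bb$onset_s))
        out$intraburst_frequencies <-
          c(out$intraburst_frequencies,
            (nrow(bb) - 1) / (max(bb$onset_s) - min(bb$onset_s)))
      }
    }
    if (sla && is.finite(sm$sla_frequency))
      out$sla_frequencies <- c(out$sla_frequencies, sm$sla_frequency)
  }
  out
}
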