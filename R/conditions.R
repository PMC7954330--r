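# Condition specifications: the generator parameter set for one
# pharmacological regime of the slice preparation.

#' Construct a condition specification
#'
#' A `condition_spec` bundles every parameter the synthetic recording
#' generator needs to emulate one experimental condition: the background
#' single-discharge renewal process, the burst model, CA3→CA1 coupling,
#' independent per-channel population spikes, the drug block model,
#' regular seizure-like activity (SLA), the two-band noise model, and the
#' intracellular (IPSC) current model.
#'
#' Rates are in events per minute, durations in seconds, amplitudes in mV,
#' block latencies in minutes, SLA frequency in Hz.
#'
#' @param name condition label.
#' @param ... parameter overrides; see [condition_defaults()] for the full
#'   set of field names and defaults.
#' @return An object of class `condition_spec` (a validated named list).
#' @seealso [make_condition()] for the documented presets.
#' @export
condition_spec <- function(name = "custom", ...) {
  spec <- utils::modifyList(condition_defaults(), list(...))
  unknown <- setdiff(names(list(...)), names(condition_defaults()))
  if (length(unknown))
    stop("unknown condition_spec fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec$name <- name
  validate_condition_spec(spec)
}

#' Default generator parameters
#'
#' The defaults describe the spontaneous-discharge regime in synaptic
#' blockers aCSF: ~1 s discharges at ~2.4 per minute, bursts in ~48% of
#' slices lasting ~36 s at ~0.5 Hz and led by a large-amplitude event,
#' near-reliable CA3→CA1 coupling at monosynaptic latency, sparse
#' CA1-dominant population spikes, and a two-band noise model (broadband
#' floor plus an uncorrelated slow wander per channel, the component that
#' sets the ceiling of the cross-correlation score).
#'
#' @return Named list of defaults.
#' @export
condition_defaults <- function() {
  list(
    name = "synaptic_blockers",
    # background single-discharge renewal process
    discharge_rate = 2.36,            # events / min
    discharge_refractory = 2,         # s, floor on inter-event intervals
    discharge_duration_mean = 1.07,   # s
    discharge_duration_sd = 0.34,
    discharge_duration_min = 0.25,
    discharge_amplitude_mean_ca3 = 2.5,   # mV (baseline to peak)
    discharge_amplitude_sd_ca3 = 1.0,
    discharge_amplitude_mean_ca1 = 1.9,
    discharge_amplitude_sd_ca1 = 0.75,
    discharge_amplitude_min = 1.3,
    # bursts (per-slice trait)
    burst_probability = 0.48,
    burst_rate = 0.375,               # bursts / min within bursting slices
    burst_duration_mean = 35.61,      # s
    burst_duration_sd = 12.67,
    burst_duration_min = 8,
    intraburst_frequency_mean = 0.52, # Hz
    intraburst_frequency_sd = 0.28,
    intraburst_frequency_min = 0.30,
    burst_leader_amplitude_factor = 2,
    # CA3 -> CA1 coupling
    coupling_delay = 0.005,           # s
    coupling_jitter_sd = 0.030,       # s
    coupling_failure_prob = 0.15,
    coupling_amplitude_cv = 0.85,     # per-event CA1/CA3 amplitude decorrelation
    # independent population spikes
    popspike_rate_ca3 = 0.5,          # events / min
    popspike_rate_ca1 = 6,
    popspike_duration = 0.05,         # s
    popspike_amplitude_mean = 1.0,    # mV
    popspike_amplitude_sd = 0.3,
    popspike_amplitude_min = 0.75,
    # drug block model
    has_block = FALSE,
    block_immediate_prob = 0,
    block_delay_mean = 0,             # min
    block_delay_sd = 0,
    # regular SLA trains (0 disables; replaces the renewal/burst process)
    sla_frequency = 0,                # Hz
    sla_jitter_frac = 0.10,           # SD of interval jitter, fraction of 1/f
    sla_duration_mean = 0.8,          # s
    sla_duration_sd = 0.15,
    # condition-level scaling
    amplitude_scale_ca3 = 1,
    amplitude_scale_ca1 = 1,
    slice_amplitude_cv = 0.15,        # slice-level random effect (shared by channels)
    # noise model
    noise_sd = 0.03,                  # mV, broadband floor (low-passed white)
    noise_cutoff = 100,               # Hz
    wander_sd = 0.17,                 # mV, slow uncorrelated baseline wander
    wander_cutoff = 1,                # Hz
    # template duration convention: nominal duration = width above this level
    duration_ref_mv = 0.36,
    # intracellular (IPSC) model
    ipsc_g_mean = 51.60 / 70,         # nS, peak conductance (51.60 pA at -70 mV)
    ipsc_g_sd = 22.71 / 70,
    ipsc_rise = 0.003,                # s
    ipsc_decay = 0.05,                # s
    ipsc_noise_sd = 14.89             # pA
  )
}

#' @noRd
validate_condition_spec <- function(spec) {
  num <- function(x) is.numeric(spec[[x]]) && length(spec[[x]]) == 1L &&
    is.finite(spec[[x]])
  nonneg <- c("discharge_rate", "discharge_refractory",
              "discharge_duration_mean", "discharge_duration_sd",
              "discharge_amplitude_mean_ca3", "discharge_amplitude_sd_ca3",
              "discharge_amplitude_mean_ca1", "discharge_amplitude_sd_ca1",
              "burst_rate", "burst_duration_mean", "burst_duration_sd",
              "intraburst_frequency_mean", "intraburst_frequency_sd",
              "popspike_rate_ca3", "popspike_rate_ca1", "popspike_duration",
              "popspike_amplitude_mean", "popspike_amplitude_sd",
              "block_delay_mean", "block_delay_sd", "sla_frequency",
              "noise_sd", "wander_sd", "ipsc_g_mean", "ipsc_g_sd",
              "ipsc_noise_sd", "coupling_jitter_sd")
  for (f in nonneg) {
    if (!num(f) || spec[[f]] < 0)
      stop("condition_spec field `", f, "` must be a nonnegative number",
           call. = FALSE)
  }
  probs <- c("burst_probability", "coupling_failure_prob",
             "block_immediate_prob")
  for (f in probs) {
    if (!num(f) || spec[[f]] < 0 || spec[[f]] > 1)
      stop("condition_spec field `", f, "` must lie in [0, 1]", call. = FALSE)
  }
  if (spec$burst_leader_amplitude_factor < 1)
    stop("burst_leader_amplitude_factor must be >= 1", call. = FALSE)
  if (spec$amplitude_scale_ca3 <= 0 || spec$amplitude_scale_ca1 <= 0)
    stop("amplitude scales must be positive", call. = FALSE)
  if (spec$duration_ref_mv <= 0)
    stop("duration_ref_mv must be positive", call. = FALSE)
  structure(spec, class = "condition_spec")
}

#' Condition presets for the documented experimental regimes
#'
#' Each preset encodes the phenomenology of one perfusion condition as
#' generator parameters:
#'
#' * `synaptic_blockers`: spontaneous CA3-CA1 synchronous discharges in
#'   AMPA/NMDA/GABA-antagonist aCSF (1.07 s, 2.36 min⁻¹, 48% bursting
#'   slices, 35.61 s bursts at 0.52 Hz).
#' * `low_ca`: nonsynaptic regime — independent per-channel population
#'   spikes only, no coupled discharges.
#' * `cd2_15uM`: Cd²⁺ application — discharges cease, immediately in
#'   45.5% of applications, otherwise after a delay averaging 4.09 min;
#'   population spikes persist.
#' * `mec_50uM`, `d_tubocurarine_50uM`: nicotinic antagonists — complete
#'   abolition of coupled discharges after a latency.
#' * `atropine_10uM`, `mla_100nM`, `dhbe_10uM`: no-effect conditions
#'   (identical to `synaptic_blockers`).
#' * `bicuculline`, `bicuculline_mec`: regular SLA at 0.13/0.15 Hz; MEC
#'   scales amplitudes (2.04→1.61 mV in CA3, 3.45→2.19 mV in CA1).
#' * `4ap`, `4ap_mec`: regular SLA at 0.36/0.33 Hz; MEC has no material
#'   effect.
#'
#' @param name one of the preset labels above.
#' @return A [condition_spec()].
#' @examples
#' make_condition("synaptic_blockers")$discharge_rate  # 2.36 events/min
#' @export
make_condition <- function(name) {
  presets <- list(
    synaptic_blockers = list(),
    low_ca = list(
      discharge_rate = 0, burst_probability = 0, coupling_failure_prob = 1,
      popspike_rate_ca3 = 20, popspike_rate_ca1 = 20,
      popspike_amplitude_mean = 1.2, popspike_amplitude_sd = 0.4
    ),
    cd2_15uM = list(
      has_block = TRUE, block_immediate_prob = 10 / 22,
      block_delay_mean = 4.09, block_delay_sd = 2.60,
      popspike_rate_ca3 = 4, popspike_rate_ca1 = 6
    ),
    mec_50uM = list(
      has_block = TRUE, block_immediate_prob = 0,
      block_delay_mean = 3, block_delay_sd = 1.5
    ),
    d_tubocurarine_50uM = list(
      has_block = TRUE, block_immediate_prob = 0,
      block_delay_mean = 3, block_delay_sd = 1.5
    ),
    atropine_10uM = list(),
    mla_100nM = list(),
    dhbe_10uM = list(),
    bicuculline = list(
      discharge_rate = 0, burst_probability = 0,
      popspike_rate_ca3 = 0, popspike_rate_ca1 = 0,
      sla_frequency = 0.13,
      discharge_amplitude_mean_ca3 = 2.04, discharge_amplitude_sd_ca3 = 1.04,
      discharge_amplitude_mean_ca1 = 3.45, discharge_amplitude_sd_ca1 = 1.87,
      coupling_failure_prob = 0.02
    ),
    bicuculline_mec = list(
      discharge_rate = 0, burst_probability = 0,
      popspike_rate_ca3 = 0, popspike_rate_ca1 = 0,
      sla_frequency = 0.15,
      discharge_amplitude_mean_ca3 = 2.04, discharge_amplitude_sd_ca3 = 1.04,
      discharge_amplitude_mean_ca1 = 3.45, discharge_amplitude_sd_ca1 = 1.87,
      coupling_failure_prob = 0.02,
      amplitude_scale_ca3 = 1.61 / 2.04, amplitude_scale_ca1 = 2.19 / 3.45
    ),
    `4ap` = list(
      discharge_rate = 0, burst_probability = 0,
      popspike_rate_ca3 = 0, popspike_rate_ca1 = 0,
      sla_frequency = 0.36,
      discharge_amplitude_mean_ca3 = 3.49, discharge_amplitude_sd_ca3 = 2.09,
      discharge_amplitude_mean_ca1 = 1.47, discharge_amplitude_sd_ca1 = 0.45,
      coupling_failure_prob = 0.02
    ),
    `4ap_mec` = list(
      discharge_rate = 0, burst_probability = 0,
      popspike_rate_ca3 = 0, popspike_rate_ca1 = 0,
      sla_frequency = 0.33,
      discharge_amplitude_mean_ca3 = 3.49, discharge_amplitude_sd_ca3 = 2.09,
      discharge_amplitude_mean_ca1 = 1.47, discharge_amplitude_sd_ca1 = 0.45,
      coupling_failure_prob = 0.02,
      amplitude_scale_ca3 = 2.93 / 3.49, amplitude_scale_ca1 = 1.34 / 1.47
    )
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown condition preset ", deparse(name), "; valid presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  do.call(condition_spec, c(list(name = name), presets[[name]]))
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec> ", x$name, "\n", sep = "")
  if (x$sla_frequency > 0) {
    cat(sprintf("  regular SLA at %.2f Hz, amplitudes CA3 %.2f / CA1 %.2f mV\n",
                x$sla_frequency,
                x$discharge_amplitude_mean_ca3 * x$amplitude_scale_ca3,
                x$discharge_amplitude_mean_ca1 * x$amplitude_scale_ca1))
  } else {
    cat(sprintf("  discharges: %.2f /min, %.2f s; bursts in %.0f%% of slices\n",
                x$discharge_rate, x$discharge_duration_mean,
                100 * x$burst_probability))
    cat(sprintf("  coupling: delay %.0f ms, failure %.2f\n",
                1000 * x$coupling_delay, x$coupling_failure_prob))
  }
  if (x$has_block)
    cat(sprintf("  block: immediate with p=%.3f, else delay %.2f ± %.2f min\n",
                x$block_immediate_prob, x$block_delay_mean, x$block_delay_sd))
  invisible(x)
}

#' Write / read a condition specification as a flat key=value file
#'
#' @param spec a [condition_spec()].
#' @param path file path.
#' @return `write_condition` returns `path` invisibly; `read_condition`
#'   returns a `condition_spec`.
#' @export
write_condition <- function(spec, path) {
  stopifnot(inherits(spec, "condition_spec"))
  vals <- vapply(spec, function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else sprintf("%.17g", v)
  }, character(1))
  writeLines(paste0(names(spec), "=", vals), path)
  invisible(path)
}

#' @rdname write_condition
#' @export
read_condition <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed key=value line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  out <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    out[[keys[i]]] <-
      if (keys[i] == "name") v
      else if (v %in% c("TRUE", "FALSE")) as.logical(v)
      else as.numeric(v)
  }
  nm <- out$name %||% "custom"
  out$name <- NULL
  do.call(condition_spec, c(list(name = nm), out))
}
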