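# Plain-text readers/writers for recordings, event tables, sync results
# and condition-comparison reports.  All numeric columns round-trip to
# full double precision.

#' Write / read a two-channel recording as CSV
#'
#' Schema: `time_s,ca3_mv,ca1_mv` with an optional `i_pa` column when an
#' intracellular trace is attached. Values are written so that a
#' write/read round trip reproduces the samples bitwise.
#'
#' @param recording a `recording`.
#' @param path file path.
#' @param itrace optional `intracellular_trace` sharing the sampling rate.
#' @return `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(recording, path, itrace = NULL) {
  stopifnot(inherits(recording, "recording"))
  n <- length(recording$ca3)
  cols <- list(time_s = (seq_len(n) - 1L) / recording$sampling_rate,
               ca3_mv = recording$ca3, ca1_mv = recording$ca1)
  if (!is.null(itrace)) {
    if (itrace$sampling_rate != recording$sampling_rate)
      stop("intracellular trace sampling rate does not match the recording",
           call. = FALSE)
    cols$i_pa <- itrace$current
  }
  # 17 significant digits so the samples round-trip bitwise
  chr <- lapply(cols, function(v) sprintf("%.17g", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(do.call(paste, c(chr, sep = ",")), con)
  invisible(path)
}

#' @rdname write_recording
#' @param condition,seed metadata restored on read (the CSV carries only
#'   samples).
#' @return `read_recording` returns a `recording` (with `i_pa` attached
#'   as `$i_pa` when present).
#' @export
read_recording <- function(path, condition = "unknown", seed = NA_integer_) {
  df <- data.table::fread(path)
  need <- c("time_s", "ca3_mv", "ca1_mv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("recording file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tm <- df$time_s
  if (length(tm) < 2)
    stop("recording file must contain at least two samples", call. = FALSE)
  dt <- diff(tm)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("time column not strictly increasing at row ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  fs <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / fs)) > 0.25 / fs)
    stop("time column of ", path, " is not uniformly sampled", call. = FALSE)
  rec <- structure(
    list(sampling_rate = fs, duration = length(tm) / fs,
         ca3 = df$ca3_mv, ca1 = df$ca1_mv,
         condition = condition, seed = seed, metadata = list(path = path)),
    class = "recording")
  if ("i_pa" %in% names(df)) rec$i_pa <- df$i_pa
  rec
}

#' Write / read an event table as CSV
#'
#' Schema: `channel,onset_s,offset_s,peak_mv,kind,burst_id` — identical
#' for ground truth and detections, so oracle comparisons can diff files
#' directly.
#'
#' @param table an [as_event_table()].
#' @param path file path.
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!nrow(df))
    return(as_event_table(empty_events()))
  df$channel <- as.character(df$channel)
  df$kind <- as.character(df$kind)
  df$burst_id <- as.integer(df$burst_id)
  as_event_table(df)
}

#' Write a sync result: per-lag CSV plus a one-line JSON-style summary
#'
#' @param result a `sync_result`.
#' @param path CSV path (`lag_s,ccf,ccf_smoothed`); the summary line is
#'   written to `paste0(path, ".summary.json")`.
#' @export
write_sync_result <- function(result, path) {
  stopifnot(inherits(result, "sync_result"))
  data.table::fwrite(data.table::data.table(
    lag_s = result$lags, ccf = result$ccf,
    ccf_smoothed = result$ccf_smoothed), path)
  p <- result$params
  summary_line <- sprintf(
    paste0('{"score": %.10g, "score_lag_s": %.10g, "cutoff_hz": %g, ',
           '"lowess_span": %g, "max_lag_s": %g, "analysis_rate_hz": %g}'),
    result$score, result$score_lag, p$cutoff, p$lowess_span, p$max_lag,
    p$analysis_rate)
  writeLines(summary_line, paste0(path, ".summary.json"))
  invisible(path)
}

#' Write a condition-comparison report table as CSV
#'
#' One row per condition pair: `condition,cc_control,cc_application,
#' test,p,n` with the mean ± SD of the synchronization scores formatted
#' as reported.
#'
#' @param report an `experiment_report` (see [run_experiment()]).
#' @param path file path.
#' @export
write_report_table <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  rows <- lapply(report$pairs, function(p) {
    cmp <- p$comparison
    data.frame(
      condition = p$label,
      cc_control = fmt_ms(cmp$group_a_summary$mean, cmp$group_a_summary$sd),
      cc_application = fmt_ms(cmp$group_b_summary$mean,
                              cmp$group_b_summary$sd),
      test = cmp$test_used, p = cmp$p_value, n = cmp$group_a_summary$n,
      stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
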