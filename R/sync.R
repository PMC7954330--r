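# The synchronization statistic: Gaussian low-pass filtering, paired
# cross-correlation, Lowess smoothing, and first-maximum extraction.

#' Synchronization analysis parameters
#'
#' @param cutoff Gaussian low-pass half-gain cutoff, Hz.
#' @param lowess_span Lowess span as a fraction of the number of lag
#'   points in the cross-correlation function.
#' @param max_lag maximum lag examined, s.
#' @param min_duration minimum recording duration accepted, s.
#' @param analysis_rate decimation target, Hz; set equal to the recording
#'   rate to disable decimation.
#' @return A `sync_params` object.
#' @export
sync_params <- function(cutoff = 50, lowess_span = 0.01, max_lag = 1.0,
                        min_duration = 300, analysis_rate = 1000) {
  p <- list(cutoff = cutoff, lowess_span = lowess_span, max_lag = max_lag,
            min_duration = min_duration, analysis_rate = analysis_rate)
  if (cutoff <= 0 || max_lag <= 0 || min_duration <= 0 || analysis_rate <= 0)
    stop("sync parameters must be positive", call. = FALSE)
  if (lowess_span <= 0 || lowess_span > 1)
    stop("lowess_span must lie in (0, 1]", call. = FALSE)
  structure(p, class = "sync_params")
}

#' Pearson-normalized cross-correlation restricted to short lags
#'
#' Both traces are mean-subtracted; the raw lagged products are computed
#' by FFT and normalized per lag by the overlap length times the product
#' of the (population) standard deviations, so `ccf(0) = 1` when the
#' traces are identical. Sign convention: a positive lag means `y` lags
#' `x` (a copy of `x` delayed by d peaks at lag +d).
#'
#' @param x,y numeric traces of equal length, neither constant.
#' @param sampling_rate Hz.
#' @param max_lag maximum |lag|, s.
#' @return List with `lags` (s, symmetric about 0) and `ccf`.
#' @export
cross_correlation <- function(x, y, sampling_rate, max_lag) {
  n <- length(x)
  if (length(y) != n)
    stop("traces must have equal length", call. = FALSE)
  L <- floor(max_lag * sampling_rate)
  if (n <= 2 * L)
    stop("traces must be longer than twice the maximum lag", call. = FALSE)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0)
    stop("cross-correlation is undefined for a constant trace",
         call. = FALSE)
  x0 <- x - mean(x); y0 <- y - mean(y)
  nf <- stats::nextn(n + L, c(2, 3, 5))
  X <- stats::fft(c(x0, numeric(nf - n)))
  Y <- stats::fft(c(y0, numeric(nf - n)))
  s <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nf
  # s[ell + 1] = sum_t x0[t] * y0[t + ell] for ell >= 0; negative lags wrap
  lags_i <- (-L):L
  raw <- numeric(2L * L + 1L)
  raw[lags_i >= 0] <- s[lags_i[lags_i >= 0] + 1L]
  raw[lags_i < 0] <- s[nf + lags_i[lags_i < 0] + 1L]
  ccf <- raw / ((n - abs(lags_i)) * sx * sy)
  list(lags = lags_i / sampling_rate, ccf = ccf)
}

#' Lowess smoothing of a cross-correlation function
#'
#' Locally weighted linear regression (tricube weights, one robustness
#' iteration) over the lag axis, with the window set to `span` times the
#' number of lag points.
#'
#' @param lags lag axis (s), sorted.
#' @param ccf correlation values.
#' @param span window as a fraction of the number of points; the window
#'   must cover at least 3 points.
#' @return Smoothed values, same length as `ccf`.
#' @export
lowess_smooth <- function(lags, ccf, span = 0.01) {
  n <- length(ccf)
  if (length(lags) != n) stop("lags and ccf lengths differ", call. = FALSE)
  if (span * n < 3)
    stop(sprintf("span %.4g covers fewer than 3 of %d points; minimum usable span is %.4g",
                 span, n, 3 / n), call. = FALSE)
  stats::lowess(lags, ccf, f = span, iter = 1, delta = 0)$y
}

#' Synchronization score of a paired recording
#'
#' The full statistic: decimate both channels to the analysis rate
#' (anti-aliased), Gaussian low-pass filter, Pearson cross-correlation
#' within `|lag| <= max_lag`, Lowess smoothing, and extraction of the
#' maximum of the smoothed function (ties broken toward the smallest
#' |lag|) as the synchronization score.
#'
#' @param recording a `recording` (or any list with `ca3`, `ca1`,
#'   `sampling_rate`, `duration`).
#' @param params a [sync_params()].
#' @param window optional `c(start, end)` (s) restricting the analysis to
#'   a sub-window of the recording.
#' @param override_min_duration analyze recordings shorter than
#'   `min_duration` anyway (logged as a warning).
#' @return A `sync_result`: `lags`, `ccf`, `ccf_smoothed`, `score`,
#'   `score_lag`, `params`.
#' @export
sync_score <- function(recording, params = sync_params(), window = NULL,
                       override_min_duration = FALSE) {
  fs <- recording$sampling_rate
  x <- recording$ca3; y <- recording$ca1
  if (!is.null(window)) {
    idx <- max(1L, floor(window[1] * fs) + 1L):min(length(x),
                                                   ceiling(window[2] * fs))
    x <- x[idx]; y <- y[idx]
  }
  dur <- length(x) / fs
  if (dur < params$min_duration) {
    if (!override_min_duration)
      stop("recording (", round(dur), " s) is shorter than the minimum ",
           params$min_duration, " s; pass override_min_duration = TRUE to ",
           "analyze anyway", call. = FALSE)
    warning("analyzing a recording shorter than the minimum duration (",
            round(dur), " s < ", params$min_duration, " s)", call. = FALSE)
  }
  if (fs > params$analysis_rate) {
    x <- decimate_trace(x, fs, params$analysis_rate)
    y <- decimate_trace(y, fs, params$analysis_rate)
    fs <- params$analysis_rate
  }
  x <- gaussian_lowpass(x, fs, params$cutoff)
  y <- gaussian_lowpass(y, fs, params$cutoff)
  cc <- cross_correlation(x, y, fs, params$max_lag)
  sm <- lowess_smooth(cc$lags, cc$ccf, params$lowess_span)
  best <- order(-sm, abs(cc$lags))[1L]
  structure(
    list(lags = cc$lags, ccf = cc$ccf, ccf_smoothed = sm,
         score = sm[best], score_lag = cc$lags[best], params = params),
    class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> score %.3f at lag %+.1f ms (%d lag points)\n",
              x$score, 1000 * x$score_lag, length(x$lags)))
  invisible(x)
}
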