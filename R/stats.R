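# Statistical comparison protocol: Shapiro-Wilk-gated test selection,
# exact small-sample Wilcoxon signed-rank, and mean ± SD summaries.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard W statistic with Royston's p-value
#' approximation, with explicit domain checks.
#'
#' @param x numeric sample, 3 <= n <= 5000, nonzero variance.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("Shapiro-Wilk is undefined for a zero-variance sample",
         call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Exact zeros are dropped (classic convention; the count is returned),
#' absolute differences are mid-ranked, and W is the sum of ranks of the
#' positive differences. For n <= 25 the two-sided p-value is exact: the
#' null distribution over all 2^n equiprobable sign assignments is built
#' by generating-function convolution over the doubled ranks (doubling
#' keeps mid-ranks on an integer grid), which enumerates every sign
#' vector implicitly and exactly. Above n = 25 a normal approximation
#' with continuity correction and tie-corrected variance is used.
#'
#' @param differences paired differences.
#' @return List with `W`, `p`, `n` (nonzero pairs), `n_zero` (dropped),
#'   `exact` (logical).
#' @examples
#' wilcoxon_signed_rank_exact(rep(-1, 10))$p  # 2/1024 = 0.00195...
#' @export
wilcoxon_signed_rank_exact <- function(differences) {
  d <- differences[is.finite(differences)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1)
    stop("all differences are zero; the signed-rank test is undefined",
         call. = FALSE)
  r <- rank(abs(d))            # mid-ranks for ties
  W <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # counts over achievable values of 2W under random signs
    counts <- c(1, numeric(total))
    for (v in r2) {
      shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
      counts <- counts + shifted
    }
    W2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(W2 + 1L)]) / 2^n
    p_ge <- sum(counts[(W2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(W = W, p = p, n = n, n_zero = n_zero, exact = exact)
}

#' @noRd
group_summary <- function(x) {
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' @noRd
comparison_result <- function(a, b, paired, normality_p_a, normality_p_b,
                              test_used, statistic, p_value, alpha,
                              note = NULL) {
  structure(
    list(group_a_summary = group_summary(a), group_b_summary = group_summary(b),
         paired = paired, normality_p_a = normality_p_a,
         normality_p_b = normality_p_b, test_used = test_used,
         statistic = statistic, p_value = p_value,
         significant = is.finite(p_value) && p_value < alpha,
         alpha = alpha, note = note),
    class = "comparison_result")
}

#' Paired two-group comparison with a normality gate
#'
#' The gate is applied to the paired differences: if Shapiro-Wilk does
#' not reject normality at `alpha_gate`, a paired t-test is used,
#' otherwise the exact Wilcoxon signed-rank test. Identical samples
#' (all-zero differences) are a degenerate no-test case reported with
#' p = 1 and flagged in `note`.
#'
#' @param a,b paired samples of equal length n >= 3.
#' @param alpha significance level (default 0.05).
#' @param alpha_gate Shapiro-Wilk gate level (default 0.05).
#' @return A `comparison_result`.
#' @export
paired_compare <- function(a, b, alpha = 0.05, alpha_gate = 0.05) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- a - b
  sw_a <- tryCatch(shapiro_wilk(a)$p, error = function(e) NA_real_)
  sw_b <- tryCatch(shapiro_wilk(b)$p, error = function(e) NA_real_)
  if (all(d == 0)) {
    return(comparison_result(a, b, TRUE, sw_a, sw_b,
                             "wilcoxon_signed_rank", NA_real_, 1, alpha,
                             note = "all paired differences are zero; no test performed"))
  }
  sw_d <- tryCatch(shapiro_wilk(d)$p, error = function(e) 0)
  if (sw_d >= alpha_gate) {
    tt <- stats::t.test(a, b, paired = TRUE)
    comparison_result(a, b, TRUE, sw_a, sw_b, "paired_t",
                      unname(tt$statistic), tt$p.value, alpha)
  } else {
    wt <- wilcoxon_signed_rank_exact(d)
    comparison_result(a, b, TRUE, sw_a, sw_b, "wilcoxon_signed_rank",
                      wt$W, wt$p, alpha,
                      note = if (wt$n_zero > 0)
                        sprintf("%d zero difference(s) dropped", wt$n_zero))
  }
}

#' Unpaired two-group comparison with a normality gate
#'
#' If both samples pass Shapiro-Wilk at `alpha_gate`, a Welch two-sample
#' t-test is used; otherwise the two-sample Kolmogorov-Smirnov test
#' (exact when the product of sample sizes is at most 10^4 and there are
#' no ties).
#'
#' @param a,b independent samples, each n >= 3.
#' @inheritParams paired_compare
#' @return A `comparison_result`.
#' @export
unpaired_compare <- function(a, b, alpha = 0.05, alpha_gate = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("need n >= 3 in each group", call. = FALSE)
  sw_a <- tryCatch(shapiro_wilk(a)$p, error = function(e) 0)
  sw_b <- tryCatch(shapiro_wilk(b)$p, error = function(e) 0)
  if (sw_a >= alpha_gate && sw_b >= alpha_gate) {
    tt <- stats::t.test(a, b)   # Welch
    comparison_result(a, b, FALSE, sw_a, sw_b, "unpaired_t",
                      unname(tt$statistic), tt$p.value, alpha)
  } else {
    ks <- suppressWarnings(
      stats::ks.test(a, b, exact = length(a) * length(b) <= 1e4))
    comparison_result(a, b, FALSE, sw_a, sw_b, "kolmogorov_smirnov",
                      unname(ks$statistic), ks$p.value, alpha)
  }
}

#' @export
print.comparison_result <- function(x, ...) {
  ga <- x$group_a_summary; gb <- x$group_b_summary
  cat(sprintf("<comparison_result> %s\n",
              if (x$paired) "paired" else "unpaired"))
  cat(sprintf("  A: %s (n = %d)   B: %s (n = %d)\n",
              fmt_ms(ga$mean, ga$sd), ga$n, fmt_ms(gb$mean, gb$sd), gb$n))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g%s\n", x$test_used,
              x$statistic, x$p_value,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}
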