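# Internal numerical helpers shared by the generator and analysis stages.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic child seed for slice `i` of a cohort
#'
#' Stable arithmetic hash (documented protocol): all intermediates stay below
#' 2^53 so the result is exact in double precision and below 2^31.
#' @noRd
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 69621 + 12345) %%
               2147483563)
}

#' Truncated normal draws whose realized mean equals a target mean
#'
#' Solves for the location parameter `mu` such that the lower-truncated
#' normal with scale `sd` has expectation `mean`; draws by inverse CDF.
#' Used for durations, burst statistics and block latencies, where the
#' calibration target is the empirical mean of an intrinsically positive
#' quantity.
#' @noRd
rtnorm_mean <- function(n, mean, sd, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(max(mean, lower), n))
  mu <- tnorm_location(mean, sd, lower)
  plo <- stats::pnorm((lower - mu) / sd)
  u <- stats::runif(n, plo, 1)
  mu + sd * stats::qnorm(u)
}

#' @noRd
tnorm_mean_given_location <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  # Mills ratio; stable for large a via asymptotic form
  lam <- exp(stats::dnorm(a, log = TRUE) -
               stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mu + sd * lam
}

#' @noRd
tnorm_location <- function(mean, sd, lower) {
  if (mean <= lower)
    stop("target mean must exceed the truncation bound", call. = FALSE)
  f <- function(mu) tnorm_mean_given_location(mu, sd, lower) - mean
  stats::uniroot(f, lower = mean - 12 * sd, upper = mean,
                 tol = 1e-10 * sd)$root
}

#' Log-normal draws parameterized by arithmetic mean and SD
#' @noRd
rlnorm_ms <- function(n, mean, sd) {
  if (mean <= 0) stop("log-normal mean must be positive", call. = FALSE)
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' mean +/- sd formatting used by print methods
#' @noRd
fmt_ms <- function(m, s, digits = 2) {
  if (!is.finite(m)) return("NA")
  sprintf("%.*f ± %.*f", digits, m, digits, if (is.finite(s)) s else NA)
}
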