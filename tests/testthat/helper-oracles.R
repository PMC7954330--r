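# Independent oracles used across the test files.  These deliberately use
# naive O(N*L) / exhaustive-enumeration implementations so they cannot
# share a defect with the FFT / generating-function production code.

# Direct-sum cross-correlation with the same normalization contract
bf_ccf <- function(x, y, sampling_rate, max_lag) {
  n <- length(x)
  L <- floor(max_lag * sampling_rate)
  x0 <- x - mean(x); y0 <- y - mean(y)
  sx <- sqrt(mean(x0^2)); sy <- sqrt(mean(y0^2))
  vapply(-L:L, function(l) {
    t <- if (l >= 0) seq_len(n - l) else seq.int(1 - l, n)
    sum(x0[t] * y0[t + l]) / ((n - abs(l)) * sx * sy)
  }, numeric(1))
}

# Exhaustive two-sided signed-rank p over all 2^n sign vectors
bf_wilcox_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- drop(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Discrete frequency response of the Gaussian kernel, evaluated directly
kernel_gain <- function(sampling_rate, cutoff, freq) {
  k <- fieldsync:::gaussian_kernel(sampling_rate, cutoff)
  half <- (length(k) - 1) / 2
  t <- (-half:half) / sampling_rate
  sum(k * cos(2 * pi * freq * t))
}

# Brute-force burst grouping: scan all index runs
bf_group_bursts <- function(tab, min_events, max_gap) {
  tab$burst_id <- NA_integer_
  nid <- 1L
  for (ch in unique(tab$channel)) {
    idx <- which(tab$channel == ch & tab$kind == "discharge")
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      while (j < length(idx) &&
             tab$onset_s[idx[j + 1]] - tab$onset_s[idx[j]] < max_gap) j <- j + 1L
      if (j - i + 1L >= min_events) {
        tab$burst_id[idx[i:j]] <- nid
        nid <- nid + 1L
      }
      i <- j + 1L
    }
  }
  tab
}

# Greedy onset-proximity matching of detections to ground truth
match_events <- function(truth, detected, tol = 0.5) {
  m <- rep(NA_integer_, nrow(truth))
  used <- rep(FALSE, nrow(detected))
  for (i in seq_len(nrow(truth))) {
    if (!nrow(detected)) break
    dif <- abs(detected$onset_s - truth$onset_s[i])
    dif[used] <- Inf
    j <- which.min(dif)
    if (is.finite(dif[j]) && dif[j] < tol) {
      m[i] <- j
      used[j] <- TRUE
    }
  }
  m
}

# A spec whose CA3->CA1 coupling is deterministic and whose noise is
# negligible: the regime in which the sync score should approach 1
perfect_coupling_spec <- function(...) {
  condition_spec(
    "perfect", coupling_failure_prob = 0, coupling_jitter_sd = 0,
    coupling_amplitude_cv = 0, noise_sd = 0.01, wander_sd = 0,
    slice_amplitude_cv = 0, popspike_rate_ca3 = 0, popspike_rate_ca1 = 0,
    ...)
}
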