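# Shared fixtures and independent oracles, built in code at test time.

# fast noiseless protocol for geometry tests
clean_protocol <- function(duration_s = 2, ...) {
  trial_protocol(duration_s = duration_s, noise_sd_px = 0, dropout_rate = 0,
                 ...)
}

# Independent brute-force oracle for the ACF-crossing feature: direct
# double-sum biased autocovariance, no stats::acf, written before the
# implementation it checks.
acf_brute <- function(x, k) {
  n <- length(x); m <- mean(x)
  num <- sum((x[1:(n - k)] - m) * (x[(k + 1):n] - m)) / n
  den <- sum((x - m)^2) / n
  num / den
}

co_f1ecac_oracle <- function(x) {
  n <- length(x)
  thresh <- exp(-1)
  prev <- 1
  for (k in 1:(n - 1)) {
    cur <- acf_brute(x, k)
    if (cur < thresh)
      return((k - 1) + (thresh - prev) / (cur - prev))
    prev <- cur
  }
  n - 1
}

# Brute-force Fleiss kappa from the textbook category-count formula,
# independent of the package implementation.
fleiss_oracle <- function(ratings) {
  m <- as.matrix(ratings)
  r <- ncol(m); n <- nrow(m)
  cats <- sort(unique(as.vector(m)))
  cnt <- matrix(0, n, length(cats))
  for (i in seq_len(n)) for (j in seq_len(r))
    cnt[i, match(m[i, j], cats)] <- cnt[i, match(m[i, j], cats)] + 1
  P_i <- (rowSums(cnt^2) - r) / (r * (r - 1))
  p_j <- colSums(cnt) / (n * r)
  Pe <- sum(p_j^2)
  if (1 - Pe < 1e-12) return(NA_real_)  # degenerate: single category used
  (mean(P_i) - Pe) / (1 - Pe)
}

# small linearly separable summary matrix for classifier tests
toy_summaries <- function(n_per = 10, p_extra = 3, seed = 1) {
  set.seed(seed)
  x1 <- c(rnorm(n_per, 0, 0.3), rnorm(n_per, 5, 0.3))
  extras <- matrix(rnorm(2 * n_per * p_extra), ncol = p_extra)
  m <- cbind(sig = x1, extras)
  colnames(m) <- c("sig", paste0("noise", seq_len(p_extra)))
  list(summaries = m,
       labels = rep(c("traditional", "nontraditional"), each = n_per))
}

dominant_freq <- function(x, fps) {
  sp <- Mod(stats::fft(x - mean(x)))[2:(floor(length(x) / 2))]
  which.max(sp) * fps / length(x)
}
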