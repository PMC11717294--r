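#' First 1/e crossing of the autocorrelation function (CO_f1ecac)
#'
#' The canonical time-series timescale feature: the first lag at which the
#' autocorrelation function (ACF) of a series falls below 1/e. The ACF is
#' computed with mean removal and the biased (divide-by-n) autocovariance
#' normalized by lag 0, the convention of the catch22 feature set, and the
#' crossing lag is linearly interpolated between the two integer lags that
#' bracket 1/e, so the result is fractional. A series whose ACF never
#' reaches 1/e returns the sentinel `length(series) - 1` (the maximum lag
#' available).
#'
#' @param series numeric vector, length >= 3, nonconstant.
#' @return the crossing lag in frames (fractional).
#' @examples
#' co_f1ecac(sin(2 * pi * 2 * (0:299) / 30))  # ~2.85 frames for 2 Hz at 30 fps
#' @export
co_f1ecac <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3) stopf("series must have length >= 3, got %d", n)
  if (anyNA(series)) stopf("series contains NA")
  if (stats::var(series) == 0) stopf("constant series has no autocorrelation timescale")
  thresh <- exp(-1)
  # stats::acf uses the biased (divide-by-n) autocovariance; extend lag.max
  # lazily since the crossing usually occurs within a few lags
  lag_max <- min(n - 1, 32L)
  repeat {
    rho <- as.numeric(stats::acf(series, lag.max = lag_max, plot = FALSE,
                                 demean = TRUE, type = "correlation")$acf)
    below <- which(rho < thresh)
    if (length(below)) {
      k <- below[1]            # 1-based index; lag = k - 1
      if (k == 1) return(0)    # cannot happen for rho[1] = 1, kept for safety
      return((k - 2) + (thresh - rho[k - 1]) / (rho[k] - rho[k - 1]))
    }
    if (lag_max >= n - 1) return(n - 1)
    lag_max <- min(n - 1, lag_max * 4L)
  }
}

# channel matrix of a grip_features object: the 4 distances plus the x and
# y trajectories of the five fingertips (14 channels)
feature_channels <- function(features) {
  tips <- c(LM$tip_I, LM$tip_II, LM$tip_III, LM$tip_IV, LM$tip_V)
  xy <- features$landmark_xy[, as.vector(rbind(2 * tips - 1, 2 * tips)),
                             drop = FALSE]
  colnames(xy) <- paste0("tip_", rep(c("I", "II", "III", "IV", "V"), each = 2),
                         c("_x", "_y"))
  cbind(features$feats, xy)
}

#' Summarize a grip feature sequence
#'
#' Collapses a per-frame feature sequence into a fixed-length summary
#' vector for sequence-level classification: for each of the 14 channels
#' (distances a-d and the x/y fingertip trajectories), the CO_f1ecac
#' autocorrelation timescale, the mean and the standard deviation, plus
#' the usable sequence length and the fraction of carry-forward-filled
#' frames. Frames left missing by [fill_gaps()] are excluded; a
#' zero-variance channel receives the CO_f1ecac sentinel (max lag) rather
#' than an error.
#'
#' @param features a `grip_features` object (length >= 3 after gap
#'   handling).
#' @return a named numeric vector of class `sequence_summary`.
#' @export
summarize_sequence <- function(features) {
  stopifnot(inherits(features, "grip_features"))
  keep <- !features$missing
  ch <- feature_channels(features)[keep, , drop = FALSE]
  n <- nrow(ch)
  if (n < 3) stopf("sequence too short to summarize: %d usable frames", n)
  ac <- apply(ch, 2, function(x)
    if (stats::var(x) == 0) n - 1 else co_f1ecac(x))
  mu <- colMeans(ch)
  sd <- apply(ch, 2, stats::sd)
  out <- c(stats::setNames(ac, paste0("cof1ecac_", colnames(ch))),
           stats::setNames(mu, paste0("mean_", colnames(ch))),
           stats::setNames(sd, paste0("sd_", colnames(ch))),
           n_frames = n,
           filled_frac = mean(features$filled[keep]))
  class(out) <- "sequence_summary"
  out
}

#' @export
print.sequence_summary <- function(x, ...) {
  cat("Sequence summary (", length(x), " features)\n", sep = "")
  print(round(unclass(x)[1:min(8, length(x))], 3))
  if (length(x) > 8) cat("...\n")
  invisible(x)
}

#' Summarize every sequence of a dataset
#'
#' Runs feature extraction, optional normalization and
#' [summarize_sequence()] over a list of sequences, returning the
#' classifier's design matrix.
#'
#' @param dataset a `grip_dataset` (or plain list of `grip_sequence`).
#' @param mode distance mode, see [point_segment_distance()].
#' @param normalize `"none"` or `"hand_length"`, see
#'   [normalize_features()].
#' @param max_gap carry-forward limit passed to [fill_gaps()].
#' @return a list with `summaries` (n_sequences x n_features matrix) and
#'   `labels` (character, `NA` where unlabelled).
#' @export
summarize_dataset <- function(dataset, mode = "perpendicular",
                              normalize = "none", max_gap = 5) {
  rows <- lapply(dataset, function(s) {
    f <- compute_features(s, mode = mode, max_gap = max_gap)
    f <- normalize_features(f, normalize)
    unclass(summarize_sequence(f))
  })
  summaries <- do.call(rbind, rows)
  labels <- vapply(dataset, function(s)
    if (!is.null(s$label)) s$label else NA_character_, "")
  list(summaries = summaries, labels = labels)
}
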