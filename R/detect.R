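#' Tape-color specification
#'
#' HSV window describing one chopstick's identification tape. The study
#' setup wraps the upper chopstick in blue tape and the lower in green;
#' the defaults are windows for saturated blue and green and can be
#' re-mapped for other tapes or lighting.
#'
#' @param name tape label, `"upper"` or `"lower"`.
#' @param hue_range hue window in degrees on the 0-360 HSV wheel; a range
#'   with `hue_range[1] > hue_range[2]` wraps through 0.
#' @param saturation_min,value_min lower HSV bounds in `[0, 1]`.
#' @param min_pixels minimum mask size (after opening) to accept a
#'   detection.
#' @return an object of class `color_spec`.
#' @export
color_spec <- function(name, hue_range, saturation_min = 0.4,
                       value_min = 0.25, min_pixels = 30) {
  if (any(hue_range < 0) || any(hue_range > 360))
    stopf("hue_range must lie on the 0-360 HSV wheel")
  if (min_pixels < 1) stopf("min_pixels must be >= 1")
  structure(list(name = name, hue_range = hue_range,
                 saturation_min = saturation_min, value_min = value_min,
                 min_pixels = min_pixels),
            class = "color_spec")
}

#' Default tape colors: upper = blue, lower = green
#' @return named list of two [color_spec()] objects.
#' @export
default_color_specs <- function() {
  list(upper = color_spec("upper", c(200, 260)),
       lower = color_spec("lower", c(90, 150)))
}

#' Segment one tape color in a frame
#'
#' Thresholds a color frame in HSV space against a tape's hue window and
#' saturation/value floors, then applies a 3x3 morphological opening to
#' suppress speckle.
#'
#' @param frame an H x W x 3 numeric array (RGB in `[0, 1]`).
#' @param spec a [color_spec()].
#' @return a binary H x W matrix (1 = in-range pixel).
#' @export
segment_color <- function(frame, spec) {
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    stopf("frame must be a color (H x W x 3) image array")
  h <- dim(frame)[1]; w <- dim(frame)[2]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(frame[, , 1]),
                                  as.vector(frame[, , 2]),
                                  as.vector(frame[, , 3])),
                            maxColorValue = 1)
  hue <- hsv[1, ] * 360
  hr <- spec$hue_range
  in_hue <- if (hr[1] <= hr[2]) hue >= hr[1] & hue <= hr[2]
            else hue >= hr[1] | hue <= hr[2]
  mask <- matrix(as.numeric(in_hue & hsv[2, ] >= spec$saturation_min &
                              hsv[3, ] >= spec$value_min), h, w)
  if (!any(mask > 0)) return(mask)
  as.matrix(EBImage::opening(mask, EBImage::makeBrush(3, "box")))
}

#' Fit a line segment to a binary mask
#'
#' Estimates a chopstick's supporting line as the principal axis of the
#' mask's pixel coordinates (first eigenvector of their covariance), with
#' endpoints at the extreme projections of the pixels onto that axis.
#'
#' @param mask binary matrix (rows = y, columns = x).
#' @param min_pixels minimum pixel count; fewer pixels is a detection
#'   failure.
#' @return a list `(p1, p2, n_pixels, axis_ratio, low_confidence)` where
#'   `p1`, `p2` are `(x, y)` endpoints and `low_confidence` flags a
#'   near-isotropic blob (principal-axis ratio < 1.5); or `NULL` on
#'   detection failure (too few pixels or a degenerate point cloud).
#' @export
fit_line_segment <- function(mask, min_pixels = 1) {
  idx <- which(mask > 0, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  if (nrow(xy) < max(min_pixels, 2)) return(NULL)
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  if (!all(is.finite(cv)) || sum(diag(cv)) == 0) return(NULL)
  eg <- eigen(cv, symmetric = TRUE)
  dir <- eg$vectors[, 1]
  # deterministic orientation: positive x, tie-broken toward positive y
  if (dir[1] < 0 || (abs(dir[1]) < 1e-12 && dir[2] < 0)) dir <- -dir
  proj <- (xy[, 1] - ctr[1]) * dir[1] + (xy[, 2] - ctr[2]) * dir[2]
  ratio <- if (eg$values[2] <= 0) Inf else sqrt(eg$values[1] / eg$values[2])
  low <- is.finite(ratio) && ratio < 1.5
  if (low) warning("near-isotropic blob: low-confidence line fit")
  list(p1 = ctr + min(proj) * dir, p2 = ctr + max(proj) * dir,
       n_pixels = nrow(xy), axis_ratio = ratio, low_confidence = low)
}

#' Chopstick pose of one frame
#'
#' @param upper,lower length-4 numeric `(x1, y1, x2, y2)` endpoints (px),
#'   `NA` when missing.
#' @param source `"detected"`, `"carried_forward"` or `"missing"`.
#' @param frame_index frame number.
#' @param age number of consecutive frames this geometry has been carried
#'   forward (0 for a fresh detection).
#' @return an object of class `chopstick_pose`.
#' @export
chopstick_pose <- function(upper, lower, source, frame_index = NA_integer_,
                           age = 0L) {
  if (source != "missing" && (anyNA(upper) || anyNA(lower)))
    stopf("non-missing pose must have finite endpoints")
  structure(list(upper = as.numeric(upper), lower = as.numeric(lower),
                 source = source, frame_index = frame_index, age = age),
            class = "chopstick_pose")
}

# largest connected component of a binary mask
largest_blob <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  if (max(lab) <= 1) return(mask)
  counts <- tabulate(lab[lab > 0])
  (lab == which.max(counts)) * 1
}

#' Detect the chopstick pose in one frame
#'
#' Segments both tape colors, keeps the largest blob per color and fits
#' line segments. If either chopstick fails to detect and a previous pose
#' exists that has been carried forward for fewer than `max_gap` frames,
#' the previous geometry is reused with `source = "carried_forward"`;
#' otherwise the pose is `"missing"`. Carrying forward never alters
#' geometry.
#'
#' @param frame H x W x 3 RGB array.
#' @param prev previous [chopstick_pose()] or `NULL`.
#' @param specs named list with `upper` and `lower` [color_spec()]s.
#' @param max_gap maximum consecutive carry-forward frames (default 5).
#' @param frame_index frame number recorded in the pose.
#' @return a [chopstick_pose()].
#' @export
detect_pose <- function(frame, prev = NULL, specs = default_color_specs(),
                        max_gap = 5, frame_index = NA_integer_) {
  stopifnot(all(c("upper", "lower") %in% names(specs)))
  fit_one <- function(spec) {
    mask <- segment_color(frame, spec)
    if (sum(mask) < spec$min_pixels) return(NULL)
    seg <- suppressWarnings(fit_line_segment(largest_blob(mask),
                                             spec$min_pixels))
    if (is.null(seg)) NULL else c(seg$p1, seg$p2)
  }
  up <- fit_one(specs$upper)
  lo <- fit_one(specs$lower)
  if (!is.null(up) && !is.null(lo))
    return(chopstick_pose(up, lo, "detected", frame_index, age = 0L))
  if (!is.null(prev) && prev$source != "missing" && prev$age < max_gap)
    return(chopstick_pose(prev$upper, prev$lower, "carried_forward",
                          frame_index, age = prev$age + 1L))
  chopstick_pose(rep(NA_real_, 4), rep(NA_real_, 4), "missing", frame_index)
}

#' Track chopsticks through a frame sequence
#'
#' Applies [detect_pose()] frame by frame, threading the previous pose for
#' the carry-forward rule, and reports the per-sequence detection rate.
#'
#' @param frames list of H x W x 3 RGB arrays (>= 1 frame).
#' @param specs tape color specs, see [default_color_specs()].
#' @param max_gap carry-forward limit in frames.
#' @return a list of [chopstick_pose()] objects with attributes
#'   `detection_rate` (fraction with `source == "detected"`) and
#'   `sources`.
#' @export
track_sequence <- function(frames, specs = default_color_specs(),
                           max_gap = 5) {
  if (length(frames) == 0) stopf("track_sequence requires at least one frame")
  poses <- vector("list", length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    p <- detect_pose(frames[[i]], prev, specs, max_gap, frame_index = i)
    poses[[i]] <- p
    if (p$source != "missing") prev <- p
  }
  src <- vapply(poses, function(p) p$source, "")
  structure(poses, detection_rate = mean(src == "detected"), sources = src)
}

#' @export
print.chopstick_pose <- function(x, ...) {
  cat(sprintf("Chopstick pose [frame %s, %s]\n", x$frame_index, x$source))
  if (x$source != "missing") {
    cat(sprintf("  upper: (%.1f,%.1f)-(%.1f,%.1f)\n", x$upper[1], x$upper[2],
                x$upper[3], x$upper[4]))
    cat(sprintf("  lower: (%.1f,%.1f)-(%.1f,%.1f)\n", x$lower[1], x$lower[2],
                x$lower[3], x$lower[4]))
  }
  invisible(x)
}
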