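#' Distance from a point to a chopstick line
#'
#' Unsigned distance from a 2D point to the infinite supporting line of a
#' segment. The default `"perpendicular"` mode measures orthogonal distance
#' in the image plane, which is invariant to chopstick orientation. The
#' `"vertical"` mode instead measures the image-vertical (y) offset between
#' the point and the line evaluated at the point's x, and is provided for
#' fidelity experiments; it is undefined for image-vertical lines.
#'
#' @param point numeric length-2 `(x, y)` in px.
#' @param segment numeric length-4 `(x1, y1, x2, y2)`; must have nonzero
#'   length (the distance is measured to the infinite line through it).
#' @param mode `"perpendicular"` (default) or `"vertical"`.
#' @return nonnegative distance in px.
#' @examples
#' point_segment_distance(c(0, 1), c(0, 0, 1, 0))  # 1
#' point_segment_distance(c(3, 4), c(0, 0, 0, 2))  # 3
#' @export
point_segment_distance <- function(point, segment,
                                   mode = c("perpendicular", "vertical")) {
  mode <- match.arg(mode)
  dx <- segment[3] - segment[1]; dy <- segment[4] - segment[2]
  len <- sqrt(dx^2 + dy^2)
  if (!is.finite(len) || len == 0)
    stopf("degenerate segment: endpoints coincide")
  if (mode == "perpendicular")
    return(abs(dx * (point[2] - segment[2]) - dy * (point[1] - segment[1])) / len)
  if (abs(dx) < 1e-9 * len)
    stopf("vertical-offset distance is undefined for an image-vertical line")
  abs((point[2] - segment[2]) - dy / dx * (point[1] - segment[1]))
}

#' Grip features of a single frame
#'
#' Computes the four geometric grip features from one frame's hand
#' landmarks and chopstick pose: `a` fingertip II to the upper chopstick,
#' `b` first joint of finger III to the upper chopstick, `c` fingertip III
#' to the lower chopstick (all point-to-line distances), and `d` the
#' Euclidean distance between the fingertips of fingers III and IV.
#'
#' @param landmarks a 21 x 2 matrix of landmark positions (rows in standard
#'   order, wrist first) or a length-42 vector `x0,y0,...,x20,y20`.
#' @param pose chopstick pose: length-8 numeric
#'   `(ux1,uy1,ux2,uy2,lx1,ly1,lx2,ly2)` or a `chopstick_pose` object.
#' @param valid optional logical length-21 landmark validity flags.
#' @param mode distance mode passed to [point_segment_distance()].
#' @return a list with elements `a`, `b`, `c`, `d`, `landmark_xy`
#'   (length 42), `chopstick_xy` (length 8), `filled = FALSE`, `ok`. When
#'   the pose is missing or a required landmark is invalid, `ok = FALSE`
#'   and the distances are `NA` (a feature failure, to be repaired by
#'   [fill_gaps()]).
#' @export
compute_frame_features <- function(landmarks, pose, valid = NULL,
                                   mode = c("perpendicular", "vertical")) {
  mode <- match.arg(mode)
  if (is.matrix(landmarks)) {
    stopifnot(nrow(landmarks) == 21, ncol(landmarks) == 2)
    lm_xy <- as.vector(t(landmarks))
  } else {
    if (length(landmarks) != 42)
      stopf("landmarks must be 21 points (42 coordinates), got %d values",
            length(landmarks))
    lm_xy <- as.numeric(landmarks)
  }
  if (inherits(pose, "chopstick_pose"))
    pose_xy <- c(pose$upper, pose$lower)
  else pose_xy <- as.numeric(pose)
  src <- if (inherits(pose, "chopstick_pose")) pose$source else
    if (anyNA(pose_xy)) "missing" else "detected"

  need <- c(LM$tip_II, LM$joint1_III, LM$tip_III, LM$tip_IV)
  pt <- function(i) lm_xy[c(2 * i - 1, 2 * i)]
  ok <- !identical(src, "missing") && !anyNA(pose_xy) &&
    all(is.finite(lm_xy[c(2 * need - 1, 2 * need)])) &&
    (is.null(valid) || all(valid[need]))
  if (!ok)
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                landmark_xy = lm_xy, chopstick_xy = pose_xy,
                filled = FALSE, ok = FALSE))
  upper <- pose_xy[1:4]; lower <- pose_xy[5:8]
  d34 <- pt(LM$tip_III) - pt(LM$tip_IV)
  list(a = point_segment_distance(pt(LM$tip_II), upper, mode),
       b = point_segment_distance(pt(LM$joint1_III), upper, mode),
       c = point_segment_distance(pt(LM$tip_III), lower, mode),
       d = sqrt(sum(d34^2)),
       landmark_xy = lm_xy, chopstick_xy = pose_xy,
       filled = FALSE, ok = TRUE)
}

#' Per-frame grip features of a whole sequence
#'
#' Vectorized feature extraction over a [generate_grip_sequence()] result
#' (or landmark matrix plus tracked poses), followed by previous-frame gap
#' filling. Frames whose chopstick pose is missing, or that fall inside a
#' gap longer than `max_gap`, are handled by [fill_gaps()].
#'
#' @param sequence a `grip_sequence`, or an n x 42 landmark matrix.
#' @param poses optional pose input overriding the sequence's own
#'   chopsticks: an n x 8 matrix, or the list of `chopstick_pose` objects
#'   returned by [track_sequence()] (carried-forward poses are used as-is).
#' @param t optional frame times when `sequence` is a bare matrix.
#' @param mode distance mode, see [point_segment_distance()].
#' @param fill apply [fill_gaps()] (default `TRUE`).
#' @param max_gap longest failure run repaired by carry-forward filling.
#' @return an object of class `grip_features`: list with `t`, `feats`
#'   (n x 4 matrix, columns `a,b,c,d`), `landmark_xy` (n x 42),
#'   `chopstick_xy` (n x 8), `filled`, `missing` (logical per frame),
#'   `fps`, `label`, `archetype`, `normalized`.
#' @export
compute_features <- function(sequence, poses = NULL, t = NULL,
                             mode = c("perpendicular", "vertical"),
                             fill = TRUE, max_gap = 5) {
  mode <- match.arg(mode)
  if (inherits(sequence, "grip_sequence")) {
    lm <- sequence$landmarks
    t <- sequence$t
    label <- sequence$label
    arche <- sequence$archetype
    fps <- sequence$protocol$fps
    if (is.null(poses)) {
      chop <- sequence$chopsticks
      src <- sequence$source
    }
  } else {
    lm <- sequence
    label <- NA_character_; arche <- NA_character_
    if (is.null(t)) t <- seq_len(nrow(lm)) - 1
    fps <- if (length(t) > 1) 1 / stats::median(diff(t)) else NA_real_
  }
  if (!is.null(poses)) {
    if (is.list(poses) && !is.matrix(poses)) {
      chop <- t(vapply(poses, function(p) c(p$upper, p$lower), numeric(8)))
      src <- vapply(poses, function(p) p$source, "")
    } else {
      chop <- as.matrix(poses)
      src <- ifelse(apply(is.na(chop), 1, any), "missing", "detected")
    }
  }
  n <- nrow(lm)
  stopifnot(nrow(chop) == n, length(src) == n)

  pxy <- function(i) list(x = lm[, 2 * i - 1], y = lm[, 2 * i])
  fail <- src == "missing" | apply(is.na(chop), 1, any)
  p2 <- pxy(LM$tip_II); j3 <- pxy(LM$joint1_III)
  p3 <- pxy(LM$tip_III); p4 <- pxy(LM$tip_IV)
  dist_line <- function(p, seg_cols) {
    seg <- chop[, seg_cols, drop = FALSE]
    if (mode == "perpendicular") {
      point_line_distance_vec(p$x, p$y, seg)
    } else {
      dx <- seg[, 3] - seg[, 1]; dy <- seg[, 4] - seg[, 2]
      abs((p$y - seg[, 2]) - dy / dx * (p$x - seg[, 1]))
    }
  }
  feats <- cbind(a = dist_line(p2, 1:4), b = dist_line(j3, 1:4),
                 c = dist_line(p3, 5:8),
                 d = sqrt((p3$x - p4$x)^2 + (p3$y - p4$y)^2))
  feats[fail, ] <- NA_real_
  out <- structure(list(t = t, feats = feats, landmark_xy = lm,
                        chopstick_xy = chop, filled = rep(FALSE, n),
                        missing = fail, fps = fps, label = label,
                        archetype = arche, normalized = "none"),
                   class = "grip_features")
  if (fill) out <- fill_gaps(out, max_gap = max_gap)
  out
}

#' Repair feature failures by previous-frame carry-forward
#'
#' Frames whose features could not be computed (missing chopstick pose or
#' invalid landmarks) are replaced by an exact copy of the previous
#' computed frame and flagged `filled`, mirroring the previous-frame rule
#' used for detection errors. Leading failures are trimmed; failure runs
#' longer than `max_gap` are left missing and excluded by downstream
#' summarization.
#'
#' @param features a `grip_features` object.
#' @param max_gap longest run of consecutive failures repaired by filling.
#' @return the repaired `grip_features` object.
#' @export
fill_gaps <- function(features, max_gap = 5) {
  stopifnot(inherits(features, "grip_features"))
  fail <- features$missing | apply(is.na(features$feats), 1, any)
  if (all(fail)) stopf("all frames failed; nothing to fill from")
  # trim leading failures
  first_ok <- which(!fail)[1]
  if (first_ok > 1) {
    keep <- first_ok:length(fail)
    for (fld in c("t", "filled", "missing", "source"))
      if (!is.null(features[[fld]])) features[[fld]] <- features[[fld]][keep]
    for (fld in c("feats", "landmark_xy", "chopstick_xy"))
      features[[fld]] <- features[[fld]][keep, , drop = FALSE]
    fail <- fail[keep]
  }
  runs <- rle(fail)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    idx <- starts[r]:ends[r]
    if (runs$lengths[r] > max_gap) {
      features$feats[idx, ] <- NA_real_
      features$missing[idx] <- TRUE
      next
    }
    src_row <- starts[r] - 1  # guaranteed >= 1 after trimming
    for (i in idx) {
      features$feats[i, ] <- features$feats[src_row, ]
      features$chopstick_xy[i, ] <- features$chopstick_xy[src_row, ]
      features$filled[i] <- TRUE
      features$missing[i] <- FALSE
    }
  }
  features
}

#' Normalize grip features by hand length
#'
#' `mode = "hand_length"` expresses each frame's geometry relative to the
#' wrist and divides all distances and coordinates by that frame's
#' wrist-to-middle-fingertip distance, removing hand-size and camera-zoom
#' scale. `mode = "none"` returns the input unchanged (raw pixel features,
#' the default pipeline behaviour).
#'
#' @param features a `grip_features` object.
#' @param mode `"none"` or `"hand_length"`.
#' @return the (possibly rescaled) `grip_features` object.
#' @export
normalize_features <- function(features, mode = c("none", "hand_length")) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "grip_features"))
  if (mode == "none") return(features)
  lm <- features$landmark_xy
  wx <- lm[, 2 * LM$wrist - 1]; wy <- lm[, 2 * LM$wrist]
  h <- sqrt((lm[, 2 * LM$tip_III - 1] - wx)^2 + (lm[, 2 * LM$tip_III] - wy)^2)
  if (any(h <= 0 | !is.finite(h))) stopf("zero or invalid hand length in frame")
  features$feats <- features$feats / h
  features$landmark_xy[, seq(1, 41, 2)] <- (lm[, seq(1, 41, 2)] - wx) / h
  features$landmark_xy[, seq(2, 42, 2)] <- (lm[, seq(2, 42, 2)] - wy) / h
  features$chopstick_xy[, c(1, 3, 5, 7)] <-
    (features$chopstick_xy[, c(1, 3, 5, 7)] - wx) / h
  features$chopstick_xy[, c(2, 4, 6, 8)] <-
    (features$chopstick_xy[, c(2, 4, 6, 8)] - wy) / h
  features$normalized <- "hand_length"
  features
}

#' @export
print.grip_features <- function(x, ...) {
  cat(sprintf("Grip features: %d frames (%d filled, %d missing), mode %s\n",
              nrow(x$feats), sum(x$filled), sum(x$missing), x$normalized))
  invisible(x)
}
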