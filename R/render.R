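#' Render synthetic frames of a grip sequence
#'
#' Draws each frame's chopsticks as thick tape-colored line segments on a
#' plain background, producing the image stack the detection stage
#' consumes. Frames whose chopstick detection is flagged as dropped out
#' (`source == "missing"`) are rendered without chopsticks. Only the
#' chopsticks are drawn: the tape is the only colored object the detector
#' is designed to find.
#'
#' @param sequence a `grip_sequence`.
#' @param frame_size `c(height, width)` in px (default `c(420, 480)`).
#' @param tape_colors list with `upper` and `lower` RGB triples in
#'   `[0, 1]` (default pure blue / pure green).
#' @param background RGB triple of the backdrop (default white).
#' @param thickness tape stroke width in px.
#' @param frames integer indices of the frames to render (default all).
#' @return a list of H x W x 3 arrays, one per requested frame, with
#'   attribute `frame_indices`.
#' @export
render_frames <- function(sequence, frame_size = c(420, 480),
                          tape_colors = list(upper = c(0, 0, 1),
                                             lower = c(0, 1, 0)),
                          background = c(1, 1, 1), thickness = 5,
                          frames = NULL) {
  stopifnot(inherits(sequence, "grip_sequence"))
  n <- length(sequence$t)
  if (n == 0) stopf("empty sequence")
  if (is.null(frames)) frames <- seq_len(n)
  h <- frame_size[1]; w <- frame_size[2]

  lm <- sequence$landmarks[frames, , drop = FALSE]
  ch <- sequence$chopsticks[frames, , drop = FALSE]
  xs <- c(lm[, seq(1, 41, 2)], ch[, c(1, 3, 5, 7)])
  ys <- c(lm[, seq(2, 42, 2)], ch[, c(2, 4, 6, 8)])
  pad <- thickness / 2 + 1
  if (any(xs < pad | xs > w - pad | ys < pad | ys > h - pad, na.rm = TRUE))
    stopf("frame size %dx%d too small to contain the scene; enlarge frame_size",
          h, w)

  draw_segment <- function(img, seg, col, thick) {
    x1 <- seg[1]; y1 <- seg[2]; x2 <- seg[3]; y2 <- seg[4]
    r <- thick / 2
    cx <- max(1, floor(min(x1, x2) - r)):min(w, ceiling(max(x1, x2) + r))
    cy <- max(1, floor(min(y1, y2) - r)):min(h, ceiling(max(y1, y2) + r))
    px <- rep(cx, each = length(cy)); py <- rep(cy, length(cx))
    dx <- x2 - x1; dy <- y2 - y1
    len <- sqrt(dx^2 + dy^2)
    s <- ((px - x1) * dx + (py - y1) * dy) / len^2
    perp <- abs((px - x1) * dy - (py - y1) * dx) / len
    hit <- s >= 0 & s <= 1 & perp <= r  # butt caps keep endpoints crisp
    for (c3 in 1:3) {
      plane <- img[, , c3]
      plane[cbind(py[hit], px[hit])] <- col[c3]
      img[, , c3] <- plane
    }
    img
  }

  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    img <- array(rep(background, each = h * w), dim = c(h, w, 3))
    if (sequence$source[frames[i]] != "missing") {
      img <- draw_segment(img, ch[i, 1:4], tape_colors$upper, thickness)
      img <- draw_segment(img, ch[i, 5:8], tape_colors$lower, thickness)
    }
    out[[i]] <- img
  }
  attr(out, "frame_indices") <- frames
  out
}

#' Write rendered frames as a PNG stack
#'
#' @param frames list of H x W x 3 arrays from [render_frames()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths (`prefix_000001.png`, ...).
#' @export
write_png_stack <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}

#' Read a PNG stack back into a frame list
#'
#' @param paths PNG file paths, or a directory containing them.
#' @return list of H x W x 3 arrays in file order.
#' @export
read_png_stack <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.png$", full.names = TRUE))
  if (!length(paths)) stopf("no PNG frames found")
  lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) stopf("grayscale frame is not a color image: %s", p)
    img[, , 1:3, drop = FALSE]
  })
}
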