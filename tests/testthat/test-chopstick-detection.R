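blank_frame <- function(h = 60, w = 80, col = c(1, 1, 1)) {
  array(rep(col, each = h * w), dim = c(h, w, 3))
}

paint_rect <- function(frame, rows, cols, col) {
  for (k in 1:3) frame[rows, cols, k] <- col[k]
  frame
}

test_that("color segmentation finds the tape and only the tape", {
  fr <- paint_rect(blank_frame(), 20:29, 31:70, c(0, 0, 1))  # 10x40 pure blue
  mask <- segment_color(fr, default_color_specs()$upper)
  # opening erodes at most the 1-px border of the 10x40 rectangle
  expect_lte(sum(mask), 400)
  expect_gte(sum(mask), 8 * 38)
  expect_equal(sum(segment_color(fr, default_color_specs()$lower)), 0)

  none <- segment_color(blank_frame(), default_color_specs()$upper)
  expect_equal(sum(none), 0)

  expect_error(segment_color(matrix(0, 5, 5), default_color_specs()$upper),
               "color")
})

test_that("line fitting recovers the principal axis exactly on a diagonal", {
  mask <- matrix(0, 6, 6)
  mask[cbind(1:4, 1:4)] <- 1   # pixels (1,1)..(4,4)
  seg <- fit_line_segment(mask)
  expect_equal(unname(seg$p1), c(1, 1))
  expect_equal(unname(seg$p2), c(4, 4))
  dir <- (seg$p2 - seg$p1) / sqrt(sum((seg$p2 - seg$p1)^2))
  expect_equal(unname(dir), c(sqrt(2) / 2, sqrt(2) / 2))
})

test_that("line fitting is accurate and rotation-equivariant on bars", {
  mask <- matrix(0, 20, 60)
  mask[9:11, 6:55] <- 1        # 3 x 50 horizontal bar
  seg <- fit_line_segment(mask)
  ang <- atan2(seg$p2[2] - seg$p1[2], seg$p2[1] - seg$p1[1])
  expect_lt(abs(ang) * 180 / pi, 1)       # within 1 degree of horizontal

  rot <- t(mask)[, nrow(mask):1]          # rotate mask by 90 degrees
  seg_r <- fit_line_segment(rot)
  ang_r <- atan2(seg_r$p2[2] - seg_r$p1[2], seg_r$p2[1] - seg_r$p1[1])
  expect_equal(unname(abs(ang_r - ang)), pi / 2, tolerance = 0.02)

  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_null(fit_line_segment(single))   # detection failure signal
  blob <- matrix(1, 7, 7)                 # isotropic blob: low confidence
  expect_warning(fit_line_segment(blob), "low-confidence")
})

test_that("carry-forward reuses previous geometry and respects max_gap", {
  s <- generate_grip_sequence("four_finger", clean_protocol(duration_s = 0.2),
                              seed = 11)
  frames <- render_frames(s)
  p1 <- detect_pose(frames[[1]], frame_index = 1)
  expect_equal(p1$source, "detected")

  blank <- blank_frame(420, 480)
  p2 <- detect_pose(blank, prev = p1, frame_index = 2)
  expect_equal(p2$source, "carried_forward")
  expect_identical(p2$upper, p1$upper)    # geometry never altered
  expect_identical(p2$lower, p1$lower)

  p_none <- detect_pose(blank, prev = NULL)
  expect_equal(p_none$source, "missing")
  expect_true(all(is.na(p_none$upper)))

  # a gap longer than max_gap turns into missing poses
  prev <- p1
  for (i in 1:7) prev <- detect_pose(blank, prev = prev, max_gap = 5)
  expect_equal(prev$source, "missing")
})

test_that("tracking a rendered sequence round-trips the simulator geometry", {
  s <- generate_grip_sequence("four_finger", clean_protocol(duration_s = 0.3),
                              seed = 5)
  frames <- render_frames(s)
  poses <- track_sequence(frames)
  expect_equal(attr(poses, "detection_rate"), 1.0)
  match_err <- function(fit, truth) {
    d1 <- max(sqrt((fit[c(1, 3)] - truth[c(1, 3)])^2 +
                     (fit[c(2, 4)] - truth[c(2, 4)])^2))
    d2 <- max(sqrt((fit[c(3, 1)] - truth[c(1, 3)])^2 +
                     (fit[c(4, 2)] - truth[c(2, 4)])^2))
    min(d1, d2)   # endpoint order is arbitrary
  }
  for (i in seq_along(poses)) {
    expect_lt(match_err(poses[[i]]$upper, s$chopsticks[i, 1:4]), 2)
    expect_lt(match_err(poses[[i]]$lower, s$chopsticks[i, 5:8]), 2)
  }

  # mask centroid sits on the segment midpoint
  mask <- segment_color(frames[[1]], default_color_specs()$upper)
  idx <- which(mask > 0, arr.ind = TRUE)
  centroid <- c(mean(idx[, 2]), mean(idx[, 1]))
  midpoint <- c(mean(s$chopsticks[1, c(1, 3)]), mean(s$chopsticks[1, c(2, 4)]))
  expect_lt(sqrt(sum((centroid - midpoint)^2)), 1)
})

test_that("dropout frames become carried_forward poses when gaps are short", {
  proto <- trial_protocol(duration_s = 0.8, noise_sd_px = 0,
                          dropout_rate = 0.2, seed = 21)
  s <- generate_grip_sequence("four_finger", proto)
  frames <- render_frames(s)
  poses <- track_sequence(frames)
  src <- attr(poses, "sources")
  dropped <- which(s$source == "missing")
  # every injected dropout after the first detection is repaired
  first_det <- which(s$source == "detected")[1]
  repaired <- dropped[dropped > first_det]
  expect_true(all(src[repaired] %in% c("carried_forward")))
  expect_equal(sum(src == "carried_forward"), length(repaired))
  expect_error(track_sequence(list()), "at least one frame")
})
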