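test_that("point-to-line distance matches closed forms", {
  expect_equal(point_segment_distance(c(0.5, 0), c(0, 0, 1, 0)), 0)
  expect_equal(point_segment_distance(c(0, 1), c(0, 0, 1, 0)), 1.0)
  # |ax + by + c| / sqrt(a^2 + b^2) with the line x = 0
  expect_equal(point_segment_distance(c(3, 4), c(0, 0, 0, 2)), 3.0)
  expect_error(point_segment_distance(c(1, 1), c(2, 2, 2, 2)), "degenerate")
  # vertical mode measures the image-y offset instead
  expect_equal(point_segment_distance(c(1, 3), c(0, 0, 2, 2), "vertical"), 2)
  expect_error(point_segment_distance(c(1, 3), c(0, 0, 0, 2), "vertical"),
               "vertical")
})

test_that("frame features reproduce the simulator's analytic distances", {
  for (arch in c("four_finger", "three_finger", "palm", "other")) {
    s <- generate_grip_sequence(arch, clean_protocol(), seed = 17)
    f <- compute_features(s)
    expect_lt(max(abs(f$feats - s$truth)), 1e-9)
  }
  # single-frame path agrees with the vectorized path
  s <- generate_grip_sequence("four_finger", clean_protocol(), seed = 2)
  fr <- compute_frame_features(s$landmarks[5, ], s$chopsticks[5, ])
  expect_equal(c(fr$a, fr$b, fr$c, fr$d), unname(s$truth[5, ]), tolerance = 1e-12)
})

test_that("degenerate frame geometry gives the expected values", {
  lm <- matrix(0, 21, 2)
  lm[9, ] <- c(5, 5)            # fingertip II on the upper chopstick line
  lm[12, ] <- c(0, 7)
  lm[13, ] <- c(4, 4); lm[17, ] <- c(4, 4)  # tips III and IV coincide
  pose <- c(0, 0, 10, 10, 0, 20, 10, 20)
  fr <- compute_frame_features(lm, pose)
  expect_equal(fr$a, 0)
  expect_equal(fr$d, 0)
  # missing pose triggers the feature-failure signal
  fr2 <- compute_frame_features(lm, rep(NA_real_, 8))
  expect_false(fr2$ok)
  expect_true(is.na(fr2$a))
})

test_that("features are invariant to translation/rotation, equivariant to scale", {
  s <- generate_grip_sequence("four_finger", clean_protocol(), seed = 8)
  f0 <- compute_features(s)$feats
  shift_seq <- function(s, dx, dy) {
    s$landmarks[, seq(1, 41, 2)] <- s$landmarks[, seq(1, 41, 2)] + dx
    s$landmarks[, seq(2, 42, 2)] <- s$landmarks[, seq(2, 42, 2)] + dy
    s$chopsticks[, c(1, 3, 5, 7)] <- s$chopsticks[, c(1, 3, 5, 7)] + dx
    s$chopsticks[, c(2, 4, 6, 8)] <- s$chopsticks[, c(2, 4, 6, 8)] + dy
    s
  }
  expect_equal(compute_features(shift_seq(s, 37, -12))$feats, f0,
               tolerance = 1e-9)
  rot_seq <- function(s, th) {
    R <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                             y = sin(th) * x + cos(th) * y)
    for (k in 1:21) {
      r <- R(s$landmarks[, 2 * k - 1], s$landmarks[, 2 * k])
      s$landmarks[, 2 * k - 1] <- r$x; s$landmarks[, 2 * k] <- r$y
    }
    for (k in c(1, 3, 5, 7)) {
      r <- R(s$chopsticks[, k], s$chopsticks[, k + 1])
      s$chopsticks[, k] <- r$x; s$chopsticks[, k + 1] <- r$y
    }
    s
  }
  expect_equal(compute_features(rot_seq(s, 0.7))$feats, f0, tolerance = 1e-9)
  scale_seq <- function(s, sc) {
    s$landmarks <- s$landmarks * sc
    s$chopsticks <- s$chopsticks * sc
    s
  }
  expect_equal(compute_features(scale_seq(s, 2.5))$feats, f0 * 2.5,
               tolerance = 1e-9)
})

test_that("gap filling copies the previous frame and trims leading failures", {
  s <- generate_grip_sequence("four_finger", clean_protocol(), seed = 12)
  f0 <- compute_features(s, fill = FALSE)
  expect_equal(sum(f0$filled), 0)
  expect_identical(fill_gaps(f0)$feats, f0$feats)  # no failures: unchanged

  s$chopsticks[10, ] <- NA; s$source[10] <- "missing"
  f1 <- compute_features(s)
  expect_true(f1$filled[10])
  expect_equal(f1$feats[10, ], f1$feats[9, ])      # exact copy
  expect_equal(sum(f1$filled), 1)

  s2 <- generate_grip_sequence("four_finger", clean_protocol(), seed = 12)
  s2$chopsticks[1:3, ] <- NA; s2$source[1:3] <- "missing"
  f2 <- compute_features(s2)
  expect_equal(nrow(f2$feats), 60 - 3)             # leading failures trimmed

  s3 <- generate_grip_sequence("four_finger", clean_protocol(), seed = 12)
  s3$chopsticks[11:20, ] <- NA; s3$source[11:20] <- "missing"
  f3 <- compute_features(s3, max_gap = 5)
  expect_true(all(f3$missing[11:20]))              # run too long: left missing
  expect_true(all(is.na(f3$feats[11:20, ])))

  s4 <- s3; s4$chopsticks[] <- NA; s4$source[] <- "missing"
  expect_error(compute_features(s4), "all frames failed")
})

test_that("hand-length normalization removes scale", {
  s <- generate_grip_sequence("four_finger", clean_protocol(), seed = 3)
  f <- compute_features(s)
  expect_identical(normalize_features(f, "none"), f)
  fn <- normalize_features(f, "hand_length")
  s2 <- s; s2$landmarks <- s2$landmarks * 2; s2$chopsticks <- s2$chopsticks * 2
  fn2 <- normalize_features(compute_features(s2), "hand_length")
  expect_equal(fn2$feats, fn$feats, tolerance = 1e-9)
  expect_equal(fn2$landmark_xy, fn$landmark_xy, tolerance = 1e-9)

  fz <- f; fz$landmark_xy[1, ] <- 0
  expect_error(normalize_features(fz, "hand_length"), "hand length")
})
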