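#' Simulate one chopstick-grip trial
#'
#' Generates a labelled synthetic sequence of 21-point hand landmarks and
#' chopstick line segments for one grip archetype under a trial protocol.
#' Finger motion is sinusoidal flexion about each metacarpophalangeal joint
#' (with a distal curl so fingertips travel farther than proximal joints);
#' the upper chopstick pivots near the thumb web with an angle coupled to
#' the mean flexion of the archetype's driving fingers, while the lower
#' chopstick stays static when supported by finger IV, wobbles when not,
#' and moves rigidly with the hand for palm-type grips. Per-sequence
#' anatomical and postural variability (hand size from the cohort
#' distribution 133.5 +/- 9.5 mm, amplitude and phase jitter, chopstick
#' contact offsets, scene rotation) is drawn once per trial, then isotropic
#' Gaussian pixel noise is added per frame.
#'
#' @param archetype a [grip_archetype()] (or archetype name).
#' @param protocol a [trial_protocol()].
#' @param seed integer seed for this sequence; defaults to `protocol$seed`.
#'   Identical seeds yield bit-identical sequences.
#' @return an object of class `grip_sequence`: a list with elements
#'   `t` (frame times, s), `landmarks` (n x 42 matrix, columns
#'   `x0,y0,...,x20,y20`), `valid` (n x 21 logical), `chopsticks` (n x 8
#'   matrix of upper then lower endpoint coordinates, `NA` on dropout
#'   frames), `source` (per-frame `"detected"`/`"missing"`), `truth`
#'   (n x 4 matrix of the noiseless analytic grip features a-d), `label`,
#'   `archetype`, `protocol`, `seed`, `handedness`.
#' @export
generate_grip_sequence <- function(archetype, protocol = trial_protocol(),
                                   seed = protocol$seed) {
  if (is.character(archetype)) archetype <- grip_archetype(archetype)
  stopifnot(inherits(archetype, "grip_archetype"),
            inherits(protocol, "trial_protocol"))
  n <- round(protocol$duration_s * protocol$fps)
  t <- (seq_len(n) - 1) / protocol$fps
  w <- 2 * pi * protocol$open_close_hz

  with_seed(seed, {
    ## per-sequence variability ------------------------------------------
    hand_scale <- min(max(1 + stats::rnorm(1, 0, 9.5 / 133.5), 0.8), 1.25)
    L <- 133.5 * hand_scale
    wrist <- c(160, 300) + stats::runif(2, -15, 15)
    scene_rot <- deg2rad(stats::runif(1, -12, 12))
    # children vary widely within a grip category: amplitudes span a wide
    # band so grips near the category boundary occur
    amp_mult <- stats::runif(5, 0.6, 1.4)
    drive_gain <- stats::runif(1, 0.4, 0.6)
    wobble_deg <- stats::runif(1, 0.5, 6)
    rig_rot <- deg2rad(stats::runif(1, 1.5, 4.5))
    rig_tx <- stats::runif(1, 5, 15)
    rig_ty <- stats::runif(1, 2, 8)
    base_flex <- deg2rad(stats::runif(5, -5, 8))
    phase0 <- stats::runif(1, 0, 2 * pi)
    phase_jit <- stats::runif(5, -0.4, 0.4)
    jit <- if (archetype$contact_jitter) c(0.10, 10) else c(0.03, 5)
    u_piv_off <- stats::runif(2, -jit[1], jit[1]) * L
    u_ang_off <- deg2rad(stats::runif(1, -jit[2], jit[2]))
    l_piv_off <- stats::runif(2, -jit[1], jit[1]) * L
    l_ang_off <- deg2rad(stats::runif(1, -jit[2], jit[2]))

    ## flexion angle of each finger over time (n x 5) --------------------
    amp <- deg2rad(archetype$amplitude_deg) * amp_mult
    phase <- phase0 + archetype$phase_rad + phase_jit
    theta <- sapply(1:5, function(f)
      base_flex[f] + amp[f] * (1 - cos(w * t + phase[f])) / 2)
    theta <- matrix(theta, nrow = n)

    ## articulated landmarks (noiseless), frames x 21 x 2 ----------------
    base <- hand_base_pose(L, wrist)
    lx <- matrix(rep(base[, 1], each = n), nrow = n)
    ly <- matrix(rep(base[, 2], each = n), nrow = n)
    curl <- c(1, 1.8, 2.3)  # cumulative rotation multiplier along the chain
    fr <- finger_rows()
    for (f in 1:5) {
      rows <- fr[[f]]
      sgn <- if (f == 1) -1 else 1   # thumb opposes the finger curl
      px <- lx[, rows[1]]; py <- ly[, rows[1]]  # pivot = MCP (first row)
      for (j in 1:3) {
        v <- base[rows[j + 1], ] - base[rows[j], ]
        a <- sgn * curl[j] * theta[, f]
        ca <- cos(a); sa <- sin(a)
        px <- px + ca * v[1] - sa * v[2]
        py <- py + sa * v[1] + ca * v[2]
        lx[, rows[j + 1]] <- px
        ly[, rows[j + 1]] <- py
      }
    }

    ## chopsticks (noiseless) --------------------------------------------
    clen <- 165 * hand_scale
    fingers <- c("I", "II", "III", "IV", "V")
    drive <- if (length(archetype$coupling))
      rowMeans(theta[, match(archetype$coupling, fingers), drop = FALSE] -
                 matrix(rep(base_flex[match(archetype$coupling, fingers)],
                            each = n), nrow = n))
    else rep(0, n)

    # upper chopstick runs past the tips of fingers I and II; lower rests
    # between the thumb web and the ring finger's first knuckle
    a0 <- deg2rad(-120) + u_ang_off
    # held 8 px off the fingertip pads so the pinch gap never collapses
    u_piv <- wrist + c(0.35, -0.65) * L + u_piv_off -
      8 * c(-sin(a0), cos(a0))
    u_ang <- a0 + drive_gain * drive
    l_piv <- wrist + c(0.10, -0.60) * L + l_piv_off
    l_ang <- rep(deg2rad(-122) + l_ang_off, n)
    l_bob <- rep(0, n)
    if (!archetype$lower_support && !archetype$hand_motion) {
      # unsupported lower chopstick wobbles with the open/close cycle,
      # weakly for near-traditional grips, strongly for loose ones
      l_ang <- l_ang + deg2rad(wobble_deg) * (1 - cos(w * t + phase0)) / 2
      l_bob <- (wobble_deg / 2.5) * sin(w * t + phase0)
    }
    chop <- cbind(
      u_piv[1] - 0.30 * clen * cos(u_ang), u_piv[2] - 0.30 * clen * sin(u_ang),
      u_piv[1] + 0.70 * clen * cos(u_ang), u_piv[2] + 0.70 * clen * sin(u_ang),
      l_piv[1] - 0.30 * clen * cos(l_ang), l_piv[2] + l_bob - 0.30 * clen * sin(l_ang),
      l_piv[1] + 0.70 * clen * cos(l_ang), l_piv[2] + l_bob + 0.70 * clen * sin(l_ang))

    ## rigid scene transform: fixed rotation + palm-type oscillation -----
    rot <- rep(scene_rot, n)
    shift_x <- rep(0, n); shift_y <- rep(0, n)
    if (archetype$hand_motion) {
      rot <- rot + rig_rot * sin(w * t + phase0)
      shift_x <- rig_tx * sin(w * t + phase0)
      shift_y <- rig_ty * sin(w * t + phase0 + 1)
    }
    ca <- cos(rot); sa <- sin(rot)
    tf_x <- function(x, y) wrist[1] + ca * (x - wrist[1]) - sa * (y - wrist[2]) + shift_x
    tf_y <- function(x, y) wrist[2] + sa * (x - wrist[1]) + ca * (y - wrist[2]) + shift_y
    for (k in 1:21) {
      x0 <- lx[, k]; y0 <- ly[, k]
      lx[, k] <- tf_x(x0, y0); ly[, k] <- tf_y(x0, y0)
    }
    for (k in c(1, 3, 5, 7)) {
      x0 <- chop[, k]; y0 <- chop[, k + 1]
      chop[, k] <- tf_x(x0, y0); chop[, k + 1] <- tf_y(x0, y0)
    }

    ## analytic ground-truth features a-d (noiseless geometry) -----------
    truth <- cbind(
      a = point_line_distance_vec(lx[, LM$tip_II], ly[, LM$tip_II], chop[, 1:4]),
      b = point_line_distance_vec(lx[, LM$joint1_III], ly[, LM$joint1_III], chop[, 1:4]),
      c = point_line_distance_vec(lx[, LM$tip_III], ly[, LM$tip_III], chop[, 5:8]),
      d = sqrt((lx[, LM$tip_III] - lx[, LM$tip_IV])^2 +
                 (ly[, LM$tip_III] - ly[, LM$tip_IV])^2))

    ## observation noise and detection dropout ---------------------------
    landmarks <- matrix(0, n, 42)
    landmarks[, seq(1, 41, 2)] <- lx
    landmarks[, seq(2, 42, 2)] <- ly
    if (protocol$noise_sd_px > 0) {
      landmarks <- landmarks + stats::rnorm(n * 42, 0, protocol$noise_sd_px)
      chop <- chop + stats::rnorm(n * 8, 0, protocol$noise_sd_px / 2)
    }
    colnames(landmarks) <- paste0(rep(c("x", "y"), 21), rep(0:20, each = 2))
    colnames(chop) <- c("ux1", "uy1", "ux2", "uy2", "lx1", "ly1", "lx2", "ly2")
    src <- rep("detected", n)
    if (protocol$dropout_rate > 0) {
      drop <- stats::runif(n) < protocol$dropout_rate
      src[drop] <- "missing"
      chop[drop, ] <- NA_real_
    }

    structure(list(t = t, landmarks = landmarks,
                   valid = matrix(TRUE, n, 21), chopsticks = chop,
                   source = src, truth = truth,
                   label = archetype_label(archetype),
                   archetype = archetype$name, protocol = protocol,
                   seed = seed, handedness = "right"),
              class = "grip_sequence")
  })
}

# perpendicular distance from points (x, y) to the infinite line through the
# segment rows seg = (x1, y1, x2, y2); vectorized over frames
point_line_distance_vec <- function(x, y, seg) {
  dx <- seg[, 3] - seg[, 1]; dy <- seg[, 4] - seg[, 2]
  len <- sqrt(dx^2 + dy^2)
  abs(dx * (y - seg[, 2]) - dy * (x - seg[, 1])) / len
}

#' @export
print.grip_sequence <- function(x, ...) {
  cat(sprintf("Grip sequence: %s (%s), %d frames at %g fps, seed %s\n",
              x$archetype, x$label, length(x$t), x$protocol$fps,
              x$seed %||% "none"))
  cat(sprintf("  chopstick source: %d detected, %d missing\n",
              sum(x$source == "detected"), sum(x$source == "missing")))
  invisible(x)
}

#' Simulate a labelled dataset of grip trials
#'
#' Generates a dataset emulating the study composition of 163 videos: 60
#' traditional (four-finger) trials and 103 nontraditional trials drawn
#' from the three-finger, palm and other archetypes in the observed cohort
#' proportions (49 : 20 : 32 by default). Per-sequence seeds are derived
#' deterministically from `seed`, so the same seed reproduces the dataset
#' bit for bit.
#'
#' @param n_traditional number of four-finger sequences (default 60).
#' @param n_nontraditional number of nontraditional sequences (default 103).
#' @param class_mix named nonnegative weights over
#'   `c("three_finger", "palm", "other")`; counts are apportioned by
#'   largest remainder.
#' @param protocol a [trial_protocol()] applied to every sequence.
#' @param seed base integer seed.
#' @return a list of [generate_grip_sequence()] results, with attributes
#'   `labels` (character) and `archetypes` (character); class `grip_dataset`.
#' @export
make_grip_dataset <- function(n_traditional = 60, n_nontraditional = 103,
                              class_mix = c(three_finger = 49, palm = 20, other = 32),
                              protocol = trial_protocol(), seed = 1234) {
  if (n_traditional <= 0 || n_nontraditional <= 0)
    stopf("sample counts must be positive")
  if (length(class_mix) == 0 || sum(class_mix) <= 0)
    stopf("class_mix must contain positive weights")
  bad <- setdiff(names(class_mix), c("three_finger", "palm", "other"))
  if (length(bad)) stopf("unknown nontraditional class in class_mix: %s", bad[1])

  p <- class_mix / sum(class_mix)
  raw <- p * n_nontraditional
  cnt <- floor(raw)
  rem <- n_nontraditional - sum(cnt)
  if (rem > 0) {
    take <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[take] <- cnt[take] + 1
  }
  arches <- c(rep("four_finger", n_traditional),
              rep(names(class_mix), times = cnt))
  seqs <- vector("list", length(arches))
  for (i in seq_along(arches))
    seqs[[i]] <- generate_grip_sequence(grip_archetype(arches[i]), protocol,
                                        seed = seed + i)
  structure(seqs,
            labels = vapply(seqs, function(s) s$label, ""),
            archetypes = arches,
            seed = seed, class = "grip_dataset")
}

#' @export
print.grip_dataset <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("Grip dataset: %d sequences (%d traditional, %d nontraditional)\n",
              length(x), sum(lab == "traditional"), sum(lab == "nontraditional")))
  print(table(attr(x, "archetypes")))
  invisible(x)
}
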