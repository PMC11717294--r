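#' Base 21-point hand skeleton
#'
#' Returns the resting pose of the standard 21-landmark hand layout used by
#' single-camera hand pose estimators: wrist at index 0, then four landmarks
#' per digit (thumb 1-4, index 5-8, middle 9-12, ring 13-16, little 17-20),
#' with each finger's tip at its last index. The pose was digitized once from
#' a traced adult right hand, scaled so that the wrist-to-middle-fingertip
#' distance equals `hand_length` exactly. Coordinates are image pixels,
#' origin top-left, x right, y down; fingers point up (-y), thumb toward +x.
#'
#' @param hand_length wrist-to-middle-fingertip distance in px. The default
#'   133.5 matches the mean dominant-hand length of first-grade children
#'   (133.50 mm) at 1 px/mm.
#' @param wrist image position of the wrist landmark (px).
#' @return a 21 x 2 numeric matrix of (x, y) positions, rows in landmark
#'   order 0..20.
#' @export
hand_base_pose <- function(hand_length = 133.5, wrist = c(160, 300)) {
  # fractions of hand length, y negative = up
  frac <- rbind(
    c(0.000,  0.000),                                           # 0 wrist
    c(0.200, -0.120), c(0.320, -0.260), c(0.410, -0.370), c(0.480, -0.450), # thumb
    c(0.180, -0.520), c(0.210, -0.680), c(0.220, -0.790), c(0.230, -0.870), # index
    c(0.050, -0.550), c(0.060, -0.750), c(0.065, -0.890), c(0.070, -1.000), # middle
    c(-0.080, -0.530), c(-0.090, -0.710), c(-0.100, -0.840), c(-0.110, -0.940), # ring
    c(-0.200, -0.470), c(-0.220, -0.600), c(-0.230, -0.690), c(-0.240, -0.770)  # little
  )
  frac <- frac / sqrt(sum(frac[13, ]^2))  # wrist->middle tip == 1 exactly
  xy <- frac * hand_length
  xy[, 1] <- xy[, 1] + wrist[1]
  xy[, 2] <- xy[, 2] + wrist[2]
  dimnames(xy) <- list(landmark_names(), c("x", "y"))
  xy
}

landmark_names <- function() {
  digits <- c("thumb", "index", "middle", "ring", "little")
  joints <- c("mcp", "pip", "dip", "tip")
  c("wrist", paste(rep(digits, each = 4), rep(joints, 5), sep = "_"))
}

# first landmark row (1-based) of each finger I..V; each finger owns 4 rows
finger_rows <- function() list(I = 2:5, II = 6:9, III = 10:13, IV = 14:17, V = 18:21)

# landmark rows (1-based) used by the grip features
LM <- list(wrist = 1L, tip_I = 5L, tip_II = 9L, joint1_III = 12L,
           tip_III = 13L, tip_IV = 17L, tip_V = 21L)

#' Grip archetype definition
#'
#' A kinematic archetype describing one of the four chopstick-holding
#' categories observed in first-grade children: `four_finger` (the
#' traditional grip: upper chopstick driven by fingers I, II and III, lower
#' chopstick resting statically against finger IV), `three_finger` (fingers
#' I-III drive both chopsticks, no ring-finger support, so the lower
#' chopstick wobbles and finger IV trails finger III), `palm` (the whole
#' hand moves rigidly with minimal independent finger motion) and `other`
#' (palm-like motion with atypical, randomized chopstick contact points).
#'
#' @param name one of `"four_finger"`, `"three_finger"`, `"palm"`, `"other"`.
#' @param amplitude_deg per-finger flexion amplitude in degrees, length 5
#'   (fingers I..V); defaults depend on `name`.
#' @param phase_rad per-finger phase offsets in radians, length 5.
#' @param coupling which fingers (subset of `"I".."V"`) drive the upper
#'   chopstick's opening/closing rotation.
#' @param lower_support logical; `TRUE` when finger IV supports a static
#'   lower chopstick (the defining trait of the traditional grip).
#' @param hand_motion logical; `TRUE` when chopstick movement is produced by
#'   rigid whole-hand oscillation (palm-type grips).
#' @param contact_jitter logical; `TRUE` randomizes the chopstick contact
#'   offsets per sequence (the `other` category).
#' @return an object of class `grip_archetype`.
#' @export
grip_archetype <- function(name = c("four_finger", "three_finger", "palm", "other"),
                           amplitude_deg = NULL, phase_rad = NULL,
                           coupling = NULL, lower_support = NULL,
                           hand_motion = NULL, contact_jitter = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    four_finger = list(amplitude_deg = c(18, 22, 22, 3, 2),
                       coupling = c("I", "II", "III"),
                       lower_support = TRUE, hand_motion = FALSE,
                       contact_jitter = FALSE),
    three_finger = list(amplitude_deg = c(18, 22, 22, 6, 5),
                        coupling = c("I", "II", "III"),
                        lower_support = FALSE, hand_motion = FALSE,
                        contact_jitter = FALSE),
    palm = list(amplitude_deg = c(0, 0, 0, 0, 0),
                coupling = character(0),
                lower_support = FALSE, hand_motion = TRUE,
                contact_jitter = FALSE),
    other = list(amplitude_deg = c(0, 0, 0, 0, 0),
                 coupling = character(0),
                 lower_support = FALSE, hand_motion = TRUE,
                 contact_jitter = TRUE)
  )
  arch <- list(
    name = name,
    amplitude_deg = amplitude_deg %||% def$amplitude_deg,
    phase_rad = phase_rad %||% rep(0, 5),
    coupling = coupling %||% def$coupling,
    lower_support = lower_support %||% def$lower_support,
    hand_motion = hand_motion %||% def$hand_motion,
    contact_jitter = contact_jitter %||% def$contact_jitter
  )
  if (length(arch$amplitude_deg) != 5L || length(arch$phase_rad) != 5L)
    stopf("amplitude_deg and phase_rad must have length 5 (fingers I..V)")
  if (!all(arch$coupling %in% c("I", "II", "III", "IV", "V")))
    stopf("coupling must name fingers among I..V")
  if (arch$name == "four_finger" &&
      (!arch$lower_support || !all(c("I", "II", "III") %in% arch$coupling)))
    stopf("four_finger requires lower_support and coupling of fingers I, II, III")
  structure(arch, class = "grip_archetype")
}

#' @export
print.grip_archetype <- function(x, ...) {
  cat("Grip archetype:", x$name, "\n")
  cat("  amplitudes (deg, I..V):", paste(x$amplitude_deg, collapse = " "), "\n")
  cat("  coupling:", if (length(x$coupling)) paste(x$coupling, collapse = ",") else "none",
      " lower support:", x$lower_support,
      " whole-hand motion:", x$hand_motion, "\n")
  invisible(x)
}

#' Grip label of an archetype
#'
#' The binary verdict the classifier targets: the `four_finger` archetype is
#' the traditional grip, every other archetype is nontraditional.
#'
#' @param archetype a [grip_archetype()] or archetype name.
#' @return `"traditional"` or `"nontraditional"`.
#' @export
archetype_label <- function(archetype) {
  name <- if (inherits(archetype, "grip_archetype")) archetype$name else archetype
  if (identical(name, "four_finger")) "traditional" else "nontraditional"
}

#' Trial recording protocol
#'
#' Parameters of one recording trial: children hold the chopsticks for 10
#' seconds while opening and closing them twice per second, filmed at 30
#' frames per second.
#'
#' @param duration_s trial length in seconds (default 10).
#' @param open_close_hz open/close cycles per second (default 2).
#' @param fps video frame rate (default 30); must satisfy the Nyquist bound
#'   `fps >= 2 * open_close_hz`.
#' @param noise_sd_px isotropic Gaussian jitter added to every landmark
#'   coordinate, in px (default 1.5; chopstick endpoints receive half).
#' @param dropout_rate fraction of frames in `[0, 1)` whose chopstick
#'   detection fails (default 0.02).
#' @param seed RNG seed used when none is passed to the generator.
#' @return an object of class `trial_protocol`.
#' @export
trial_protocol <- function(duration_s = 10, open_close_hz = 2, fps = 30,
                           noise_sd_px = 1.5, dropout_rate = 0.02,
                           seed = NULL) {
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (fps < 2 * open_close_hz)
    stopf("protocol violates Nyquist: fps (%g) < 2 * open_close_hz (%g)",
          fps, 2 * open_close_hz)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  structure(list(duration_s = duration_s, open_close_hz = open_close_hz,
                 fps = fps, noise_sd_px = noise_sd_px,
                 dropout_rate = dropout_rate, seed = seed),
            class = "trial_protocol")
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat(sprintf("Trial protocol: %gs at %g fps, open/close %g Hz, noise sd %g px, dropout %g\n",
              x$duration_s, x$fps, x$open_close_hz, x$noise_sd_px, x$dropout_rate))
  invisible(x)
}
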