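#' Container for marker trajectories
#'
#' Time-indexed 3D positions for a named marker set. Coordinates follow the
#' convention x = direction of travel (anterior), y = vertical up,
#' z = mediolateral, all in metres, sampled at a constant rate. The left side
#' is the perturbed limb, the right side the unperturbed limb.
#'
#' @param positions Numeric array `frames x markers x 3` with marker dimnames
#'   and coordinate dimnames `c("x", "y", "z")`.
#' @param sampling_rate Sampling frequency in Hz.
#' @param side_labels Which side is the perturbed limb (default left).
#' @return An object of class `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(positions, sampling_rate,
                                  side_labels = c(perturbed = "L",
                                                  unperturbed = "R")) {
  if (!is.array(positions) || length(dim(positions)) != 3 ||
      dim(positions)[3] != 3) {
    stopf("positions must be a frames x markers x 3 array")
  }
  if (dim(positions)[1] < 2) stopf("need at least 2 frames")
  if (any(!is.finite(positions))) stopf("positions contain non-finite values")
  if (is.null(dimnames(positions)[[2]])) stopf("markers must be named")
  dimnames(positions)[[3]] <- c("x", "y", "z")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stopf("sampling_rate must be positive")
  }
  structure(list(positions = positions,
                 marker_names = dimnames(positions)[[2]],
                 sampling_rate = sampling_rate,
                 side_labels = side_labels),
            class = "marker_trajectory_set")
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("Marker trajectory set: %d frames x %d markers @ %g Hz (%.2f s)\n",
              d[1], d[2], x$sampling_rate, d[1] / x$sampling_rate))
  cat("  markers:", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth specification for a synthetic gait trial
#'
#' Parameters of the planar (sagittal-dominant) periodic walking template used
#' by [generate_marker_trial()]. Defaults describe preferred-speed overground
#' walking of a healthy older adult.
#'
#' @param gait_speed Average forward speed, m/s.
#' @param cadence Steps per minute (two steps per gait cycle).
#' @param trunk_lean Forward trunk lean from vertical, degrees (>= 0).
#' @param max_toe_height Peak toe marker height during swing, m.
#' @param leg_length Hip-marker height during quiet stance, m.
#' @param step_length Anteroposterior heel-to-heel step, m. `NULL` (default)
#'   derives the kinematically consistent value `gait_speed * 60 / cadence`;
#'   an explicit inconsistent value is honoured for foot placement, with a
#'   warning, and lets feet drift relative to the trunk.
#' @param sampling_rate Hz (motion-capture default 120).
#' @param n_cycles Number of full gait cycles (>= 1).
#' @param noise_sd Isotropic Gaussian marker jitter, m.
#' @return An object of class `gait_trial_spec`.
#' @export
gait_trial_spec <- function(gait_speed = 1.1, cadence = 112, trunk_lean = 3,
                            max_toe_height = 0.16, leg_length = 0.9,
                            step_length = NULL, sampling_rate = 120,
                            n_cycles = 3, noise_sd = 0.002) {
  pos <- c(gait_speed = gait_speed, cadence = cadence,
           max_toe_height = max_toe_height, leg_length = leg_length,
           sampling_rate = sampling_rate)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stopf("gait_speed, cadence, max_toe_height, leg_length and sampling_rate must be positive")
  }
  if (trunk_lean < 0 || noise_sd < 0) {
    stopf("trunk_lean and noise_sd must be non-negative")
  }
  if (!is_count(n_cycles)) stopf("n_cycles must be a positive integer")
  consistent <- gait_speed * 60 / cadence
  if (is.null(step_length)) {
    step_length <- consistent
  } else {
    if (step_length <= 0) stopf("step_length must be positive")
    if (abs(step_length - consistent) > 0.01 * consistent) {
      warning(sprintf(paste0("step_length %.3f m is inconsistent with ",
                             "gait_speed * step time = %.3f m; feet will ",
                             "drift relative to the trunk"),
                      step_length, consistent), call. = FALSE)
    }
  }
  structure(list(gait_speed = gait_speed, cadence = cadence,
                 trunk_lean = trunk_lean, max_toe_height = max_toe_height,
                 leg_length = leg_length, step_length = step_length,
                 sampling_rate = sampling_rate, n_cycles = as.integer(n_cycles),
                 noise_sd = noise_sd),
            class = "gait_trial_spec")
}

# Smooth 0 -> 1 blend on [0, 1].
blend01 <- function(s) 0.5 - 0.5 * cos(pi * pmin(pmax(s, 0), 1))

# Foot pitch (deg, + = toe above heel) over one foot cycle:
# heel-strike dorsiflexion decays in early stance, flat mid-stance,
# plantarflexion while pivoting over the toe in late stance, then swing
# dorsiflexion back towards the next heel strike.
FOOT_STANCE_FRAC <- 0.6
FOOT_TD_PITCH <- 15
FOOT_LO_PITCH <- -25

foot_pitch <- function(phase) {
  st <- FOOT_STANCE_FRAC
  p <- phase
  # swing: rapid early dorsiflexion out of the -25 deg push-off pose (the
  # toe leaves the ground with nonzero velocity, so liftoff is sharply
  # localized), then a slow drift to the +15 deg heel-strike pose
  s <- pmax((p - st) / (1 - st), 0)
  swing_pitch <- ifelse(s < 0.3,
                        FOOT_LO_PITCH + (10 - FOOT_LO_PITCH) * s / 0.3,
                        10 + (FOOT_TD_PITCH - 10) * (s - 0.3) / 0.7)
  ifelse(p < 0.25 * st,
         FOOT_TD_PITCH * (1 - blend01(p / (0.25 * st))),
  ifelse(p < 0.7 * st, 0,
  ifelse(p < st, FOOT_LO_PITCH * blend01((p - 0.7 * st) / (0.3 * st)),
         swing_pitch)))
}

# Unit-height heel elevation profile over swing phase s in [0, 1]: rises
# steeply after push-off, peaks in the first half of swing (the foot then
# extends forward rather than up), and descends linearly into heel strike so
# touchdown is sharply localized in time.
swing_bump <- function(s) {
  core <- function(u) sin(pi * pmin(u, 1)^0.55)^1.5
  tail_from <- 0.85
  ifelse(s <= tail_from, core(s),
         core(tail_from) * (1 - s) / (1 - tail_from))
}

# Fixed heel-strike approach ramp (m): lifts the heel slightly in late swing
# and drops it briskly (~0.4 m/s at typical swing times) into touchdown, so
# ground contact is a sharp corner rather than a tangent — as in real
# heel-strike kinematics.
strike_ramp <- function(s) {
  h <- 0.025
  ifelse(s < 0.55, 0,
  ifelse(s < 0.85, h * blend01((s - 0.55) / 0.3),
         h * (1 - s) / 0.15))
}

# Heel and toe trajectories of one foot for a vector of times. `td_x` maps
# cycle index j to the heel x at that cycle's touchdown. `swing_amp` is the
# extra heel-height bump amplitude during swing.
foot_track <- function(t, t0, cycle_time, stride, td_x0, foot_len,
                       ground_y, swing_amp) {
  ph_raw <- (t - t0) / cycle_time
  j <- floor(ph_raw)
  phase <- ph_raw - j
  st <- FOOT_STANCE_FRAC
  pitch <- foot_pitch(phase) * pi / 180
  hx <- td_x0 + j * stride
  heel_x <- heel_y <- numeric(length(t))
  early <- phase < 0.7 * st
  late <- !early & phase < st
  swing <- phase >= st

  # heel planted (dorsiflexion handled through the toe)
  heel_x[early] <- hx[early]
  heel_y[early] <- ground_y
  # pivot over the planted toe
  toe_x_fix <- hx + foot_len
  heel_x[late] <- toe_x_fix[late] - foot_len * cos(pitch[late])
  heel_y[late] <- ground_y - foot_len * sin(pitch[late])
  # swing: blend from liftoff pose to next touchdown, plus a height bump
  s <- (phase - st) / (1 - st)
  lo_pitch <- FOOT_LO_PITCH * pi / 180
  x_start <- toe_x_fix - foot_len * cos(lo_pitch)
  y_start <- ground_y - foot_len * sin(lo_pitch)
  heel_x[swing] <- x_start[swing] +
    (hx[swing] + stride - x_start[swing]) * blend01(s[swing])
  heel_y[swing] <- ground_y + (y_start - ground_y) * (1 - blend01(s[swing])) +
    swing_amp * swing_bump(s[swing]) + strike_ramp(s[swing])

  toe_x <- heel_x + foot_len * cos(pitch)
  toe_y <- heel_y + foot_len * sin(pitch)
  # ankle sits above the heel, perpendicular to the sole
  ankle_x <- heel_x - 0.08 * sin(pitch) + 0.04 * cos(pitch)
  ankle_y <- heel_y + 0.08 * cos(pitch) + 0.04 * sin(pitch)
  list(heel_x = heel_x, heel_y = heel_y, toe_x = toe_x, toe_y = toe_y,
       ankle_x = ankle_x, ankle_y = ankle_y, phase = phase)
}

# Peak toe height in swing for a given heel bump amplitude (noise-free).
swing_toe_peak <- function(amp, cycle_time, stride, foot_len, ground_y) {
  s <- seq(0, 1, length.out = 400)
  t <- (FOOT_STANCE_FRAC + s * (1 - FOOT_STANCE_FRAC)) * cycle_time
  tr <- foot_track(t, 0, cycle_time, stride, 0, foot_len, ground_y, amp)
  max(tr$toe_y)
}

# Two-link (thigh/shank) inverse kinematics: knee position given hip and
# ankle, bending anteriorly; clamps to a straight leg when out of reach.
knee_ik <- function(hip_x, hip_y, ankle_x, ankle_y, thigh, shank) {
  dx <- ankle_x - hip_x
  dy <- ankle_y - hip_y
  d <- sqrt(dx^2 + dy^2)
  d <- pmin(d, thigh + shank - 1e-9)
  a <- (thigh^2 - shank^2 + d^2) / (2 * d)
  h <- sqrt(pmax(thigh^2 - a^2, 0))
  ux <- dx / d
  uy <- dy / d
  # perpendicular chosen so the knee bends forward (anterior) when the
  # hip-ankle axis points downwards
  list(x = hip_x + a * ux - h * uy,
       y = hip_y + a * uy + h * ux)
}

#' Generate a synthetic marker-level gait trial
#'
#' Builds a periodic, kinematically plausible walking record for a 12-marker
#' set (heel, toe, ankle, knee, hip, shoulder on both sides) from
#' sinusoid-composed limb trajectories: feet alternate a 60% stance / 40%
#' swing cycle with heel-strike and push-off foot pitch, knees are placed by
#' two-link inverse kinematics between hip and ankle, and the trunk leans
#' forward by a constant angle. Before noise, the ground-truth average gait
#' speed, trunk angle (90 - `trunk_lean` degrees from horizontal), maximum
#' swing toe height, cadence and step length equal the spec values; the
#' generator solves the swing heel profile numerically so the toe peak lands
#' exactly on `max_toe_height`.
#'
#' The true gait-event frames of an interior gait cycle are attached as
#' `attr(, "ground_truth")$events`, together with the nominal feature values,
#' so event detection and feature extraction can be validated end to end.
#'
#' @param spec A [gait_trial_spec()].
#' @param seed Integer seed (used only for the marker jitter).
#' @return A [marker_trajectory_set()] with a `ground_truth` attribute.
#' @examples
#' trial <- generate_marker_trial(gait_trial_spec(noise_sd = 0), seed = 1)
#' attr(trial, "ground_truth")$events
#' @export
generate_marker_trial <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "gait_trial_spec"))
  if (spec$n_cycles < 1) stopf("n_cycles must be >= 1")
  v <- spec$gait_speed
  step_time <- 60 / spec$cadence
  cycle_time <- 2 * step_time
  stride <- 2 * spec$step_length
  rate <- spec$sampling_rate
  L <- spec$leg_length
  foot_len <- 0.22
  ground_y <- 0.02
  thigh <- 0.47 * L
  shank <- 0.425 * L
  hip_w <- 0.20
  sho_w <- 0.30
  trunk_len <- 0.50
  lean <- spec$trunk_lean * pi / 180

  pad <- 0.25 * cycle_time
  duration <- spec$n_cycles * cycle_time + 2 * pad
  nf <- floor(duration * rate) + 1
  t <- (seq_len(nf) - 1) / rate

  # swing heel-bump amplitude solved so that max swing toe height is exact
  f_amp <- function(a) swing_toe_peak(a, cycle_time, stride, foot_len,
                                      ground_y) - spec$max_toe_height
  amp <- tryCatch(
    stats::uniroot(f_amp, c(-0.5, 1), tol = 1e-10)$root,
    error = function(e) stopf(
      "max_toe_height %.3f m is unreachable for this foot geometry",
      spec$max_toe_height))

  # right (unperturbed) foot touches down at t = pad, left offset by one step
  x_r0 <- v * pad + spec$step_length
  x_l0 <- x_r0 + spec$step_length
  rt <- foot_track(t, pad, cycle_time, stride, x_r0, foot_len, ground_y, amp)
  lt <- foot_track(t, pad + step_time, cycle_time, stride, x_l0, foot_len,
                   ground_y, amp)

  # pelvis: constant forward speed plus a zero-mean oscillation at step rate
  osc_x <- 0.06 * v * cycle_time / (4 * pi)
  hip_x <- v * t + spec$step_length / 2 + osc_x * sin(4 * pi * (t - pad) / cycle_time)
  hip_y <- 0.94 * L + ground_y + 0.015 * cos(4 * pi * (t - pad) / cycle_time)
  sway_z <- 0.02 * sin(2 * pi * (t - pad) / cycle_time)

  sho_x <- hip_x + trunk_len * sin(lean)
  sho_y <- hip_y + trunk_len * cos(lean)

  kl <- knee_ik(hip_x, hip_y, lt$ankle_x, lt$ankle_y, thigh, shank)
  kr <- knee_ik(hip_x, hip_y, rt$ankle_x, rt$ankle_y, thigh, shank)

  z <- function(base) base + sway_z
  pos <- array(0, dim = c(nf, 12, 3),
               dimnames = list(NULL,
                               c("L_heel", "L_toe", "L_ankle", "L_knee",
                                 "L_hip", "L_shoulder",
                                 "R_heel", "R_toe", "R_ankle", "R_knee",
                                 "R_hip", "R_shoulder"),
                               c("x", "y", "z")))
  fill <- function(name, x, y, zbase) {
    pos[, name, "x"] <<- x
    pos[, name, "y"] <<- y
    pos[, name, "z"] <<- z(zbase)
  }
  fill("L_heel", lt$heel_x, lt$heel_y, -0.06)
  fill("L_toe", lt$toe_x, lt$toe_y, -0.06)
  fill("L_ankle", lt$ankle_x, lt$ankle_y, -0.06)
  fill("L_knee", kl$x, kl$y, -0.08)
  fill("L_hip", hip_x, hip_y, -hip_w / 2)
  fill("L_shoulder", sho_x, sho_y, -sho_w / 2)
  fill("R_heel", rt$heel_x, rt$heel_y, 0.06)
  fill("R_toe", rt$toe_x, rt$toe_y, 0.06)
  fill("R_ankle", rt$ankle_x, rt$ankle_y, 0.06)
  fill("R_knee", kr$x, kr$y, 0.08)
  fill("R_hip", hip_x, hip_y, hip_w / 2)
  fill("R_shoulder", sho_x, sho_y, sho_w / 2)

  if (spec$noise_sd > 0) {
    pos <- with_seed(seed, pos + stats::rnorm(length(pos), 0, spec$noise_sd))
  }
  traj <- marker_trajectory_set(pos, sampling_rate = rate)

  frame_at <- function(tt) round(tt * rate) + 1L
  st <- FOOT_STANCE_FRAC
  truth <- list(
    events = gait_events(
      pre_TD = frame_at(pad),
      LO = frame_at(pad + step_time + st * cycle_time - cycle_time),
      post_TD = frame_at(pad + step_time),
      next_TD = frame_at(pad + cycle_time)),
    gait_speed = v,
    trunk_angle = 90 - spec$trunk_lean,
    toe_clearance = spec$max_toe_height,
    step_time = step_time,
    swing_time = (1 - st) * cycle_time,
    step_length = spec$step_length,
    cycle_time = cycle_time)
  attr(traj, "ground_truth") <- truth
  traj
}
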