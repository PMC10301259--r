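#' Extract the 40 gait features from one gait cycle
#'
#' Computes the full 40-feature vector (see [feature_names_full()]) over the
#' cycle bounded by `events`: COM-based gait speeds (average speed as cycle
#' displacement over cycle time, maximum and instantaneous anteroposterior
#' COM velocity), COM position relative to the posterior base of support and
#' margin of stability at the three events, step/swing/cycle timing and
#' cadence, step geometry, swing-phase foot clearance, and sagittal trunk,
#' hip, knee and foot angles at the events plus the swing/cycle extremes.
#'
#' Flexion extremes follow clinical convention on the horizontal-referenced
#' angles: "Max knee flexion" and "Max trunk flexion" report the cycle
#' minimum of the respective angle (deeper flexion = smaller angle; a
#' straight knee is 180), while "Max hip flexion" and "Max foot angle" report
#' maxima. All angles are sagittal (x-y) plane only.
#'
#' @param traj A [marker_trajectory_set()].
#' @param events A [gait_events()] valid for `traj`.
#' @param model A [body_model()]; if its `leg_length` is `NULL`, the median
#'   mid-hip marker height over the cycle is used for the MOS pendulum
#'   length.
#' @return Named numeric vector of exactly 40 features, in
#'   [feature_names_full()] order. Units: speeds m/s, lengths m, times s,
#'   cadence steps/min, angles degrees.
#' @export
extract_features <- function(traj, events, model = default_body_model()) {
  stopifnot(inherits(traj, "marker_trajectory_set"),
            inherits(events, "gait_events"))
  pos <- traj$positions
  nf <- dim(pos)[1]
  if (events$next_TD > nf) stopf("events extend past the end of the record")
  rate <- traj$sampling_rate
  cyc <- events$pre_TD:events$next_TD
  swing <- events$LO:events$post_TD
  ev <- c(pre_TD = events$pre_TD, LO = events$LO, post_TD = events$post_TD)

  com <- compute_com(traj, model)
  speed <- com$velocity[, "x"]
  l <- model$leg_length %||%
    stats::median(marker_xyz(traj, "mid_hip")[cyc, "y"])

  heel_l <- marker_xyz(traj, "L_heel")
  heel_r <- marker_xyz(traj, "R_heel")
  toe_l <- marker_xyz(traj, "L_toe")
  bos_min <- pmin(heel_l[, "x"], heel_r[, "x"])
  com_rel <- com$position[, "x"] - bos_min
  mos <- margin_of_stability(com$position[, "x"], bos_min, speed, model,
                             leg_length = l)

  step_time <- (events$post_TD - events$pre_TD) / rate
  cycle_time <- (events$next_TD - events$pre_TD) / rate
  mid_swing <- swing[swing >= swing[1] + length(swing) / 3 &
                       swing <= swing[1] + 2 * length(swing) / 3]

  ang <- function(marker_d, marker_p, frames) {
    segment_angle(marker_xyz(traj, marker_d)[frames, c("x", "y")],
                  marker_xyz(traj, marker_p)[frames, c("x", "y")])
  }
  kang <- function(side, frames) {
    knee_angle(marker_xyz(traj, paste0(side, "_hip"))[frames, c("x", "y")],
               marker_xyz(traj, paste0(side, "_knee"))[frames, c("x", "y")],
               marker_xyz(traj, paste0(side, "_ankle"))[frames, c("x", "y")])
  }
  trunk <- ang("mid_shoulder", "mid_hip", cyc)
  hip_l_sw <- ang("L_hip", "L_knee", swing)
  knee_l_sw <- kang("L", swing)
  foot_l_sw <- ang("L_toe", "L_heel", swing)

  out <- c(
    "Gait speed in gait cycle" =
      unname(com$position[events$next_TD, "x"] -
               com$position[events$pre_TD, "x"]) / cycle_time,
    "Max gait speed in gait cycle" = max(speed[cyc]),
    "COM velocity at pre-TD" = unname(speed[ev["pre_TD"]]),
    "COM velocity at LO" = unname(speed[ev["LO"]]),
    "COM velocity at post-TD" = unname(speed[ev["post_TD"]]),
    "COM position at pre-TD" = unname(com_rel[ev["pre_TD"]]),
    "COM position at LO" = unname(com_rel[ev["LO"]]),
    "COM position at post-TD" = unname(com_rel[ev["post_TD"]]),
    "MOS at pre-TD" = unname(mos[ev["pre_TD"]]),
    "MOS at LO" = unname(mos[ev["LO"]]),
    "MOS at post-TD" = unname(mos[ev["post_TD"]]),
    "Step time" = step_time,
    "Swing time" = (events$post_TD - events$LO) / rate,
    "Gait cycle duration" = cycle_time,
    "Cadence" = 60 / step_time,
    "Step length" = abs(unname(heel_l[events$post_TD, "x"] -
                                 heel_r[events$pre_TD, "x"])),
    "Stride length" = abs(unname(heel_r[events$next_TD, "x"] -
                                   heel_r[events$pre_TD, "x"])),
    "Step width" = abs(unname(heel_l[events$post_TD, "z"] -
                                heel_r[events$pre_TD, "z"])),
    "Toe clearance" = max(toe_l[swing, "y"]),
    "Min toe clearance" = min(toe_l[mid_swing, "y"]),
    "Max heel height in swing phase" = max(heel_l[swing, "y"]),
    "Trunk angle at LO" = unname(trunk[match(events$LO, cyc)]),
    "Trunk angle at post-TD" = unname(trunk[match(events$post_TD, cyc)]),
    "Max trunk flexion in gait cycle" = min(trunk),
    "L hip angle at LO" = ang("L_hip", "L_knee", events$LO),
    "L hip angle at post-TD" = ang("L_hip", "L_knee", events$post_TD),
    "R hip angle at LO" = ang("R_hip", "R_knee", events$LO),
    "R hip angle at post-TD" = ang("R_hip", "R_knee", events$post_TD),
    "L knee angle at LO" = kang("L", events$LO),
    "L knee angle at post-TD" = kang("L", events$post_TD),
    "R knee angle at LO" = kang("R", events$LO),
    "R knee angle at post-TD" = kang("R", events$post_TD),
    "L foot angle at LO" = ang("L_toe", "L_heel", events$LO),
    "L foot angle at post-TD" = ang("L_toe", "L_heel", events$post_TD),
    "R foot angle at LO" = ang("R_toe", "R_heel", events$LO),
    "R foot angle at post-TD" = ang("R_toe", "R_heel", events$post_TD),
    "Max hip flexion in swing phase" = max(hip_l_sw),
    "Max knee flexion in swing phase" = min(knee_l_sw),
    "Max foot angle in swing phase" = max(foot_l_sw),
    "COM vertical excursion in gait cycle" =
      diff(range(com$position[cyc, "y"])))

  stopifnot(identical(names(out), feature_names_full()),
            all(is.finite(out)))
  out
}

#' Extract features for a batch of trials into a feature table
#'
#' Convenience wrapper: detects events and extracts the 40-feature vector
#' for each trajectory, returning one row per trial.
#'
#' @param trials List of [marker_trajectory_set()] objects.
#' @param model A [body_model()].
#' @param outcome Optional vector of class labels, one per trial.
#' @return A `data.frame` with 40 feature columns (plus `outcome` if given).
#' @export
extract_feature_table <- function(trials, model = default_body_model(),
                                  outcome = NULL) {
  rows <- lapply(trials, function(tr) {
    extract_features(tr, detect_gait_events(tr), model)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  if (!is.null(outcome)) {
    stopifnot(length(outcome) == nrow(out))
    out$outcome <- factor(outcome, levels = outcome_levels())
  }
  rownames(out) <- NULL
  out
}
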