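#' Gait-event frame indices
#'
#' The event triad bounding the analysed gait cycle: unperturbed (right) foot
#' touchdown (`pre_TD`), perturbed (left) foot liftoff (`LO`) and touchdown
#' (`post_TD`), and the next right touchdown (`next_TD`). Frames are 1-based;
#' intervals are closed at both event frames.
#'
#' @param pre_TD,LO,post_TD,next_TD Frame indices with
#'   `pre_TD < LO < post_TD < next_TD`.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(pre_TD, LO, post_TD, next_TD) {
  ev <- c(pre_TD = as.integer(pre_TD), LO = as.integer(LO),
          post_TD = as.integer(post_TD), next_TD = as.integer(next_TD))
  if (any(ev < 1)) stopf("event frames must be >= 1")
  if (!all(diff(ev) > 0)) {
    stopf("event ordering violated: need pre_TD < LO < post_TD < next_TD, got %s",
          paste(ev, collapse = ", "))
  }
  structure(as.list(ev), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events (frames): pre-TD %d | LO %d | post-TD %d | next TD %d\n",
              x$pre_TD, x$LO, x$post_TD, x$next_TD))
  invisible(x)
}

moving_average <- function(x, k = 5) {
  if (length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) ->
    y
  # keep the ends unsmoothed rather than NA
  y[is.na(y)] <- x[is.na(y)]
  y
}

# Ground-contact bouts for a vertical marker trace: frames within `margin`
# of the record minimum, lightly smoothed, kept if at least `min_run` long.
contact_runs <- function(y, margin, min_run) {
  ys <- moving_average(y)
  contact <- ys < (min(ys) + margin)
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  list(starts = starts[keep], ends = ends[keep], smooth = ys)
}

# Touchdowns: first frame of each contact bout, refined forward to where the
# trace reaches its in-bout plateau (the height threshold is crossed during
# the final descent, a few frames before the foot is actually down).
contact_starts <- function(y, margin, min_run, refine_tol = 0.0025) {
  runs <- contact_runs(y, margin, min_run)
  td <- mapply(function(s, e) {
    # the in-bout median is the flat-contact level (robust to jitter, unlike
    # the bout minimum); refine on the raw trace so smoothing does not drag
    # the crossing into the final descent
    level <- stats::median(y[s:e])
    s + which(y[s:e] <= level + refine_tol)[1] - 1L
  }, runs$starts, runs$ends)
  td <- td[runs$starts > 1L]  # a run starting at frame 1 is not a touchdown
  as.integer(td)
}

# Liftoffs: onset of sustained rise at the end of each contact bout,
# refined back to the last frame still on the in-bout plateau.
contact_ends <- function(y, margin, min_run, refine_tol = 0.0025) {
  runs <- contact_runs(y, margin, min_run)
  lo_f <- mapply(function(s, e) {
    level <- stats::median(y[s:e])
    on_plateau <- which(y[s:e] <= level + refine_tol)
    s + on_plateau[length(on_plateau)] - 1L
  }, runs$starts, runs$ends)
  lo_f <- lo_f[runs$ends < length(y)]  # run ending at the last frame: no liftoff
  as.integer(lo_f) + 1L  # first frame of the rise
}

#' Detect gait events from marker kinematics
#'
#' Kinematics-only event detection (the laboratory alternative uses force
#' plates): touchdown is the first frame of a sustained ground-contact bout
#' of the heel marker (heel height within `height_margin` of its record
#' minimum, after light smoothing), and liftoff is the onset of sustained
#' vertical rise of the toe marker at the end of its contact bout. The
#' returned triad is the first right-foot cycle that fully contains a left
#' liftoff and left touchdown.
#'
#' @param traj A [marker_trajectory_set()] with >= 1.5 gait cycles of data.
#' @param height_margin Contact threshold above the per-marker minimum
#'   height, m.
#' @param min_run Minimum contact-bout length, frames.
#' @return A [gait_events()] object.
#' @export
detect_gait_events <- function(traj, height_margin = 0.03, min_run = 5) {
  stopifnot(inherits(traj, "marker_trajectory_set"))
  pos <- traj$positions
  need <- c("L_heel", "L_toe", "R_heel")
  miss <- setdiff(need, dimnames(pos)[[2]])
  if (length(miss)) stopf("markers missing for event detection: %s",
                          paste(miss, collapse = ", "))
  degenerate <- function(y) diff(range(y)) < 2 * height_margin
  r_heel <- pos[, "R_heel", "y"]
  l_heel <- pos[, "L_heel", "y"]
  l_toe <- pos[, "L_toe", "y"]
  if (degenerate(r_heel)) {
    stopf("no detectable gait cycle for the right (unperturbed) limb")
  }
  if (degenerate(l_heel) || degenerate(l_toe)) {
    stopf("no detectable gait cycle for the left (perturbed) limb")
  }
  r_td <- contact_starts(r_heel, height_margin, min_run)
  l_td <- contact_starts(l_heel, height_margin, min_run)
  l_lo <- contact_ends(l_toe, height_margin, min_run)
  if (length(r_td) < 2) {
    stopf("no detectable gait cycle for the right (unperturbed) limb")
  }
  if (length(l_td) < 1 || length(l_lo) < 1) {
    stopf("no detectable gait cycle for the left (perturbed) limb")
  }
  for (i in seq_len(length(r_td) - 1)) {
    pre <- r_td[i]
    nxt <- r_td[i + 1]
    lo <- l_lo[l_lo > pre & l_lo < nxt]
    if (!length(lo)) next
    td <- l_td[l_td > lo[1] & l_td < nxt]
    if (!length(td)) next
    return(gait_events(pre, lo[1], td[1], nxt))
  }
  stopf("no right-foot cycle contains a left liftoff and touchdown")
}
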