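#' Sagittal-plane segment angle
#'
#' Angle of the proximal-to-distal segment axis against the horizontal, as
#' `atan2(distal_y - proximal_y, distal_x - proximal_x)` in degrees, in
#' `(-180, 180]`. With x anterior and y up, a vertical segment reads 90 and a
#' horizontal, forward-pointing one reads 0. Used for the trunk
#' (shoulder over hip), thigh (hip over knee) and foot (toe over heel).
#'
#' @param distal,proximal Length-2 numeric `(x, y)` points, or matrices with
#'   two columns for vectorized evaluation.
#' @return Angle(s) in degrees.
#' @examples
#' segment_angle(c(0, 1), c(0, 0))  # vertical: 90
#' segment_angle(c(1, -1), c(0, 0)) # -45
#' @export
segment_angle <- function(distal, proximal) {
  d <- rbind(distal) - rbind(proximal)
  if (any(abs(d[, 1]) < 1e-12 & abs(d[, 2]) < 1e-12)) {
    stopf("coincident points: segment direction undefined")
  }
  unname(atan2(d[, 2], d[, 1]) * 180 / pi)
}

#' Sagittal knee angle
#'
#' Angle between thigh and shank as
#' `atan2(knee_y - ankle_y, knee_x - ankle_x) + (180 - theta_hip)` with
#' `theta_hip` the thigh segment angle ([segment_angle()] of hip over knee).
#' A straight, vertical leg reads 180; flexion reduces the value.
#'
#' @param hip,knee,ankle Length-2 `(x, y)` points or two-column matrices.
#' @return Knee angle(s) in degrees.
#' @export
knee_angle <- function(hip, knee, ankle) {
  shank <- segment_angle(knee, ankle)
  theta_hip <- segment_angle(hip, knee)
  shank + (180 - theta_hip)
}

#' Anteroposterior margin of stability
#'
#' Extrapolated-centre-of-mass stability margin: the COM offset from the
#' posterior base-of-support boundary plus the COM velocity scaled by the
#' inverted-pendulum eigenfrequency,
#' `MOS = (com_x - bos_min_x) + vcom_x / sqrt(g / l)`,
#' with `g` the gravitational acceleration and `l` the leg length. Computed
#' on the anteroposterior axis only; `bos_min_x` is the rear heel marker at
#' the evaluation instant.
#'
#' @param com_x COM anteroposterior position, m.
#' @param bos_min_x Posterior base-of-support boundary (rear heel x), m.
#' @param vcom_x COM anteroposterior velocity, m/s.
#' @param model A [body_model()] providing `g` and `leg_length`.
#' @param leg_length Overrides the model leg length if given.
#' @return Margin of stability, m (larger = more stable forward).
#' @examples
#' m <- body_model(default_body_model()$segments, leg_length = 0.9)
#' margin_of_stability(0.1, 0, 0.33, m)  # ~0.200
#' @export
margin_of_stability <- function(com_x, bos_min_x, vcom_x, model,
                                leg_length = NULL) {
  stopifnot(inherits(model, "body_model"))
  l <- leg_length %||% model$leg_length
  if (is.null(l) || l <= 0) stopf("leg length must be positive")
  (com_x - bos_min_x) + vcom_x / sqrt(model$g / l)
}
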