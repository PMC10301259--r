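#' Segmental body model for centre-of-mass computation
#'
#' A 13-segment rigid-body model with sex-dependent segmental inertial
#' parameters in the style of the standard adjusted anthropometric tables
#' (de Leva-type): each segment is defined by a proximal and a distal marker,
#' a mass fraction of total body mass, and the fractional location of the
#' segment centre of mass along the proximal-to-distal axis. Mass fractions
#' are normalized to sum to exactly 1.
#'
#' @param segments `data.frame` with columns `name`, `proximal`, `distal`,
#'   `mass_fraction`, `com_fraction`.
#' @param leg_length Leg length in m used by the margin-of-stability
#'   pendulum scaling; `NULL` defers to the hip-marker height of the record
#'   being analysed.
#' @param g Gravitational acceleration, m/s^2.
#' @param sex `"female"` or `"male"` (tags which parameter set is in use).
#' @return An object of class `body_model`.
#' @export
body_model <- function(segments, leg_length = NULL, g = 9.81,
                       sex = c("female", "male")) {
  sex <- match.arg(sex)
  need <- c("name", "proximal", "distal", "mass_fraction", "com_fraction")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    stopf("segments must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  }
  if (any(segments$mass_fraction < 0)) stopf("mass fractions must be >= 0")
  if (any(segments$com_fraction < 0 | segments$com_fraction > 1)) {
    stopf("COM fractions must lie in [0, 1]")
  }
  total <- sum(segments$mass_fraction)
  if (abs(total - 1) > 1e-6) {
    segments$mass_fraction <- segments$mass_fraction / total
  }
  if (!is.null(leg_length) && leg_length <= 0) stopf("leg_length must be > 0")
  structure(list(segments = segments, leg_length = leg_length, g = g,
                 sex = sex),
            class = "body_model")
}

# Mass fractions per segment (percent of body mass) and COM location along
# the proximal->distal axis, by sex. Head/arm segments anchor to the
# shoulder markers of the reduced 12-marker set, so their COM fraction is 0.
segment_parameters <- function(sex) {
  if (sex == "male") {
    mass <- c(head = 6.94, trunk = 32.29, pelvis = 11.17,
              upper_arm = 2.71, forearm_hand = 2.23,
              thigh = 14.16, shank = 4.33, foot = 1.37)
    com <- c(head = 0, trunk = 0.45, pelvis = 0.5,
             upper_arm = 0, forearm_hand = 0,
             thigh = 0.41, shank = 0.44, foot = 0.44)
  } else {
    mass <- c(head = 6.68, trunk = 30.10, pelvis = 12.47,
              upper_arm = 2.55, forearm_hand = 1.94,
              thigh = 14.78, shank = 4.81, foot = 1.29)
    com <- c(head = 0, trunk = 0.45, pelvis = 0.5,
             upper_arm = 0, forearm_hand = 0,
             thigh = 0.36, shank = 0.44, foot = 0.40)
  }
  list(mass = mass / 100, com = com)
}

#' Default 13-segment body model for the reduced marker set
#'
#' Maps the 13 segments onto the 12-marker set produced by
#' [generate_marker_trial()] (heel, toe, ankle, knee, hip, shoulder
#' bilaterally) plus the derived `mid_hip` / `mid_shoulder` virtual markers.
#' Head and arm segments, whose own markers are absent from the reduced set,
#' are carried as point masses at the shoulder markers.
#'
#' @inheritParams body_model
#' @export
default_body_model <- function(sex = c("female", "male"), leg_length = NULL,
                               g = 9.81) {
  sex <- match.arg(sex)
  par <- segment_parameters(sex)
  seg <- function(name, kind, proximal, distal) {
    data.frame(name = name, proximal = proximal, distal = distal,
               mass_fraction = par$mass[[kind]],
               com_fraction = par$com[[kind]])
  }
  segments <- rbind(
    seg("head", "head", "mid_shoulder", "mid_shoulder"),
    seg("trunk", "trunk", "mid_shoulder", "mid_hip"),
    seg("pelvis", "pelvis", "mid_hip", "mid_hip"),
    seg("upper_arm_L", "upper_arm", "L_shoulder", "L_shoulder"),
    seg("upper_arm_R", "upper_arm", "R_shoulder", "R_shoulder"),
    seg("forearm_hand_L", "forearm_hand", "L_shoulder", "L_shoulder"),
    seg("forearm_hand_R", "forearm_hand", "R_shoulder", "R_shoulder"),
    seg("thigh_L", "thigh", "L_hip", "L_knee"),
    seg("thigh_R", "thigh", "R_hip", "R_knee"),
    seg("shank_L", "shank", "L_knee", "L_ankle"),
    seg("shank_R", "shank", "R_knee", "R_ankle"),
    seg("foot_L", "foot", "L_heel", "L_toe"),
    seg("foot_R", "foot", "R_heel", "R_toe"))
  body_model(segments, leg_length = leg_length, g = g, sex = sex)
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("Body model (%s): %d segments, g = %g m/s^2, leg length = %s\n",
              x$sex, nrow(x$segments), x$g,
              if (is.null(x$leg_length)) "from data" else
                sprintf("%.3f m", x$leg_length)))
  invisible(x)
}

#' Serialize a body model to YAML
#' @param model A [body_model()].
#' @param path File path.
#' @export
write_body_model <- function(model, path) {
  stopifnot(inherits(model, "body_model"))
  yaml::write_yaml(list(sex = model$sex, g = model$g,
                        leg_length = model$leg_length,
                        segments = lapply(seq_len(nrow(model$segments)),
                                          function(i) as.list(model$segments[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_body_model
#' @export
read_body_model <- function(path) {
  obj <- yaml::read_yaml(path)
  segments <- do.call(rbind, lapply(obj$segments, as.data.frame))
  body_model(segments, leg_length = obj$leg_length, g = obj$g, sex = obj$sex)
}

# Positions for a marker name, allowing the derived bilateral midpoints.
marker_xyz <- function(traj, name) {
  pos <- traj$positions
  if (name %in% dimnames(pos)[[2]]) return(pos[, name, , drop = TRUE])
  if (name == "mid_hip") {
    return((marker_xyz(traj, "L_hip") + marker_xyz(traj, "R_hip")) / 2)
  }
  if (name == "mid_shoulder") {
    return((marker_xyz(traj, "L_shoulder") + marker_xyz(traj, "R_shoulder")) / 2)
  }
  stopf("marker '%s' not found in the trajectory set", name)
}

#' Whole-body centre of mass from a segmental model
#'
#' Per-frame COM as the mass-fraction-weighted sum of segment centres of
#' mass (each at `com_fraction` along its proximal-to-distal marker axis),
#' and its velocity by central differences at the sampling rate (one-sided
#' differences at the record ends).
#'
#' @param traj A [marker_trajectory_set()].
#' @param model A [body_model()]; missing markers raise an error naming the
#'   first one missing.
#' @return List with `position` and `velocity`, both `frames x 3` matrices
#'   (columns x, y, z; m and m/s).
#' @export
compute_com <- function(traj, model) {
  stopifnot(inherits(traj, "marker_trajectory_set"),
            inherits(model, "body_model"))
  nf <- dim(traj$positions)[1]
  com <- matrix(0, nf, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(model$segments))) {
    s <- model$segments[i, ]
    prox <- marker_xyz(traj, s$proximal)
    dist <- marker_xyz(traj, s$distal)
    com <- com + s$mass_fraction * (prox + s$com_fraction * (dist - prox))
  }
  vel <- apply(com, 2, central_diff, rate = traj$sampling_rate)
  colnames(vel) <- c("x", "y", "z")
  list(position = com, velocity = vel)
}

central_diff <- function(x, rate) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  if (n > 2) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  v
}
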