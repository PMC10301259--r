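#' Names of the 40 gait features
#'
#' The full feature set computed by [extract_features()] from one gait cycle:
#' centre-of-mass (COM) speeds and state at the three gait events (unperturbed
#' touchdown pre-TD, perturbed liftoff LO, perturbed touchdown post-TD),
#' margin of stability, step timing and geometry, foot clearance, and
#' sagittal-plane trunk, hip, knee and foot angles. The left limb is the
#' perturbed limb, the right one the unperturbed limb. Angle conventions:
#' all angles are measured against the horizontal in the sagittal plane, in
#' degrees; a straight knee reads 180. "Max ... flexion" features report the
#' angle at the instant of deepest flexion (so the knee value is the cycle
#' minimum, the hip value the maximum).
#'
#' @return Character vector of 40 unique feature names, in canonical order.
#' @export
feature_names_full <- function() {
  c(
    "Gait speed in gait cycle",        # mean AP COM velocity, m/s
    "Max gait speed in gait cycle",
    "COM velocity at pre-TD",
    "COM velocity at LO",
    "COM velocity at post-TD",
    "COM position at pre-TD",          # AP COM minus posterior BOS, m
    "COM position at LO",
    "COM position at post-TD",
    "MOS at pre-TD",                   # extrapolated-COM margin, m
    "MOS at LO",
    "MOS at post-TD",
    "Step time",                       # s
    "Swing time",
    "Gait cycle duration",
    "Cadence",                         # steps/min
    "Step length",                     # m
    "Stride length",
    "Step width",
    "Toe clearance",                   # max toe height in swing, m
    "Min toe clearance",               # mid-swing minimum toe height, m
    "Max heel height in swing phase",
    "Trunk angle at LO",               # deg from horizontal
    "Trunk angle at post-TD",
    "Max trunk flexion in gait cycle",
    "L hip angle at LO",
    "L hip angle at post-TD",
    "R hip angle at LO",
    "R hip angle at post-TD",
    "L knee angle at LO",
    "L knee angle at post-TD",
    "R knee angle at LO",
    "R knee angle at post-TD",
    "L foot angle at LO",
    "L foot angle at post-TD",
    "R foot angle at LO",
    "R foot angle at post-TD",
    "Max hip flexion in swing phase",
    "Max knee flexion in swing phase",
    "Max foot angle in swing phase",
    "COM vertical excursion in gait cycle"
  )
}
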