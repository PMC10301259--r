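toy_traj <- function(f) {
  # 2-marker record built from a frame-indexed generator function
  nf <- 10
  pos <- array(NA_real_, dim = c(nf, 2, 3),
               dimnames = list(NULL, c("A", "B"), c("x", "y", "z")))
  for (i in seq_len(nf)) {
    p <- f(i)
    pos[i, "A", ] <- p$A
    pos[i, "B", ] <- p$B
  }
  marker_trajectory_set(pos, sampling_rate = 100)
}

test_that("segment angles follow the atan2 convention", {
  expect_equal(segment_angle(c(0, 1), c(0, 0)), 90)
  expect_equal(segment_angle(c(1, 0), c(0, 0)), 0)
  expect_equal(segment_angle(c(1, -1), c(0, 0)), -45)
  expect_equal(segment_angle(c(-1, 0), c(0, 0)), 180)
  expect_error(segment_angle(c(1, 1), c(1, 1)), "coincident")
})

test_that("knee angle composes shank direction with hip angle", {
  # straight vertical leg reads full extension
  expect_equal(knee_angle(c(0, 2), c(0, 1), c(0, 0)), 180)
  # flexed geometry equals the interior angle from the dot product
  hip <- c(0, 2); knee <- c(0, 1); ankle <- c(-0.5, 0.5)
  thigh_v <- hip - knee
  shank_v <- ankle - knee
  interior <- acos(sum(thigh_v * shank_v) /
                     sqrt(sum(thigh_v^2) * sum(shank_v^2))) * 180 / pi
  expect_equal(knee_angle(hip, knee, ankle), interior)
  expect_error(knee_angle(hip, knee, knee), "coincident")
})

test_that("margin of stability implements the extrapolated-COM form", {
  m <- body_model(default_body_model()$segments, leg_length = 0.9)
  expect_equal(margin_of_stability(0.5, 0.5, 0, m), 0)
  expect_equal(margin_of_stability(0.1, 0, 0.33, m),
               0.1 + 0.33 / sqrt(9.81 / 0.9), tolerance = 1e-12)
  expect_equal(round(margin_of_stability(0.1, 0, 0.33, m), 3), 0.2)
  # strictly increasing in COM velocity at fixed positions
  v <- seq(-1, 1, by = 0.1)
  mos <- margin_of_stability(0.1, 0, v, m)
  expect_true(all(diff(mos) > 0))
  expect_error(margin_of_stability(0, 0, 0, body_model(m$segments)),
               "leg length")
})

test_that("COM reduces to the point for degenerate geometry", {
  model <- body_model(data.frame(name = c("s1", "s2"),
                                 proximal = c("A", "B"),
                                 distal = c("A", "B"),
                                 mass_fraction = c(0.3, 0.7),
                                 com_fraction = c(0, 0)))
  traj <- toy_traj(function(i) list(A = c(1, 2, 3), B = c(1, 2, 3)))
  com <- compute_com(traj, model)
  expect_true(all(abs(sweep(com$position, 2, c(1, 2, 3))) < 1e-12))
})

test_that("rigid translation moves the COM at the common velocity", {
  v <- c(1.5, -0.2, 0.3)
  traj <- toy_traj(function(i) {
    d <- v * (i - 1) / 100
    list(A = c(0, 1, 0) + d, B = c(0.4, 0.2, 0) + d)
  })
  model <- body_model(data.frame(name = c("s1", "s2"),
                                 proximal = c("A", "A"),
                                 distal = c("B", "B"),
                                 mass_fraction = c(0.5, 0.5),
                                 com_fraction = c(0.25, 0.75)))
  com <- compute_com(traj, model)
  expect_true(all(abs(sweep(com$velocity, 2, v)) < 1e-9))
})

test_that("two-segment COM equals the hand-computed weighted mean", {
  model <- body_model(data.frame(name = c("s1", "s2"),
                                 proximal = c("A", "A"),
                                 distal = c("B", "B"),
                                 mass_fraction = c(0.3, 0.7),
                                 com_fraction = c(0.2, 0.9)))
  A <- c(0, 0, 0); B <- c(1, 2, 4)
  traj <- toy_traj(function(i) list(A = A, B = B))
  com <- compute_com(traj, model)
  by_hand <- 0.3 * (A + 0.2 * (B - A)) + 0.7 * (A + 0.9 * (B - A))
  expect_equal(unname(com$position[1, ]), by_hand, tolerance = 1e-12)
})

test_that("missing markers are reported by name", {
  model <- default_body_model()
  traj <- toy_traj(function(i) list(A = c(0, 0, 0), B = c(1, 1, 1)))
  expect_error(compute_com(traj, model), "L_hip|mid_shoulder|L_shoulder")
})

test_that("the default body model is a normalized 13-segment set per sex", {
  for (sex in c("female", "male")) {
    m <- default_body_model(sex)
    expect_equal(nrow(m$segments), 13L)
    expect_lt(abs(sum(m$segments$mass_fraction) - 1), 1e-6)
    expect_true(all(m$segments$com_fraction >= 0 &
                      m$segments$com_fraction <= 1))
  }
  expect_false(identical(default_body_model("male")$segments$mass_fraction,
                         default_body_model("female")$segments$mass_fraction))
})

test_that("body models round-trip through YAML", {
  m <- default_body_model("male", leg_length = 0.93)
  yml <- tempfile(fileext = ".yaml")
  write_body_model(m, yml)
  m2 <- read_body_model(yml)
  expect_equal(m2$segments$mass_fraction, m$segments$mass_fraction)
  expect_equal(m2$leg_length, 0.93)
  expect_equal(m2$sex, "male")
})

test_that("extraction yields exactly the 40 named features", {
  trial <- generate_marker_trial(gait_trial_spec(noise_sd = 0), seed = 1)
  fv <- extract_features(trial, detect_gait_events(trial))
  expect_length(fv, 40L)
  expect_identical(names(fv), feature_names_full())
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))
  expect_gt(fv[["Toe clearance"]], 0)
  expect_gt(fv[["Step time"]], 0)
})

test_that("step time follows event frame arithmetic", {
  trial <- generate_marker_trial(gait_trial_spec(noise_sd = 0, cadence = 120),
                                 seed = 1)
  ev <- attr(trial, "ground_truth")$events
  shifted <- gait_events(ev$pre_TD, ev$LO, ev$pre_TD + 60, ev$next_TD)
  fv <- extract_features(trial, shifted)
  expect_equal(fv[["Step time"]], 0.5)  # 60 frames at 120 Hz
})

test_that("batch extraction builds a labelled feature table", {
  trials <- lapply(1:3, function(s) {
    generate_marker_trial(gait_trial_spec(n_cycles = 2), seed = s)
  })
  tab <- extract_feature_table(trials, outcome = c("no_fall", "L_fall",
                                                   "E_fall"))
  expect_equal(dim(tab), c(3L, 41L))
  expect_equal(nrow(validate_table(tab)), 0L)
})
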