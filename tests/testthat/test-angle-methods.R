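# CF and IK joint-angle computation, alignment and differencing.

make_zero_noise_trial <- function(mv, model = default_model(1),
                                  latency = 0, offsets = FALSE) {
  sc <- generate_movement(mv)
  ns <- exact_noise()
  ns$latency <- latency
  if (offsets) ns$frame_offsets <- default_frame_offsets()
  mk <- simulate_markerless(sc, model, 30, ns, "frontal")
  list(script = sc, mk = mk, ns = ns)
}

test_that("all-identity orientations give all-zero angles", {
  n <- 40
  Q <- array(rep(c(1, 0, 0, 0), each = n * 3), c(n, 3, 4),
             dimnames = list(NULL, c("thorax", "humerus", "forearm"), NULL))
  os <- orientation_series((seq_len(n) - 1) / 30, Q, 30)
  tab <- cf_joint_angles(os, alpha = 1, upsample = FALSE)
  for (ch in c(angle_channels(), "pronation"))
    expect_equal(tab[[ch]], rep(0, n))
})

test_that("CF recovers every script exactly at the native rate", {
  for (mv in movement_names()) {
    tr <- make_zero_noise_trial(mv)
    tab <- cf_joint_angles(tr$mk$orientations, alpha = 1, upsample = FALSE)
    truth <- tr$script$fun(tab$time)
    keep <- !tab$gimbal
    for (j in 1:4) {
      e <- abs(tab[[angle_channels()[j]]] - truth[, j])
      if (j %in% c(1, 3)) e <- e[keep]
      expect_lt(max(e), 1e-6)
    }
    # pronation channel is carried and exact as well
    expect_lt(max(abs(tab$pronation - truth[, 5])), 1e-6)
  }
})

test_that("device offsets with matching realignment cancel exactly", {
  tr0 <- make_zero_noise_trial("drink_from_cup")
  tab0 <- cf_joint_angles(tr0$mk$orientations, alpha = 1, upsample = FALSE)
  tr1 <- make_zero_noise_trial("drink_from_cup", offsets = TRUE)
  tab1 <- cf_joint_angles(tr1$mk$orientations,
                          realignment =
                            realignment_from_offsets(tr1$ns$frame_offsets),
                          alpha = 1, upsample = FALSE)
  for (ch in angle_channels())
    expect_equal(tab1[[ch]], tab0[[ch]], tolerance = 1e-6)
  # random constant offsets and their inverses also cancel
  set.seed(71)
  offs <- list(thorax = quat_normalize(rnorm(4)),
               humerus = quat_normalize(rnorm(4)),
               forearm = quat_normalize(rnorm(4)))
  tr2 <- make_zero_noise_trial("brush_hair")
  tr2$ns$frame_offsets <- offs
  mk2 <- simulate_markerless(tr2$script, default_model(1), 30, tr2$ns,
                             "frontal")
  tab2 <- cf_joint_angles(mk2$orientations,
                          realignment = realignment_from_offsets(offs),
                          alpha = 1, upsample = FALSE)
  tabref <- cf_joint_angles(tr2$mk$orientations, alpha = 1, upsample = FALSE)
  for (ch in angle_channels())
    expect_equal(tab2[[ch]], tabref[[ch]], tolerance = 1e-6)
})

test_that("CF requires the three segments by name", {
  n <- 10
  Q <- array(rep(c(1, 0, 0, 0), each = n * 2), c(n, 2, 4),
             dimnames = list(NULL, c("thorax", "humerus"), NULL))
  os <- orientation_series((seq_len(n) - 1) / 30, Q, 30)
  expect_error(cf_joint_angles(os), "forearm")
})

test_that("IK recovers noise-free keypoints within 0.1 deg", {
  for (mv in c("elbow_flexion", "shoulder_abduction", "drink_from_cup")) {
    tr <- make_zero_noise_trial(mv)
    tab <- ik_joint_angles(tr$mk$keypoints, default_model(1),
                           ik_settings(tolerance = 1e-9,
                                       max_iterations = 200L),
                           filter = NULL, upsample = FALSE)
    truth <- tr$script$fun(tab$time)
    for (j in c(1, 2, 4)) {
      expect_lt(max(abs(tab[[angle_channels()[j]]] - truth[, j])), 0.1)
    }
    # zero-residual fixed point on exact input
    expect_lt(max(attr(tab, "ik_objective")), 1e-10)
  }
})

test_that("reference IK recovers all five DOFs including pronation", {
  sc <- generate_movement("pronation_supination")
  rf <- simulate_reference(sc, default_model(1), 120, exact_noise())
  tab <- compute_reference_angles(rf$keypoints, default_model(1),
                                  filter = NULL)
  expect_identical(attr(tab, "rate"), 120)
  expect_identical(nrow(tab), length(rf$keypoints$time))
  truth <- sc$fun(tab$time)
  for (j in 1:5) {
    ch <- c(angle_channels(), "pronation")[j]
    expect_lt(max(abs(tab[[ch]] - truth[, j])), 0.1)
  }
})

test_that("IK with keypoint noise stays in the expected error band", {
  sc <- generate_movement("elbow_flexion")
  ns <- noise_spec(keypoint_sd = 5, orientation_sd = 0, latency = 0,
                   misdetection_prob = 0, seed = 91)
  mk <- simulate_markerless(sc, default_model(1), 30, ns, "frontal")
  tab <- ik_joint_angles(mk$keypoints, default_model(1), upsample = FALSE)
  expect_gt(min(attr(tab, "ik_objective")), 0)
  truth <- sc$fun(tab$time)
  rmse <- sqrt(mean((tab$elbow_flexion - truth[, 4])^2))
  expect_gt(rmse, 0.5)
  expect_lt(rmse, 10)
})

test_that("frames with too few keypoints are interpolated from neighbours", {
  tr <- make_zero_noise_trial("elbow_flexion")
  kp <- tr$mk$keypoints
  drop <- 50:53
  kp$valid[drop, c("elbow", "wrist")] <- FALSE
  tab <- ik_joint_angles(kp, default_model(1), filter = NULL,
                         upsample = FALSE)
  expect_identical(attr(tab, "n_unresolved"), length(drop))
  truth <- tr$script$fun(tab$time)
  # linear interpolation across a short smooth gap stays close
  expect_lt(max(abs(tab$elbow_flexion[drop] - truth[drop, 4])), 1)
})

test_that("CF and IK agree on noise-free data for every task", {
  for (mv in movement_names()) {
    tr <- make_zero_noise_trial(mv)
    cf <- cf_joint_angles(tr$mk$orientations, alpha = 1, upsample = FALSE)
    ik <- ik_joint_angles(tr$mk$keypoints, default_model(1), filter = NULL,
                          upsample = FALSE)
    keep <- !(cf$gimbal | ik$gimbal)
    for (j in c(1, 2, 4)) {
      ch <- angle_channels()[j]
      e <- abs(cf[[ch]] - ik[[ch]])
      if (j == 1) e <- e[keep]
      expect_lt(max(e), 0.5)
    }
  }
})

test_that("angle tables align and difference correctly", {
  tr <- make_zero_noise_trial("shoulder_abduction", latency = 0.15)
  cf <- cf_joint_angles(tr$mk$orientations, alpha = 1, out_rate = 120)
  rf <- simulate_reference(tr$script, default_model(1), 120, exact_noise())
  ref <- compute_reference_angles(rf$keypoints, default_model(1),
                                  filter = NULL)
  al <- align_angle_tables(cf, ref)
  expect_identical(al$lag, 18L)
  expect_identical(al$sync_channel, "angle_of_elevation")
  d <- build_difference_sets(al$test, al$reference)
  expect_lt(max(abs(d$angle_of_elevation)), 0.1)
  # identical tables difference to zero; constant offsets pass through
  d0 <- build_difference_sets(ref, ref)
  for (ch in angle_channels()) expect_equal(max(abs(d0[[ch]])), 0)
  shifted <- ref
  shifted$elbow_flexion <- shifted$elbow_flexion + 5
  d5 <- build_difference_sets(shifted, ref)
  expect_equal(range(d5$elbow_flexion), c(5, 5))
  expect_error(build_difference_sets(uplimb:::.subset_table(ref, 1:10), ref),
               "aligned")
})
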