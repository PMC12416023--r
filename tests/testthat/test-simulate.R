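# Two-channel measurement simulation: determinism, noise structure, latency.

test_that("zero-noise reference equals forward kinematics exactly", {
  sc <- generate_movement("drink_from_cup")
  m <- default_model(1)
  rf <- simulate_reference(sc, m, 120, exact_noise())
  expect_identical(length(rf$keypoints$time), as.integer(sc$duration * 120 + 1))
  poses <- sc$fun(rf$keypoints$time)
  fk <- uplimb:::.fk_batch(m, poses)
  expect_equal(rf$keypoints$points, fk$keypoints, tolerance = 1e-12)
  expect_equal(rf$truth$angle_of_elevation, poses[, 2], tolerance = 1e-12)
})

test_that("seeded simulation is reproducible and seeds are independent", {
  sc <- generate_movement("brush_hair")
  m <- default_model(1)
  ns <- noise_spec(keypoint_sd = 0.5, seed = 123)
  a <- simulate_markerless(sc, m, 30, ns, "frontal")
  b <- simulate_markerless(sc, m, 30, ns, "frontal")
  expect_identical(a$keypoints$points, b$keypoints$points)
  expect_identical(a$orientations$quats, b$orientations$quats)
  ns2 <- ns; ns2$seed <- 124L
  c_ <- simulate_markerless(sc, m, 30, ns2, "frontal")
  expect_false(identical(a$keypoints$points, c_$keypoints$points))
})

test_that("latency shifts the carried pose, not the timestamps", {
  sc <- generate_movement("shoulder_abduction")
  m <- default_model(1)
  ns <- exact_noise(); ns$latency <- 0.15
  mk <- simulate_markerless(sc, m, 30, ns, "frontal")
  expect_equal(mk$keypoints$time[1], 0)
  poses <- sc$fun(mk$keypoints$time - 0.15)
  fk <- uplimb:::.fk_batch(m, poses)
  expect_equal(mk$keypoints$points, fk$keypoints, tolerance = 1e-12)
})

test_that("misdetections are flagged, displaced and reproducible", {
  sc <- generate_movement("collect_change", repetitions = 2)
  m <- default_model(1)
  ns <- noise_spec(keypoint_sd = 0, orientation_sd = 0, latency = 0,
                   misdetection_prob = 0.05, misdetection_sd = 150,
                   seed = 55)
  mk <- simulate_markerless(sc, m, 30, ns, "frontal")
  n_invalid <- sum(!mk$keypoints$valid)
  expect_gt(n_invalid, 0)
  mk2 <- simulate_markerless(sc, m, 30, ns, "frontal")
  expect_identical(mk$keypoints$valid, mk2$keypoints$valid)
  # misdetected points are far from the exact positions, valid ones are exact
  fk <- uplimb:::.fk_batch(m, sc$fun(mk$keypoints$time))$keypoints
  d <- sqrt(apply((mk$keypoints$points - fk)^2, c(1, 2), sum))
  expect_equal(max(d[mk$keypoints$valid]), 0)
  expect_gt(median(d[!mk$keypoints$valid]), 10)
})

test_that("orientation noise keeps quaternions unit norm", {
  sc <- generate_movement("eat_with_spoon")
  m <- default_model(1)
  ns <- noise_spec(orientation_sd = 8, seed = 66)
  mk <- simulate_markerless(sc, m, 30, ns, "sagittal")
  norms <- sqrt(apply(mk$orientations$quats^2, c(1, 2), sum))
  expect_equal(max(abs(norms - 1)), 0, tolerance = 1e-12)
})

test_that("device frame offsets rotate segment frames in their own frame", {
  sc <- generate_movement("shoulder_abduction")
  m <- default_model(1)
  ns <- exact_noise()
  ns$frame_offsets <- default_frame_offsets()
  mk <- simulate_markerless(sc, m, 30, ns, "frontal")
  fk <- uplimb:::.fk_batch(m, sc$fun(mk$orientations$time))
  i <- 40L
  for (s in c("thorax", "humerus", "forearm")) {
    expected <- quat_multiply(fk$quats[i, s, ], ns$frame_offsets[[s]])
    got <- mk$orientations$quats[i, s, ]
    expect_lt(min(max(abs(got - expected)), max(abs(got + expected))), 1e-9)
  }
})

test_that("keypoint RMS error grows with the noise sd", {
  sc <- generate_movement("shoulder_flexion")
  m <- default_model(1)
  fk <- NULL
  rms <- vapply(c(0, 2, 5, 10), function(s) {
    err <- 0
    for (rep in 1:3) {
      ns <- noise_spec(keypoint_sd = s, orientation_sd = 0, latency = 0,
                       misdetection_prob = 0, seed = 1000L + rep)
      mk <- simulate_markerless(sc, m, 30, ns, "frontal")
      if (is.null(fk)) fk <<- uplimb:::.fk_batch(m, sc$fun(mk$keypoints$time))$keypoints
      err <- err + sqrt(mean((mk$keypoints$points - fk)^2))
    }
    err / 3
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})
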