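# Limb model: anthropometry, forward kinematics, scaling, axis diagnostic.

test_that("default_model scales all dimensions linearly and is deterministic", {
  m1 <- default_model(1)
  expect_equal(m1$humerus_length, 300)
  expect_equal(m1$forearm_length, 260)
  m11 <- default_model(1.1)
  expect_equal(m11$humerus_length, 330)
  expect_equal(m11$clavicle_offset, m1$clavicle_offset * 1.1)
  expect_identical(default_model(0.93), default_model(0.93))
  expect_error(default_model(-1), "positive")
  expect_error(default_model(0), "positive")
})

test_that("neutral-pose FK hangs the arm along -Y from the shoulder", {
  m <- default_model(1)
  fk <- forward_kinematics(m, c(0, 0, 0, 0, 0))
  expect_equal(fk$keypoints["elbow", ],
               fk$keypoints["shoulder", ] + c(x = 0, y = -300, z = 0))
  expect_equal(fk$keypoints["wrist", ],
               fk$keypoints["elbow", ] + c(x = 0, y = -260, z = 0))
  expect_equal(fk$orientations$thorax, c(1, 0, 0, 0))
})

test_that("90 deg elbow flexion displaces the wrist along the flexed axis", {
  m <- default_model(1)
  fk <- forward_kinematics(m, c(0, 0, 0, 90, 0))
  # geometry oracle: forearm direction rotated by Rz(90) from (0,-1,0)
  d <- as.numeric(rot_z(90) %*% c(0, -1, 0))
  expect_equal(unname(fk$keypoints["wrist", ] - fk$keypoints["elbow", ]),
               260 * d, tolerance = 1e-9)
  expect_equal(sqrt(sum((fk$keypoints["wrist", ] -
                           fk$keypoints["elbow", ])^2)), 260,
               tolerance = 1e-9)
})

test_that("segment lengths are conserved over random in-limit poses", {
  set.seed(17)
  m <- default_model(1.07)
  worst <- 0
  for (i in 1:200) {
    pose <- c(runif(1, -90, 130), runif(1, 0, 180), runif(1, -90, 90),
              runif(1, 0, 150), runif(1, -90, 90))
    fk <- forward_kinematics(m, pose)
    worst <- max(worst,
                 abs(sqrt(sum((fk$keypoints["elbow", ] -
                                 fk$keypoints["shoulder", ])^2)) -
                       m$humerus_length),
                 abs(sqrt(sum((fk$keypoints["wrist", ] -
                                 fk$keypoints["elbow", ])^2)) -
                       m$forearm_length))
  }
  expect_lt(worst, 1e-9)
})

test_that("decomposing the FK humerus orientation returns the shoulder pose", {
  set.seed(19)
  m <- default_model(1)
  for (i in 1:100) {
    pose <- c(runif(1, -89, 129), runif(1, 1, 179), runif(1, -89, 89),
              runif(1, 0, 150), 0)
    fk <- forward_kinematics(m, pose)
    sh <- shoulder_angles_from_matrix(quat_to_matrix(fk$orientations$humerus))
    expect_equal(as.numeric(sh), pose[1:3], tolerance = 1e-9)
    # elbow decomposition: Z-X-Y with flexion leading
    Rel <- t(quat_to_matrix(fk$orientations$humerus)) %*%
      quat_to_matrix(fk$orientations$forearm)
    el <- euler_intrinsic(Rel, "ZXY")
    expect_equal(as.numeric(el), c(pose[4], 0, pose[5]), tolerance = 1e-9)
  }
})

test_that("poses outside the joint limits are rejected by name", {
  m <- default_model(1)
  expect_error(forward_kinematics(m, c(0, -5, 0, 0, 0)),
               "angle_of_elevation")
  expect_error(forward_kinematics(m, c(0, 10, 0, 170, 0)), "elbow_flexion")
})

test_that("model scaling from keypoints is exact on FK output", {
  m <- default_model(1)
  big <- limb_model(humerus_length = 320, forearm_length = 250)
  set.seed(23)
  poses <- cbind(runif(60, -80, 120), runif(60, 5, 170), runif(60, -80, 80),
                 runif(60, 0, 140), runif(60, -80, 80))
  fk <- uplimb:::.fk_batch(big, poses)
  kps <- keypoint_series((0:59) / 30, fk$keypoints, 30)
  sc <- scale_model_from_keypoints(m, kps)
  expect_equal(sc$humerus_length, 320, tolerance = 1e-9)
  expect_equal(sc$forearm_length, 250, tolerance = 1e-9)
  r <- mean(c(320 / 300, 250 / 260))
  expect_equal(sc$thorax_height, m$thorax_height * r, tolerance = 1e-9)
})

test_that("model scaling tolerates noise and rejects sparse data", {
  big <- default_model(1.06)
  set.seed(29)
  n <- 300
  poses <- cbind(runif(n, -80, 120), runif(n, 5, 170), runif(n, -80, 80),
                 runif(n, 0, 140), 0)
  fk <- uplimb:::.fk_batch(big, poses)
  kp <- fk$keypoints + array(rnorm(length(fk$keypoints), 0, 5), dim(fk$keypoints))
  dimnames(kp) <- dimnames(fk$keypoints)
  kps <- keypoint_series((seq_len(n) - 1) / 30, kp, 30)
  sc <- scale_model_from_keypoints(default_model(1), kps)
  expect_lt(abs(sc$humerus_length - big$humerus_length), 2)
  expect_lt(abs(sc$forearm_length - big$forearm_length), 2)
  # all frames invalid -> insufficient data
  bad <- keypoint_series((seq_len(n) - 1) / 30, kp, 30,
                         valid = matrix(FALSE, n, dim(kp)[2]))
  expect_error(scale_model_from_keypoints(default_model(1), bad),
               "insufficient")
})

test_that("axis dot-product test counts 5 axes extended, 6 flexed", {
  m <- default_model(1)
  # generic shoulder pose, elbow extended: pronation axis collinear with
  # the shoulder axial-rotation axis
  ext <- axis_independence_test(m, c(40, 60, 30, 0, 0))
  expect_identical(ext$n_independent, 5L)
  pr <- ext$pairs
  expect_gt(pr$abs_dot[pr$axis_a == "shoulder_axial" &
                         pr$axis_b == "pronation"], 1 - 1e-9)
  flex <- axis_independence_test(m, c(40, 60, 30, 60, 0))
  expect_identical(flex$n_independent, 6L)
  # at exactly 90 deg flexion the carrying axis meets the axial axis
  expect_identical(axis_independence_test(m, c(40, 60, 30, 90, 0))$n_independent, 5L)
  # absurd tolerance collapses everything onto the first axis
  expect_identical(axis_independence_test(m, c(40, 60, 30, 60, 0),
                                          tol = 2)$n_independent, 1L)
})

test_that("limb model round-trips through its text config", {
  m <- default_model(1.13)
  f <- tempfile(fileext = ".txt")
  write_limb_model(m, f)
  m2 <- read_limb_model(f)
  expect_equal(m2[names(m2) != "limits"], m[names(m) != "limits"])
  expect_equal(m2$limits, m$limits)
  unlink(f)
})

test_that("C++ and R forward kinematics agree", {
  set.seed(31)
  m <- default_model(0.97)
  poses <- cbind(runif(50, -80, 120), runif(50, 0, 170), runif(50, -80, 80),
                 runif(50, 0, 140), runif(50, -80, 80))
  fkR <- uplimb:::.fk_batch(m, poses)
  fkC <- uplimb:::.fk_points_cpp(
    c(m$humerus_length, m$forearm_length, m$clavicle_offset, m$hand_offset),
    poses)
  for (i in seq_len(4)) {
    nm <- c("shoulder", "elbow", "wrist", "hand")[i]
    expect_equal(fkC[, (3 * i - 2):(3 * i)],
                 unname(fkR$keypoints[, nm, ]), tolerance = 1e-9)
  }
})
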