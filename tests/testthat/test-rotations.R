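# Quaternion / rotation-matrix algebra, SLERP, manifold smoothing.

test_that("quat_to_matrix handles closed-form cases and rejects bad input", {
  expect_equal(quat_to_matrix(c(1, 0, 0, 0)), diag(3))
  s <- sqrt(2) / 2
  R <- quat_to_matrix(c(s, 0, 0, s))   # 90 deg about Z
  expect_equal(R, cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)),
               tolerance = 1e-12)
  expect_error(quat_to_matrix(c(0, 0, 0, 0)), "zero-norm")
  expect_error(quat_to_matrix(c(NA, 0, 0, 1)), "finite")
  expect_error(quat_to_matrix(c(2, 0, 0, 0)), "unit norm")
})

test_that("quaternion/matrix round trip is exact to 1e-9 on 1000 rotations", {
  set.seed(11)
  Q <- random_quats(1000)
  worst_q <- 0
  worst_R <- 0
  for (i in seq_len(nrow(Q))) {
    q <- quat_canonical(Q[i, ])
    R <- quat_to_matrix(q)
    # matrix invariants
    worst_R <- max(worst_R, max(abs(crossprod(R) - diag(3))),
                   abs(det(R) - 1))
    q2 <- matrix_to_quat(R)
    worst_q <- max(worst_q, min(max(abs(q2 - q)), max(abs(q2 + q))))
  }
  expect_lt(worst_R, 1e-9)
  expect_lt(worst_q, 1e-9)
})

test_that("elementary rotations match quaternion construction", {
  for (ax in list(c("x", 1, 0, 0), c("y", 0, 1, 0), c("z", 0, 0, 1))) {
    fn <- switch(ax[1L], x = rot_x, y = rot_y, z = rot_z)
    for (a in c(-120, -30, 45, 170)) {
      q <- quat_from_axis_angle(as.numeric(ax[2:4]), a)
      expect_equal(fn(a), quat_to_matrix(q), tolerance = 1e-12)
    }
  }
})

test_that("slerp endpoints, symmetry and fractional-angle property hold", {
  set.seed(21)
  q0 <- quat_canonical(random_quats(1)[1, ])
  q1 <- quat_canonical(random_quats(1)[1, ])
  expect_equal(slerp(q0, q1, 0), quat_canonical(q0), tolerance = 1e-12)
  expect_equal(slerp(q0, q1, 1), quat_canonical(q1), tolerance = 1e-12)
  # identity to 90 deg about X at t = 0.5 is 45 deg about X
  qx <- quat_from_axis_angle(c(1, 0, 0), 90)
  expect_equal(slerp(c(1, 0, 0, 0), qx, 0.5),
               quat_from_axis_angle(c(1, 0, 0), 45), tolerance = 1e-12)
  # fractional geodesic angle, verified by the matrix-log oracle
  for (t in c(0.25, 0.6)) {
    qt <- slerp(q0, q1, t)
    full <- rotmat_angle(quat_to_matrix(q0), quat_to_matrix(q1))
    part <- rotmat_angle(quat_to_matrix(q0), quat_to_matrix(qt))
    expect_equal(part, t * full, tolerance = 1e-9)
  }
  expect_error(slerp(q0, q1, 1.5), "t must be")
})

test_that("slerp output is unit norm to 1e-12 across an input sweep", {
  set.seed(31)
  Q <- random_quats(200)
  worst <- 0
  for (i in seq_len(100)) {
    s <- slerp(Q[2 * i - 1, ], Q[2 * i, ], runif(1))
    worst <- max(worst, abs(sqrt(sum(s * s)) - 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("slerp_smooth fixed points and noise reduction", {
  q <- quat_from_axis_angle(c(1, 2, 0), 37)
  const <- matrix(q, 10, 4, byrow = TRUE)
  expect_equal(slerp_smooth(const, 0.3), const, tolerance = 1e-12)
  set.seed(41)
  Q <- random_quats(50)
  expect_equal(slerp_smooth(Q, 1),
               t(apply(Q, 1, quat_canonical)), tolerance = 1e-12)
  # noisy samples around a fixed rotation: smoothing reduces RMS deviation
  n <- 400
  noisy <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    ax <- rnorm(3)
    noisy[i, ] <- quat_multiply(quat_from_axis_angle(ax, rnorm(1, 0, 8)), q)
  }
  sm <- slerp_smooth(noisy, 0.3)
  dev <- function(M) sqrt(mean(vapply(seq_len(n), function(i)
    quat_angle(M[i, ] / sqrt(sum(M[i, ]^2)), q)^2, numeric(1))))
  expect_lt(dev(sm), dev(noisy))
  expect_error(slerp_smooth(noisy, 0), "alpha")
  expect_error(slerp_smooth(noisy, 1.2), "alpha")
})
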