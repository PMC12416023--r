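# Intrinsic Euler decomposition, gimbal conventions, unwrapping.

test_that("identity decomposes to zeros for symmetric and asymmetric seqs", {
  for (s in c("YXY", "ZXY", "XYX", "XYZ")) {
    a <- euler_intrinsic(diag(3), s)
    expect_equal(as.numeric(a), c(0, 0, 0))
  }
})

test_that("compose/decompose round-trips within canonical ranges", {
  expect_equal(as.numeric(euler_intrinsic(euler_compose(c(30, 45, -20),
                                                        "YXY"), "YXY")),
               c(30, 45, -20), tolerance = 1e-9)
  set.seed(7)
  for (s in c("YXY", "XYX", "ZYZ")) {     # symmetric: middle in [0, 180]
    for (i in 1:200) {
      a <- c(runif(1, -179, 179), runif(1, 1, 179), runif(1, -179, 179))
      out <- as.numeric(euler_intrinsic(euler_compose(a, s), s))
      expect_equal(out, a, tolerance = 1e-9)
    }
  }
  for (s in c("ZXY", "XYZ", "YZX", "XZY")) {  # asymmetric: middle [-90, 90]
    for (i in 1:200) {
      a <- c(runif(1, -179, 179), runif(1, -89, 89), runif(1, -179, 179))
      out <- as.numeric(euler_intrinsic(euler_compose(a, s), s))
      expect_equal(out, a, tolerance = 1e-9)
    }
  }
})

test_that("recomposition reproduces the matrix away from the gimbal band", {
  set.seed(9)
  worst <- 0
  for (i in 1:1000) {
    R <- quat_to_matrix(quat_canonical(random_quats(1)[1, ]))
    a <- euler_intrinsic(R, "YXY")
    if (a[2] < 1 || a[2] > 179) next
    worst <- max(worst, max(abs(euler_compose(a, "YXY") - R)))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal-degenerate input follows the a3 = 0 convention and flags", {
  # middle angle 0: pure Y rotation, a1 carries the whole rotation
  R <- euler_compose(c(25, 0, 40), "YXY")
  a <- euler_intrinsic(R, "YXY")
  expect_true(attr(a, "degenerate"))
  expect_equal(as.numeric(a), c(65, 0, 0), tolerance = 1e-9)
  # middle angle 180: a1 carries the difference
  R2 <- euler_compose(c(25, 180, 40), "YXY")
  a2 <- euler_intrinsic(R2, "YXY")
  expect_true(attr(a2, "degenerate"))
  expect_equal(as.numeric(a2), c(-15, 180, 0), tolerance = 1e-9)
  # non-degenerate input is not flagged
  expect_false(attr(euler_intrinsic(euler_compose(c(10, 50, 5), "YXY"),
                                    "YXY"), "degenerate"))
  expect_error(euler_intrinsic(diag(3), "XXY"), "distinct")
})

test_that("unwrap_angles removes period jumps and is idempotent", {
  expect_equal(unwrap_angles(c(179, -179)), c(179, 181))
  expect_equal(unwrap_angles(rep(42, 20)), rep(42, 20))
  ramp <- seq(0, 720, by = 2.5)
  wrapped <- ((ramp + 180) %% 360) - 180
  expect_equal(unwrap_angles(wrapped) - unwrap_angles(wrapped)[1],
               ramp - ramp[1], tolerance = 1e-9)
  set.seed(3)
  x <- cumsum(rnorm(500, 0, 40))
  w <- ((x + 180) %% 360) - 180
  u <- unwrap_angles(w)
  expect_true(all(abs(diff(u)) <= 180 + 1e-9))
  expect_equal(((u - w) %% 360), rep(0, length(u)), tolerance = 1e-9)
  expect_equal(unwrap_angles(u), u)
  expect_equal(unwrap_angles(numeric(0)), numeric(0))
})

test_that("shoulder adapter inverts the model composition convention", {
  set.seed(13)
  for (i in 1:100) {
    p <- runif(1, -89, 129); e <- runif(1, 1, 179); r <- runif(1, -89, 89)
    R <- rot_y(p) %*% rot_x(-e) %*% rot_y(r)
    out <- shoulder_angles_from_matrix(R)
    expect_equal(as.numeric(out), c(p, e, r), tolerance = 1e-9)
  }
})
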