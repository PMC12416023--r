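# Orientation algebra: quaternions, rotation matrices, SLERP, smoothing.
#
# Quaternions are length-4 numeric vectors (w, x, y, z), scalar first, unit
# norm, active rotations, right-handed frames. q and -q encode the same
# rotation; functions returning quaternions canonicalize to w >= 0.
# Batched variants operate on n x 4 matrices (one quaternion per row) and are
# used internally by the simulation and angle pipelines.

.DEG <- pi / 180

.check_quat <- function(q) {
  if (!is.numeric(q) || length(q) != 4L || anyNA(q) || any(!is.finite(q)))
    stop("invalid orientation: quaternion must be 4 finite numbers",
         call. = FALSE)
  n <- sqrt(sum(q * q))
  if (n < 1e-12)
    stop("invalid orientation: zero-norm quaternion", call. = FALSE)
  if (abs(n - 1) > 1e-6)
    stop("invalid orientation: quaternion is not unit norm (|q| = ",
         format(n), ")", call. = FALSE)
  q / n
}

#' Normalize a quaternion to unit norm
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)`.
#' @return unit quaternion, canonicalized to `w >= 0`.
#' @export
quat_normalize <- function(q) {
  if (!is.numeric(q) || length(q) != 4L || any(!is.finite(q)))
    stop("invalid orientation: quaternion must be 4 finite numbers",
         call. = FALSE)
  n <- sqrt(sum(q * q))
  if (n < 1e-12)
    stop("invalid orientation: zero-norm quaternion", call. = FALSE)
  quat_canonical(q / n)
}

#' Canonicalize quaternion sign so that w >= 0
#' @param q unit quaternion.
#' @return `q` or `-q`, whichever has non-negative scalar part.
#' @export
quat_canonical <- function(q) if (q[1L] < 0) -q else q

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @param q unit quaternion.
#' @return conjugated quaternion.
#' @export
quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

#' Hamilton product of two quaternions
#'
#' `quat_multiply(p, q)` composes rotations so that the rotation `q` is applied
#' first, then `p` (matching matrix composition `R(p) %*% R(q)`).
#'
#' @param p,q unit quaternions.
#' @return product quaternion (not sign-canonicalized).
#' @export
quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

#' Quaternion from rotation axis and angle
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis * axis))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  h <- angle_deg * .DEG / 2
  c(cos(h), sin(h) * axis / n)
}

#' Geodesic angle between two orientations
#' @param q0,q1 unit quaternions.
#' @return rotation angle from `q0` to `q1` in degrees, in `[0, 180]`.
#' @export
quat_angle <- function(q0, q1) {
  q0 <- .check_quat(q0); q1 <- .check_quat(q1)
  d <- min(1, abs(sum(q0 * q1)))
  2 * acos(d) / .DEG
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  q <- .check_quat(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z),     1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
    2 * (x * z + w * y),     2 * (y * z - w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3L, ncol = 3L)
}

.check_rotmat <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || any(!is.finite(R)))
    stop("invalid orientation: expected a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("invalid orientation: matrix is not a proper rotation",
         call. = FALSE)
  R
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses the numerically stable branch selection on the largest diagonal
#' component (Shepperd's method).
#'
#' @param R 3x3 rotation matrix.
#' @return unit quaternion with `w >= 0`.
#' @export
matrix_to_quat <- function(R) {
  R <- .check_rotmat(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' Elementary rotation matrices
#'
#' Active rotations about the laboratory X, Y or Z axis.
#'
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(angle_deg) {
  a <- angle_deg * .DEG; c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) {
  a <- angle_deg * .DEG; c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) {
  a <- angle_deg * .DEG; c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3L, 3L)
}

#' Spherical linear interpolation between two orientations
#'
#' Interpolates along the shortest great-circle arc (the sign of `q1` is
#' flipped if `dot(q0, q1) < 0`), at constant angular velocity.
#'
#' @param q0,q1 unit quaternions.
#' @param t interpolation parameter in `[0, 1]`; 0 returns `q0`, 1 returns
#'   `q1`.
#' @return unit quaternion, canonicalized to `w >= 0`.
#' @export
slerp <- function(q0, q1, t) {
  q0 <- .check_quat(q0); q1 <- .check_quat(q1)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t > 1)
    stop("slerp parameter t must be a single value in [0, 1]", call. = FALSE)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  d <- min(1, d)
  if (d > 1 - 1e-10) {
    # nearly parallel: linear interpolation avoids 0/0
    return(quat_normalize(q0 + t * (q1 - q0)))
  }
  th <- acos(d)
  quat_normalize((sin((1 - t) * th) * q0 + sin(t * th) * q1) / sin(th))
}

#' Exponential smoothing of an orientation series on the rotation manifold
#'
#' First-order recursive smoother: `s[1] = q[1]`,
#' `s[t] = slerp(s[t-1], q[t], alpha)`. `alpha = 1` returns the input
#' unchanged; smaller values smooth more (and introduce a group delay of
#' roughly `(1 - alpha) / alpha` samples, which downstream time alignment
#' absorbs).
#'
#' @param quats n x 4 matrix of unit quaternions (rows), or a list of
#'   length-4 vectors.
#' @param alpha smoothing weight in `(0, 1]`.
#' @return object of the same shape as the input, unit-norm rows with
#'   `w >= 0`.
#' @export
slerp_smooth <- function(quats, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("smoothing alpha must be a single value in (0, 1]", call. = FALSE)
  as_list <- is.list(quats)
  Q <- if (as_list) do.call(rbind, quats) else as.matrix(quats)
  if (ncol(Q) != 4L) stop("expected quaternions with 4 components",
                          call. = FALSE)
  n <- nrow(Q)
  out <- matrix(NA_real_, n, 4L)
  s <- quat_normalize(Q[1L, ])
  out[1L, ] <- s
  if (n > 1L) for (i in 2:n) {
    s <- slerp(s, Q[i, ], alpha)
    out[i, ] <- s
  }
  if (as_list) lapply(seq_len(n), function(i) out[i, ]) else out
}

# ---- batched helpers (internal) ----

# normalize rows, flip signs for hemisphere continuity along the series
.quat_rows_normalize <- function(Q) {
  n <- sqrt(rowSums(Q * Q))
  if (any(n < 1e-12)) stop("invalid orientation: zero-norm quaternion",
                           call. = FALSE)
  Q / n
}

# rowwise Hamilton product of n x 4 matrices (or one side length-4)
.quat_rows_multiply <- function(P, Q) {
  if (is.null(dim(P))) P <- matrix(P, nrow = if (is.null(dim(Q))) 1L else nrow(Q),
                                   ncol = 4L, byrow = TRUE)
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = nrow(P), ncol = 4L, byrow = TRUE)
  pw <- P[, 1L]; px <- P[, 2L]; py <- P[, 3L]; pz <- P[, 4L]
  qw <- Q[, 1L]; qx <- Q[, 2L]; qy <- Q[, 3L]; qz <- Q[, 4L]
  cbind(pw * qw - px * qx - py * qy - pz * qz,
        pw * qx + px * qw + py * qz - pz * qy,
        pw * qy - px * qz + py * qw + pz * qx,
        pw * qz + px * qy - py * qx + pz * qw, deparse.level = 0)
}

.quat_rows_conjugate <- function(Q) {
  cbind(Q[, 1L], -Q[, 2L], -Q[, 3L], -Q[, 4L], deparse.level = 0)
}

# n x 9 rotation-matrix elements in column-major order
# (r11, r21, r31, r12, r22, r32, r13, r23, r33)
.quat_rows_to_Rm <- function(Q) {
  w <- Q[, 1L]; x <- Q[, 2L]; y <- Q[, 3L]; z <- Q[, 4L]
  cbind(1 - 2 * (y * y + z * z), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x * x + y * y),
        deparse.level = 0)
}

# rotate n x 3 points (or a single length-3 vector) by n x 4 quaternion rows
.quat_rows_rotate <- function(Q, v) {
  Rm <- .quat_rows_to_Rm(Q)
  if (is.null(dim(v))) {
    cbind(Rm[, 1L] * v[1L] + Rm[, 4L] * v[2L] + Rm[, 7L] * v[3L],
          Rm[, 2L] * v[1L] + Rm[, 5L] * v[2L] + Rm[, 8L] * v[3L],
          Rm[, 3L] * v[1L] + Rm[, 6L] * v[2L] + Rm[, 9L] * v[3L],
          deparse.level = 0)
  } else {
    cbind(Rm[, 1L] * v[, 1L] + Rm[, 4L] * v[, 2L] + Rm[, 7L] * v[, 3L],
          Rm[, 2L] * v[, 1L] + Rm[, 5L] * v[, 2L] + Rm[, 8L] * v[, 3L],
          Rm[, 3L] * v[, 1L] + Rm[, 6L] * v[, 2L] + Rm[, 9L] * v[, 3L],
          deparse.level = 0)
  }
}

# quaternions for elementary axis rotations, vectorized over angle (degrees)
.quat_axis_rows <- function(axis, angle_deg) {
  h <- angle_deg * .DEG / 2
  z <- numeric(length(h))
  switch(axis,
         x = cbind(cos(h), sin(h), z, z, deparse.level = 0),
         y = cbind(cos(h), z, sin(h), z, deparse.level = 0),
         z = cbind(cos(h), z, z, sin(h), deparse.level = 0),
         stop("axis must be one of 'x', 'y', 'z'", call. = FALSE))
}
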