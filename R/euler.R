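# Intrinsic Euler decomposition and angle unwrapping.
#
# An Euler sequence is a string such as "YXY" or "ZXY": intrinsic rotations,
# applied left to right (R = R_a1 %*% R_a2 %*% R_a3 about the successively
# rotated axes). Symmetric sequences (first axis == last axis) canonicalize
# the middle angle to [0, 180] degrees; asymmetric (Tait-Bryan) sequences to
# [-90, 90] degrees.

.AXIS_IDX <- c(X = 1L, Y = 2L, Z = 3L)

.parse_seq <- function(seq) {
  s <- toupper(gsub("[^XYZxyz]", "", seq))
  ax <- strsplit(s, "")[[1L]]
  if (length(ax) != 3L || !all(ax %in% names(.AXIS_IDX)))
    stop("Euler sequence must name three axes from {X, Y, Z}", call. = FALSE)
  idx <- unname(.AXIS_IDX[ax])
  if (idx[1L] == idx[2L] || idx[2L] == idx[3L])
    stop("consecutive Euler axes must be distinct", call. = FALSE)
  idx
}

# parity of a permutation (i, j, k) of (1, 2, 3): +1 even, -1 odd
.perm_parity <- function(i, j, k) {
  if (identical(c(i, j, k), c(1L, 2L, 3L)) ||
      identical(c(i, j, k), c(2L, 3L, 1L)) ||
      identical(c(i, j, k), c(3L, 1L, 2L))) 1 else -1
}

.rot_elem <- function(axis_idx, angle_deg) {
  switch(axis_idx, rot_x(angle_deg), rot_y(angle_deg), rot_z(angle_deg))
}

#' Compose a rotation matrix from intrinsic Euler angles
#'
#' @param angles numeric length-3, angles in degrees applied in sequence
#'   order.
#' @param seq Euler sequence string, e.g. `"YXY"` or `"ZXY"`.
#' @return 3x3 rotation matrix.
#' @export
euler_compose <- function(angles, seq) {
  idx <- .parse_seq(seq)
  .rot_elem(idx[1L], angles[1L]) %*% .rot_elem(idx[2L], angles[2L]) %*%
    .rot_elem(idx[3L], angles[3L])
}

# angle (deg) of a rotation assumed to be about elementary axis i,
# extracted from matrix elements; (i, j, l) chosen as an even permutation
.pure_axis_angle <- function(R, i) {
  jl <- switch(i, c(2L, 3L), c(3L, 1L), c(1L, 2L))
  atan2(R[jl[2L], jl[1L]], R[jl[1L], jl[1L]]) / .DEG
}

#' Decompose a rotation matrix into intrinsic Euler angles
#'
#' For symmetric sequences (e.g. Y-X-Y) the middle angle is returned in
#' `[0, 180]` degrees; for asymmetric sequences (e.g. Z-X-Y) in `[-90, 90]`.
#' At gimbal-degenerate orientations (middle angle at the boundary of its
#' range, where the first and third axes align) only the sum or difference of
#' the outer angles is defined; the convention used is `a3 = 0` with `a1`
#' carrying the free rotation, and the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param R 3x3 rotation matrix.
#' @param seq Euler sequence string.
#' @return numeric length-3 of angles in degrees, with attribute
#'   `degenerate` (logical).
#' @export
euler_intrinsic <- function(R, seq) {
  R <- .check_rotmat(R)
  idx <- .parse_seq(seq)
  Rm <- matrix(as.numeric(R), 1L, 9L)
  ang <- .euler_rows(Rm, seq)
  out <- c(ang$a1, ang$a2, ang$a3)
  attr(out, "degenerate") <- ang$degenerate
  out
}

# Vectorized Euler decomposition from n x 9 column-major matrix elements.
# Returns list(a1, a2, a3, degenerate), angles in degrees.
.euler_rows <- function(Rm, seq) {
  idx <- .parse_seq(seq)
  i <- idx[1L]; j <- idx[2L]; k <- idx[3L]
  el <- function(r, c_) Rm[, (c_ - 1L) * 3L + r]
  n <- nrow(Rm)
  a1 <- numeric(n); a2 <- numeric(n); a3 <- numeric(n)
  if (i == k) {                      # symmetric i-j-i
    l <- 6L - i - j
    eps <- .perm_parity(i, j, l)
    c2 <- pmin(1, pmax(-1, el(i, i)))
    a2 <- acos(c2) / .DEG
    s2 <- sqrt(pmax(0, 1 - c2 * c2))
    deg <- s2 < 1e-8
    ok <- !deg
    a1[ok] <- atan2(el(j, i)[ok], -eps * el(l, i)[ok]) / .DEG
    a3[ok] <- atan2(el(i, j)[ok], eps * el(i, l)[ok]) / .DEG
    if (any(deg)) {
      for (r in which(deg)) {
        R <- matrix(Rm[r, ], 3L, 3L)
        if (c2[r] > 0) {             # a2 ~ 0: R = R_i(a1 + a3)
          a2[r] <- 0
          a1[r] <- .pure_axis_angle(R, i)
        } else {                     # a2 ~ 180: R = R_i(a1 - a3) R_j(180)
          a2[r] <- 180
          a1[r] <- .pure_axis_angle(R %*% t(.rot_elem(j, 180)), i)
        }
        a3[r] <- 0
      }
    }
  } else {                           # asymmetric i-j-k (Tait-Bryan)
    eps <- .perm_parity(i, j, k)
    s2 <- pmin(1, pmax(-1, eps * el(i, k)))
    a2 <- asin(s2) / .DEG
    c2 <- sqrt(pmax(0, 1 - s2 * s2))
    deg <- c2 < 1e-8
    ok <- !deg
    a1[ok] <- atan2(-eps * el(j, k)[ok], el(k, k)[ok]) / .DEG
    a3[ok] <- atan2(-eps * el(i, j)[ok], el(i, i)[ok]) / .DEG
    if (any(deg)) {
      for (r in which(deg)) {
        R <- matrix(Rm[r, ], 3L, 3L)
        # a3 = 0 convention: R = R_i(a1) R_j(+-90)
        a1[r] <- .pure_axis_angle(R %*% t(.rot_elem(j, a2[r])), i)
        a3[r] <- 0
      }
    }
  }
  list(a1 = a1, a2 = a2, a3 = a3, degenerate = as.logical(deg))
}

#' Unwrap a periodic angle series
#'
#' Removes artificial jumps larger than half a period between consecutive
#' samples by adding integer multiples of the period, preserving each value
#' modulo the period. Idempotent.
#'
#' @param x numeric vector of angles (degrees).
#' @param period wrap period in degrees (default 360).
#' @return unwrapped numeric vector of the same length.
#' @export
unwrap_angles <- function(x, period = 360) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("period must be a positive scalar", call. = FALSE)
  n <- length(x)
  if (n <= 1L) return(x)
  x + period * cumsum(c(0, round(-diff(x) / period)))
}
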