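# Centre-of-rotation estimation from rigid marker trajectories.

#' Estimate a fixed centre of rotation from marker trajectories
#'
#' Markers rigidly attached to a segment rotating about a fixed point lie on
#' spheres sharing that point as centre. The centre is recovered by the linear
#' least-squares sphere fit with a centre shared across markers: each
#' observation `y` contributes the equation `2 y'c - g_m = |y|^2`, where
#' `g_m = |c|^2 - r_m^2` is a per-marker nuisance parameter. This is the
#' closed-form member of the pivot / centre-transformation family of
#' calibration methods.
#'
#' @param markers either an `n x 3` matrix (single marker), an
#'   `n x m x 3` array, or a list of `n x 3` matrices (one per marker), all in
#'   a common fixed reference frame, millimetres.
#' @return list with `center` (length-3, mm), `radii` (per-marker fitted
#'   sphere radius, mm) and `residual` (RMS over all observations of the
#'   distance-to-centre deviation from the fitted radius, mm).
#' @export
estimate_rotation_center <- function(markers) {
  if (is.list(markers)) {
    mats <- lapply(markers, function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 3L) stop("each marker trajectory must be n x 3",
                              call. = FALSE)
      m
    })
  } else if (is.array(markers) && length(dim(markers)) == 3L) {
    if (dim(markers)[3L] != 3L)
      stop("marker array must be n x m x 3", call. = FALSE)
    mats <- lapply(seq_len(dim(markers)[2L]),
                   function(j) markers[, j, , drop = TRUE])
  } else {
    m <- as.matrix(markers)
    if (ncol(m) != 3L) stop("marker trajectory must be n x 3", call. = FALSE)
    mats <- list(m)
  }
  nmark <- length(mats)
  nfr <- vapply(mats, nrow, integer(1))
  if (any(nfr < 10L))
    stop("insufficient data: need at least 10 frames per marker",
         call. = FALSE)
  if (any(vapply(mats, function(m) any(!is.finite(m)), logical(1))))
    stop("marker trajectories contain non-finite values", call. = FALSE)

  # rows: [2 y', indicator(marker)] %*% c(center, g_1..g_m) = |y|^2
  A <- matrix(0, sum(nfr), 3L + nmark)
  b <- numeric(sum(nfr))
  at <- 0L
  for (m in seq_len(nmark)) {
    y <- mats[[m]]
    rows <- at + seq_len(nrow(y))
    A[rows, 1:3] <- 2 * y
    A[rows, 3L + m] <- -1
    b[rows] <- rowSums(y * y)
    at <- at + nrow(y)
  }
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[length(sv)] < max(sv) * 1e-10)
    stop(paste("rank-deficiency: marker motion does not determine a",
               "rotation centre (no rotation observed)"), call. = FALSE)
  coef <- qr.solve(A, b)
  center <- coef[1:3]
  g <- coef[3L + seq_len(nmark)]        # g_m = |c|^2 - r_m^2
  r2 <- sum(center * center) - g
  if (any(r2 < 0))
    stop("rank-deficiency: degenerate sphere fit", call. = FALSE)
  radii <- sqrt(r2)
  res2 <- 0
  for (m in seq_len(nmark)) {
    d <- sqrt(rowSums(sweep(mats[[m]], 2L, center)^2))
    res2 <- res2 + sum((d - radii[m])^2)
  }
  list(center = unname(center), radii = unname(radii),
       residual = sqrt(res2 / sum(nfr)))
}
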