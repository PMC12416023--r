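# Filtering, resampling and time alignment.

#' Butterworth filter specification
#'
#' @param order filter order of the single-pass Butterworth design (even,
#'   >= 2). Zero-phase forward-backward application squares the magnitude
#'   response.
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param rate sampling rate, Hz.
#' @param zero_phase logical; apply forward-backward (default `TRUE`).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff, rate, zero_phase = TRUE) {
  if (order < 2L || order %% 2L != 0L)
    stop("filter order must be an even integer >= 2", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must satisfy 0 < cutoff < rate / 2", call. = FALSE)
  structure(list(order = as.integer(order), cutoff = cutoff, rate = rate,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase Butterworth filtering
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase;
#' effective magnitude response is the square of the single-pass response).
#' Edges are handled by odd-reflection padding of length `3 * order` at both
#' ends. DC gain is exactly 1: a constant series passes unchanged.
#'
#' @param x numeric vector, or matrix with one channel per column.
#' @param spec a [filter_spec()].
#' @return filtered series, same shape as `x`.
#' @export
butterworth_zero_phase <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  mat <- is.matrix(x)
  X <- if (mat) x else matrix(x, ncol = 1L)
  n <- nrow(X)
  if (n <= 3L * spec$order)
    stop("insufficient data: series length must exceed 3 x filter order",
         call. = FALSE)
  bf <- signal::butter(spec$order, 2 * spec$cutoff / spec$rate,
                       type = "low")
  pad <- 3L * spec$order
  # one filter pass with the initial level removed, so the zero-state
  # startup transient is excited only by actual signal change and a
  # constant input passes exactly (DC gain 1)
  pass <- function(v) {
    v0 <- v[1L]
    as.numeric(signal::filter(bf, v - v0)) + v0
  }
  out <- X
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    # odd reflection about the end samples bounds startup transients
    left <- 2 * v[1L] - v[(pad + 1L):2L]
    right <- 2 * v[n] - v[(n - 1L):(n - pad)]
    vp <- c(left, v, right)
    f <- pass(vp)
    if (spec$zero_phase) f <- rev(pass(rev(f)))
    out[, j] <- f[(pad + 1L):(pad + n)]
  }
  if (mat) out else out[, 1L]
}

#' Resample a uniformly sampled series
#'
#' Scalar channels are interpolated with a cubic spline (exact on
#' polynomials up to degree 3); orientation channels are interpolated by
#' SLERP between adjacent frames. When the two rates share a coincident
#' sample grid, the input samples are preserved exactly at coincident
#' timestamps.
#'
#' @param x numeric vector / matrix (kind "scalar") or `n x 4` quaternion
#'   matrix (kind "orientation").
#' @param from_rate,to_rate sampling rates, Hz. For upsampling, `to_rate`
#'   must be an integer multiple of `from_rate` (and conversely for
#'   downsampling).
#' @param kind `"scalar"` or `"orientation"`.
#' @return resampled series with `(n - 1) * to_rate / from_rate + 1` rows.
#' @export
resample <- function(x, from_rate, to_rate, kind = c("scalar", "orientation")) {
  kind <- match.arg(kind)
  ratio <- to_rate / from_rate
  up <- ratio >= 1
  if (up && abs(ratio - round(ratio)) > 1e-9)
    stop("to_rate must be an integer multiple of from_rate for upsampling",
         call. = FALSE)
  if (!up && abs(1 / ratio - round(1 / ratio)) > 1e-9)
    stop("from_rate must be an integer multiple of to_rate for downsampling",
         call. = FALSE)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  n <- nrow(X)
  if (!up) {                      # exact decimation on the coincident grid
    idx <- seq(1L, n, by = as.integer(round(1 / ratio)))
    out <- X[idx, , drop = FALSE]
    return(if (is.matrix(x)) out else out[, 1L])
  }
  ratio <- as.integer(round(ratio))
  m <- (n - 1L) * ratio + 1L
  told <- (seq_len(n) - 1L) / from_rate
  tnew <- (seq_len(m) - 1L) / to_rate
  if (kind == "scalar") {
    out <- matrix(NA_real_, m, ncol(X))
    for (j in seq_len(ncol(X)))
      out[, j] <- spline(told, X[, j], xout = tnew, method = "fmm")$y
    # input samples preserved exactly at coincident timestamps
    out[seq(1L, m, by = ratio), ] <- X
    return(if (is.matrix(x)) out else out[, 1L])
  }
  if (ncol(X) != 4L)
    stop("orientation resampling expects an n x 4 quaternion matrix",
         call. = FALSE)
  out <- matrix(NA_real_, m, 4L)
  out[seq(1L, m, by = ratio), ] <- X
  for (i in seq_len(n - 1L)) {
    q0 <- X[i, ]; q1 <- X[i + 1L, ]
    for (s in seq_len(ratio - 1L))
      out[(i - 1L) * ratio + 1L + s, ] <- slerp(q0, q1, s / ratio)
  }
  out
}

#' Cross-correlation time alignment of two angle series
#'
#' Finds the integer-sample lag (within `+- max_lag` seconds) that maximizes
#' the normalized cross-correlation of the mean-removed signals, and returns
#' the pair truncated to the common support. A positive lag means `a` lags
#' `b` (the content of `a` at index `t` matches `b` at `t - lag`). Ties are
#' broken toward the smallest `|lag|`.
#'
#' @param a,b numeric vectors sampled at the same `rate`.
#' @param rate sampling rate, Hz.
#' @param max_lag search half-window, seconds (default 2).
#' @return list with `lag` (integer samples), `a_aligned`, `b_aligned`
#'   (equal-length vectors on the common support) and `correlation` at the
#'   chosen lag.
#' @export
cross_correlation_align <- function(a, b, rate, max_lag = 2) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sd(a) < 1e-12 || sd(b) < 1e-12)
    stop("undefined correlation: input signal has zero variance",
         call. = FALSE)
  L <- as.integer(round(max_lag * rate))
  n <- min(length(a), length(b))
  if (n <= 2L * L)
    stop("overlapping duration must exceed 2 x max_lag", call. = FALSE)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ai <- (1L + l):n; bi <- 1L:(n - l)
    } else {
      ai <- 1L:(n + l); bi <- (1L - l):n
    }
    suppressWarnings(cor(a[ai], b[bi]))
  }, numeric(1))
  cc[is.na(cc)] <- -Inf
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  lag <- cand[which.min(abs(cand))]
  if (lag >= 0) {
    ai <- (1L + lag):n; bi <- 1L:(n - lag)
  } else {
    ai <- 1L:(n + lag); bi <- (1L - lag):n
  }
  list(lag = as.integer(lag), a_aligned = a[ai], b_aligned = b[bi],
       correlation = cc[match(lag, lags)])
}
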