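# Timestamped measurement streams and joint-angle tables.

.check_uniform_time <- function(time, rate, what = "series") {
  if (length(time) < 1L || anyNA(time) || any(!is.finite(time)))
    stop(what, ": timestamps must be finite", call. = FALSE)
  if (length(time) > 1L) {
    if (any(diff(time) <= 0))
      stop(what, ": timestamps must be strictly increasing", call. = FALSE)
    expected <- (length(time) - 1) / rate
    if (abs((time[length(time)] - time[1L]) - expected) > 0.5 / rate)
      stop(what, ": timestamps inconsistent with declared rate",
           call. = FALSE)
  }
  invisible(time)
}

#' Keypoint time series
#'
#' Named 3D joint-centre positions (mm) per frame at a uniform rate, with a
#' per-point validity flag (misdetected points are flagged invalid and carry
#' no numeric guarantee).
#'
#' @param time timestamps in seconds, strictly increasing, uniform.
#' @param points `n x k x 3` array with marker names as the second dimnames.
#' @param rate sampling rate in Hz.
#' @param valid `n x k` logical matrix; defaults to all valid.
#' @return object of class `keypoint_series`.
#' @export
keypoint_series <- function(time, points, rate, valid = NULL) {
  if (!is.array(points) || length(dim(points)) != 3L || dim(points)[3L] != 3L)
    stop("points must be an n x k x 3 array", call. = FALSE)
  if (is.null(dimnames(points)[[2L]]))
    stop("points must carry keypoint names", call. = FALSE)
  n <- dim(points)[1L]
  if (length(time) != n)
    stop("length(time) must match the number of frames", call. = FALSE)
  .check_uniform_time(time, rate, "keypoint_series")
  if (is.null(valid)) valid <- matrix(TRUE, n, dim(points)[2L])
  if (!is.logical(valid) || !all(dim(valid) == dim(points)[1:2]))
    stop("valid must be an n x k logical matrix", call. = FALSE)
  colnames(valid) <- dimnames(points)[[2L]]
  structure(list(time = as.numeric(time), points = points, valid = valid,
                 rate = rate),
            class = "keypoint_series")
}

#' Segment orientation time series
#'
#' Named unit quaternions (scalar first) per body segment per frame at a
#' uniform rate.
#'
#' @param time timestamps in seconds.
#' @param quats `n x s x 4` array with segment names as the second dimnames;
#'   rows are normalized on construction.
#' @param rate sampling rate in Hz.
#' @return object of class `orientation_series`.
#' @export
orientation_series <- function(time, quats, rate) {
  if (!is.array(quats) || length(dim(quats)) != 3L || dim(quats)[3L] != 4L)
    stop("quats must be an n x s x 4 array", call. = FALSE)
  if (is.null(dimnames(quats)[[2L]]))
    stop("quats must carry segment names", call. = FALSE)
  n <- dim(quats)[1L]
  if (length(time) != n)
    stop("length(time) must match the number of frames", call. = FALSE)
  .check_uniform_time(time, rate, "orientation_series")
  for (s in seq_len(dim(quats)[2L]))
    quats[, s, ] <- .quat_rows_normalize(quats[, s, , drop = TRUE])
  structure(list(time = as.numeric(time), quats = quats, rate = rate),
            class = "orientation_series")
}

#' Uniformly sampled angle series
#'
#' @param time timestamps in seconds, strictly increasing, uniform.
#' @param values angles in degrees.
#' @param rate sampling rate in Hz.
#' @param label channel label.
#' @return object of class `angle_series`.
#' @export
angle_series <- function(time, values, rate, label = "angle") {
  if (length(time) != length(values))
    stop("time and values must have equal length", call. = FALSE)
  .check_uniform_time(time, rate, "angle_series")
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 rate = rate, label = label),
            class = "angle_series")
}

#' Joint-angle channel names analysed for agreement
#'
#' The four angle sets compared between systems: shoulder plane of elevation,
#' shoulder angle of elevation, shoulder rotation, elbow flexion. Forearm
#' pronation is carried in tables where available but excluded from agreement
#' analysis (its tracking is degenerate; see [axis_independence_test()]).
#'
#' @return character vector of channel names.
#' @export
angle_channels <- function() {
  c("plane_of_elevation", "angle_of_elevation", "shoulder_rotation",
    "elbow_flexion")
}

#' Per-frame joint-angle table
#'
#' A data frame with a `time` column, one column per angle channel (degrees,
#' unwrapped), and a logical `gimbal` column flagging frames where the
#' shoulder Y-X-Y decomposition is degenerate (elevation within 1 degree of 0
#' or 180, where plane of elevation and axial rotation are not separable).
#' Trial metadata (rate, method, placement, movement, participant) is stored
#' in attributes.
#'
#' @param time timestamps (s).
#' @param channels named list or data frame of angle columns (deg).
#' @param rate sampling rate (Hz).
#' @param method one of "CF", "IK", "reference", "truth".
#' @param placement camera placement label ("frontal", "sagittal" or NA).
#' @param movement movement name or NA.
#' @param participant participant id or NA.
#' @param gimbal optional logical vector; computed from `angle_of_elevation`
#'   when absent.
#' @return object of class `joint_angle_table` (a data frame).
#' @export
joint_angle_table <- function(time, channels, rate, method = NA_character_,
                              placement = NA_character_,
                              movement = NA_character_,
                              participant = NA_character_, gimbal = NULL) {
  channels <- as.data.frame(channels)
  if (!all(angle_channels() %in% names(channels)))
    stop("missing angle channels: ",
         paste(setdiff(angle_channels(), names(channels)), collapse = ", "),
         call. = FALSE)
  if (nrow(channels) != length(time))
    stop("channel length must match time", call. = FALSE)
  .check_uniform_time(time, rate, "joint_angle_table")
  if (is.null(gimbal))
    gimbal <- channels$angle_of_elevation < 1 |
      channels$angle_of_elevation > 179
  df <- cbind(data.frame(time = as.numeric(time)), channels,
              data.frame(gimbal = as.logical(gimbal)))
  structure(df, class = c("joint_angle_table", "data.frame"),
            rate = rate, method = method, placement = placement,
            movement = movement, participant = participant)
}

#' @export
print.joint_angle_table <- function(x, ...) {
  cat(sprintf("joint_angle_table: %d frames at %g Hz (method=%s, %s, %s)\n",
              nrow(x), attr(x, "rate"), attr(x, "method"),
              attr(x, "movement"), attr(x, "placement")))
  chans <- setdiff(names(x), c("time", "gimbal"))
  for (ch in chans)
    cat(sprintf("  %-22s range [%8.2f, %8.2f] deg\n", ch,
                min(x[[ch]]), max(x[[ch]])))
  cat(sprintf("  gimbal-flagged frames: %d\n", sum(x$gimbal)))
  invisible(x)
}
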