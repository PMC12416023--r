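# The two joint-angle computation methods under comparison.
#
# CF (coordinate-frame): joint angles directly from measured segment
# orientations via relative rotations and intrinsic Euler decomposition
# (shoulder Y-X-Y, elbow Z-X-Y with flexion leading).
# IK (inverse kinematics): per-frame bounded least squares fitting the limb
# model's virtual keypoints to measured keypoints, warm-started across
# frames, with a small continuity penalty that breaks the plane-of-elevation
# indeterminacy near zero elevation.

#' Inverse-kinematics solver settings
#'
#' @param weights named non-negative keypoint weights (`shoulder`, `elbow`,
#'   `wrist`, `hand`). At least 3 must be positive.
#' @param pronation_locked lock the pronation DOF (default `TRUE`: the
#'   pronation axis is collinear with the shoulder axial-rotation axis when
#'   the elbow is extended, and the hand keypoint that would disambiguate it
#'   tracks poorly).
#' @param thumb_excluded exclude the hand/thumb keypoint (forces its weight
#'   to 0; default `TRUE`).
#' @param tolerance convergence tolerance on the per-frame step, degrees.
#' @param max_iterations per-frame iteration cap.
#' @param warm_start start each frame from the previous frame's solution
#'   (frame 0 starts from `start_pose`).
#' @param lambda continuity penalty weight on `|q - q_prev|^2`.
#' @param start_pose length-5 starting pose, degrees.
#' @return object of class `ik_settings`.
#' @export
ik_settings <- function(weights = c(shoulder = 1, elbow = 1, wrist = 1,
                                    hand = 0),
                        pronation_locked = TRUE, thumb_excluded = TRUE,
                        tolerance = 1e-6, max_iterations = 50L,
                        warm_start = TRUE, lambda = 1e-6,
                        start_pose = c(0, 0, 0, 0, 0)) {
  need <- c("shoulder", "elbow", "wrist", "hand")
  if (!all(need %in% names(weights)))
    stop("weights must name shoulder, elbow, wrist, hand", call. = FALSE)
  weights <- weights[need]
  if (any(weights < 0)) stop("keypoint weights must be >= 0", call. = FALSE)
  if (thumb_excluded) weights[["hand"]] <- 0
  if (sum(weights > 0) < 3L)
    stop("at least 3 keypoints must have positive weight", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(weights = weights, pronation_locked = pronation_locked,
                 thumb_excluded = thumb_excluded, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 warm_start = isTRUE(warm_start), lambda = lambda,
                 start_pose = as.numeric(start_pose)),
            class = "ik_settings")
}

.wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Solver settings for the marker-based reference channel
#'
#' The reference marker set is complete and reliable, so all keypoints carry
#' weight and the pronation DOF is free.
#'
#' @param ... overrides passed to [ik_settings()].
#' @return an [ik_settings()].
#' @export
reference_ik_settings <- function(...) {
  defaults <- list(weights = c(shoulder = 1, elbow = 1, wrist = 1, hand = 1),
                   pronation_locked = FALSE, thumb_excluded = FALSE)
  do.call(ik_settings, modifyList(defaults, list(...)))
}

# upsample angle channels + gimbal flag to out_rate
.upsample_table <- function(channels, gimbal, from_rate, to_rate) {
  if (to_rate == from_rate)
    return(list(channels = as.data.frame(channels), gimbal = gimbal,
                rate = from_rate))
  X <- as.matrix(as.data.frame(channels))
  up <- resample(X, from_rate, to_rate, kind = "scalar")
  colnames(up) <- colnames(X)
  ratio <- as.integer(round(to_rate / from_rate))
  g <- rep(gimbal, each = ratio)[seq_len(nrow(up))]
  list(channels = as.data.frame(up), gimbal = g, rate = to_rate)
}

#' Joint angles by the coordinate-frame (CF) method
#'
#' Pipeline: smooth the per-segment quaternions on the rotation manifold
#' ([slerp_smooth()]), realign the device segment frames to the ISB
#' definitions with the supplied per-segment rotations, form the joint
#' rotations (thorax-to-humerus and humerus-to-forearm), decompose to
#' intrinsic Euler angles (shoulder Y-X-Y via the right-arm convention,
#' elbow Z-X-Y with flexion leading), unwrap for continuity, then upsample to
#' the output rate.
#'
#' @param orientations an [orientation_series()] containing `thorax`,
#'   `humerus` and `forearm`.
#' @param realignment named list (thorax/humerus/forearm) of unit quaternions
#'   or 3x3 rotation matrices applied in each segment's own frame to undo the
#'   device frame convention; `NULL` for identity. See
#'   [realignment_from_offsets()].
#' @param alpha SLERP smoothing weight in `(0, 1]`; 1 disables smoothing.
#' @param out_rate output sampling rate, Hz.
#' @param upsample resample to `out_rate` (default `TRUE`).
#' @param movement,placement,participant metadata carried into the table.
#' @return a [joint_angle_table()] with the four analysed channels plus
#'   `pronation`.
#' @export
cf_joint_angles <- function(orientations, realignment = NULL, alpha = 0.5,
                            out_rate = 120, upsample = TRUE,
                            movement = NA_character_,
                            placement = NA_character_,
                            participant = NA_character_) {
  stopifnot(inherits(orientations, "orientation_series"))
  segs <- dimnames(orientations$quats)[[2L]]
  for (s in c("thorax", "humerus", "forearm"))
    if (!s %in% segs)
      stop("missing segment in orientation series: ", s, call. = FALSE)
  getQ <- function(s) {
    Q <- orientations$quats[, s, , drop = TRUE]
    if (is.null(dim(Q))) Q <- matrix(Q, 1L, 4L)
    Q <- slerp_smooth(Q, alpha)
    re <- realignment[[s]]
    if (!is.null(re)) {
      if (is.matrix(re)) re <- matrix_to_quat(re)
      Q <- .quat_rows_multiply(Q, quat_normalize(re))
    }
    Q
  }
  q_th <- getQ("thorax"); q_hu <- getQ("humerus"); q_fo <- getQ("forearm")
  q_sh <- .quat_rows_multiply(.quat_rows_conjugate(q_th), q_hu)
  q_el <- .quat_rows_multiply(.quat_rows_conjugate(q_hu), q_fo)
  sh <- .shoulder_rows(.euler_rows(.quat_rows_to_Rm(q_sh), "YXY"))
  el <- .euler_rows(.quat_rows_to_Rm(q_el), "ZXY")
  # right-arm reporting convention (see shoulder_angles_from_matrix)
  channels <- list(
    plane_of_elevation = unwrap_angles(sh$plane),
    angle_of_elevation = sh$elev,
    shoulder_rotation = unwrap_angles(sh$rot),
    elbow_flexion = unwrap_angles(el$a1),
    pronation = unwrap_angles(el$a3))
  gim <- sh$degenerate | channels$angle_of_elevation < 1 |
    channels$angle_of_elevation > 179
  res <- .upsample_table(channels, gim, orientations$rate,
                         if (upsample) out_rate else orientations$rate)
  time <- (seq_len(nrow(res$channels)) - 1L) / res$rate +
    orientations$time[1L]
  joint_angle_table(time, res$channels, res$rate, method = "CF",
                    placement = placement, movement = movement,
                    participant = participant, gimbal = res$gimbal)
}

# shared IK driver for markerless and reference channels
.ik_angles <- function(keypoints, model, settings, filter, out_rate,
                       upsample, method, movement, placement, participant) {
  stopifnot(inherits(keypoints, "keypoint_series"),
            inherits(model, "limb_model"),
            inherits(settings, "ik_settings"))
  kp_names <- c("shoulder", "elbow", "wrist", "hand")
  have <- dimnames(keypoints$points)[[2L]]
  for (s in c("shoulder", "elbow", "wrist"))
    if (!s %in% have)
      stop("missing keypoint: ", s, call. = FALSE)
  n <- length(keypoints$time)
  targets <- matrix(NA_real_, n, 12L)
  usable <- matrix(FALSE, n, 4L)
  for (k in seq_along(kp_names)) {
    nm <- kp_names[k]
    if (!nm %in% have) next
    P <- keypoints$points[, nm, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, 1L, 3L)
    v <- keypoints$valid[, nm]
    # gap-fill misdetections before filtering so outliers do not smear
    if (any(!v) && any(v)) {
      idx <- seq_len(n)
      for (a in 1:3)
        P[!v, a] <- approx(idx[v], P[v, a], xout = idx[!v], rule = 2)$y
    }
    if (!is.null(filter)) P <- butterworth_zero_phase(P, filter)
    targets[, (3L * (k - 1L) + 1L):(3L * k)] <- P
    usable[, k] <- v
  }
  free <- c(TRUE, TRUE, TRUE, TRUE, !settings$pronation_locked)
  limits <- do.call(rbind, model$limits)
  fit <- .ik_solve_cpp(targets, usable,
                       c(model$humerus_length, model$forearm_length,
                         model$clavicle_offset, model$hand_offset),
                       as.numeric(settings$weights), settings$start_pose,
                       limits, free, settings$lambda, settings$tolerance,
                       settings$max_iterations, settings$warm_start)
  poses <- fit$poses
  unresolved <- !fit$resolved
  if (any(unresolved)) {
    if (all(unresolved))
      stop("no frame has at least 3 usable keypoints", call. = FALSE)
    idx <- seq_len(n)
    for (j in 1:5)
      poses[unresolved, j] <- approx(idx[!unresolved], poses[!unresolved, j],
                                     xout = idx[unresolved], rule = 2)$y
    if (mean(unresolved) > 0.1)
      warning(sprintf("trial has %.1f%% unresolved frames",
                      100 * mean(unresolved)), call. = FALSE)
  }
  channels <- list(plane_of_elevation = unwrap_angles(poses[, 1L]),
                   angle_of_elevation = poses[, 2L],
                   shoulder_rotation = unwrap_angles(poses[, 3L]),
                   elbow_flexion = unwrap_angles(poses[, 4L]),
                   pronation = unwrap_angles(poses[, 5L]))
  gim <- channels$angle_of_elevation < 1 | channels$angle_of_elevation > 179
  res <- .upsample_table(channels, gim, keypoints$rate,
                         if (upsample) out_rate else keypoints$rate)
  time <- (seq_len(nrow(res$channels)) - 1L) / res$rate + keypoints$time[1L]
  tab <- joint_angle_table(time, res$channels, res$rate, method = method,
                           placement = placement, movement = movement,
                           participant = participant, gimbal = res$gimbal)
  attr(tab, "ik_objective") <- fit$objective
  attr(tab, "ik_iterations") <- fit$iterations
  attr(tab, "n_unresolved") <- sum(unresolved)
  tab
}

#' Joint angles by inverse kinematics (IK)
#'
#' Per frame, finds the in-limit pose minimizing the weighted squared
#' Euclidean distance between the model's virtual keypoints and the measured
#' keypoints (plus a tiny continuity penalty toward the previous frame's
#' solution). Keypoints are gap-filled at misdetections, low-pass filtered at
#' the native rate, the solution warm-starts from the previous frame, and the
#' resulting angle channels are upsampled to the output rate. Frames with
#' fewer than 3 usable keypoints are marked unresolved and interpolated from
#' their neighbours.
#'
#' @param keypoints a [keypoint_series()] with `shoulder`, `elbow`, `wrist`
#'   (and optionally `hand`).
#' @param model a [limb_model()], typically scaled via
#'   [scale_model_from_keypoints()].
#' @param settings an [ik_settings()].
#' @param filter a [filter_spec()] applied to keypoint coordinates before
#'   solving; `NULL` to skip. Default: 4th-order 5 Hz at the native rate.
#' @param out_rate,upsample output rate handling as in [cf_joint_angles()].
#' @param movement,placement,participant metadata.
#' @return a [joint_angle_table()]; attributes `ik_objective`,
#'   `ik_iterations`, `n_unresolved` carry solver diagnostics.
#' @export
ik_joint_angles <- function(keypoints, model, settings = ik_settings(),
                            filter = filter_spec(4L, 5, keypoints$rate),
                            out_rate = 120, upsample = TRUE,
                            movement = NA_character_,
                            placement = NA_character_,
                            participant = NA_character_) {
  .ik_angles(keypoints, model, settings, filter, out_rate, upsample,
             method = "IK", movement = movement, placement = placement,
             participant = participant)
}

#' Reference joint angles from the marker-based channel
#'
#' Same inverse-kinematics procedure as [ik_joint_angles()] but with the
#' reference filter (default 4th-order 8 Hz at 120 Hz) and no upsampling:
#' the output rate equals the input rate. Unlike the markerless default, the
#' reference marker set is complete and well-tracked, so the hand marker is
#' included and pronation is left free — every degree of freedom is
#' observable in every posture.
#'
#' @inheritParams ik_joint_angles
#' @return a [joint_angle_table()] at the input rate, method `"reference"`.
#' @export
compute_reference_angles <- function(keypoints, model,
                                     settings = reference_ik_settings(),
                                     filter = filter_spec(4L, 8,
                                                          keypoints$rate),
                                     movement = NA_character_,
                                     placement = NA_character_,
                                     participant = NA_character_) {
  .ik_angles(keypoints, model, settings, filter, out_rate = keypoints$rate,
             upsample = FALSE, method = "reference", movement = movement,
             placement = placement, participant = participant)
}

#' Time-align two joint-angle tables by cross-correlation
#'
#' Chooses a sync channel, estimates a single integer-sample lag by
#' [cross_correlation_align()], and truncates both tables to the common
#' support. The sync channel is the first sufficiently moving channel
#' (SD above 2 degrees in both tables) in a fixed priority order — angle of
#' elevation, elbow flexion, pronation, shoulder rotation, plane of
#' elevation — so that channels that are intermittently unobservable (and
#' hence noise-dominated) are only used when nothing better moves. When no
#' channel moves (so correlation is undefined) the lag falls back to 0 with
#' a warning.
#'
#' @param test,reference [joint_angle_table()]s at the same rate.
#' @param max_lag search half-window, seconds.
#' @return list with `test`, `reference` (aligned tables), `lag`
#'   (integer samples; positive when `test` lags `reference`) and
#'   `sync_channel`.
#' @export
align_angle_tables <- function(test, reference, max_lag = 2) {
  rate <- attr(test, "rate")
  if (!isTRUE(all.equal(rate, attr(reference, "rate"))))
    stop("tables must share a sampling rate", call. = FALSE)
  priority <- c("angle_of_elevation", "elbow_flexion", "pronation",
                "shoulder_rotation", "plane_of_elevation")
  chans <- intersect(priority, intersect(names(reference), names(test)))
  n <- min(nrow(test), nrow(reference))
  ch <- NA_character_
  for (cand in chans) {
    if (sd(reference[[cand]][seq_len(n)]) > 2 &&
        sd(test[[cand]][seq_len(n)]) > 2) { ch <- cand; break }
  }
  if (is.na(ch)) {
    warning("all channels near-constant; sync lag set to 0", call. = FALSE)
    lag <- 0L
  } else {
    al <- cross_correlation_align(test[[ch]][seq_len(n)],
                                  reference[[ch]][seq_len(n)], rate,
                                  max_lag = max_lag)
    lag <- al$lag
  }
  if (lag >= 0) {
    ti <- (1L + lag):n; ri <- 1L:(n - lag)
  } else {
    ti <- 1L:(n + lag); ri <- (1L - lag):n
  }
  list(test = .subset_table(test, ti),
       reference = .subset_table(reference, ri), lag = lag,
       sync_channel = ch)
}

# subset a joint_angle_table while preserving metadata attributes
.subset_table <- function(tab, idx) {
  out <- as.data.frame(tab)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("joint_angle_table", "data.frame"),
            rate = attr(tab, "rate"), method = attr(tab, "method"),
            placement = attr(tab, "placement"),
            movement = attr(tab, "movement"),
            participant = attr(tab, "participant"))
}

#' Per-frame angle differences between an aligned table pair
#'
#' Computes `test - reference` on the common support for the four analysed
#' angle channels (pronation is excluded from agreement analysis). For the
#' plane-of-elevation and shoulder-rotation channels, frames flagged
#' gimbal-degenerate in either table are dropped (those angles are not
#' separable there).
#'
#' @param test,reference aligned, equal-rate [joint_angle_table()]s of equal
#'   length (see [align_angle_tables()]).
#' @return named list of numeric difference vectors (degrees), one per
#'   channel in [angle_channels()], with the test table's metadata attached
#'   as attributes.
#' @export
build_difference_sets <- function(test, reference) {
  if (nrow(test) != nrow(reference) || nrow(test) == 0L)
    stop("tables must be aligned to a common, non-empty support",
         call. = FALSE)
  if (!isTRUE(all.equal(attr(test, "rate"), attr(reference, "rate"))))
    stop("tables must share a sampling rate", call. = FALSE)
  gim <- test$gimbal | reference$gimbal
  out <- lapply(angle_channels(), function(ch) {
    d <- test[[ch]] - reference[[ch]]
    if (ch %in% c("plane_of_elevation", "shoulder_rotation")) {
      # circular channels: compare modulo 360 so that an unwrap branch
      # difference between the two series does not masquerade as bias
      d <- .wrap180(d[!gim])
    }
    d
  })
  names(out) <- angle_channels()
  attr(out, "method") <- attr(test, "method")
  attr(out, "placement") <- attr(test, "placement")
  attr(out, "movement") <- attr(test, "movement")
  attr(out, "participant") <- attr(test, "participant")
  out
}
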