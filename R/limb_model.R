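# Kinematic chain of the upper limb.
#
# The chain is thorax (fixed at the origin, identity orientation: seated
# subject) -> ball-and-socket shoulder at a fixed clavicle offset ->
# 1-DOF elbow flexion -> 1-DOF forearm pronation (lockable). Shoulder girdle
# (clavicle/scapula) motion is collapsed into the glenohumeral joint, matching
# the information content of single-camera keypoints, which carry no scapular
# landmarks.
#
# The shoulder generalized coordinates are the ISB-style Y-X-Y angles:
# plane of elevation (0 = abduction plane, +90 = forward flexion), angle of
# elevation (>= 0) and axial rotation. Internally
# R_shoulder = Ry(plane) %*% Rx(-elevation) %*% Ry(rotation): the elevation is
# a negative X rotation for the right arm (lab frame X anterior, Y up, Z
# right), the standard right-arm convention. Elbow flexion rotates about the
# humerus Z (lateral) axis, pronation about the forearm long (Y) axis.

.POSE_NAMES <- c("plane_of_elevation", "angle_of_elevation",
                 "shoulder_rotation", "elbow_flexion", "pronation")

.KEYPOINT_NAMES <- c("sternum", "c7_proxy", "shoulder", "elbow", "wrist",
                     "hand")

#' Construct an upper-limb kinematic model
#'
#' @param humerus_length,forearm_length segment lengths, mm.
#' @param thorax_height thorax vertical extent, mm (sternum top to pelvis;
#'   used for proportional scaling only).
#' @param clavicle_offset length-3 vector, mm: shoulder joint centre relative
#'   to the thorax origin (sternum top), lab frame.
#' @param c7_offset length-3, mm: C7-proxy keypoint relative to the thorax
#'   origin.
#' @param hand_offset length-3, mm: hand/thumb keypoint relative to the wrist,
#'   expressed in the forearm frame (off the long axis so that pronation is
#'   observable from it).
#' @param limits named list of `c(lo, hi)` joint limits in degrees for
#'   `plane_of_elevation`, `angle_of_elevation`, `shoulder_rotation`,
#'   `elbow_flexion`, `pronation`.
#' @return object of class `limb_model`.
#' @export
limb_model <- function(humerus_length = 300, forearm_length = 260,
                       thorax_height = 500,
                       clavicle_offset = c(0, -40, 180),
                       c7_offset = c(-60, 20, 0),
                       hand_offset = c(30, -80, 0),
                       limits = default_joint_limits()) {
  lens <- c(humerus_length = humerus_length, forearm_length = forearm_length,
            thorax_height = thorax_height)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all segment lengths must be positive", call. = FALSE)
  if (!all(.POSE_NAMES %in% names(limits)))
    stop("limits must cover all joint coordinates", call. = FALSE)
  for (nm in .POSE_NAMES) {
    l <- limits[[nm]]
    if (length(l) != 2L || l[1L] >= l[2L])
      stop("limit for ", nm, " must satisfy lo < hi", call. = FALSE)
  }
  structure(list(humerus_length = humerus_length,
                 forearm_length = forearm_length,
                 thorax_height = thorax_height,
                 clavicle_offset = as.numeric(clavicle_offset),
                 c7_offset = as.numeric(c7_offset),
                 hand_offset = as.numeric(hand_offset),
                 limits = limits[.POSE_NAMES]),
            class = "limb_model")
}

#' Default joint range-of-motion limits (degrees)
#'
#' Config-overridable defaults spanning a realistic active range of motion.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
default_joint_limits <- function() {
  list(plane_of_elevation = c(-90, 130),
       angle_of_elevation = c(0, 180),
       shoulder_rotation = c(-90, 90),
       elbow_flexion = c(0, 150),
       pronation = c(-90, 90))
}

#' Default anthropometric model scaled to a participant
#'
#' All linear dimensions scale multiplicatively; `participant_scale = 1`
#' gives the reference anthropometry (humerus 300 mm, forearm 260 mm).
#'
#' @param participant_scale positive scale factor (realistic adult range is
#'   about 0.8 to 1.2).
#' @return a [limb_model()].
#' @export
default_model <- function(participant_scale = 1) {
  if (!is.numeric(participant_scale) || length(participant_scale) != 1L ||
      !is.finite(participant_scale) || participant_scale <= 0)
    stop("participant_scale must be a positive scalar", call. = FALSE)
  s <- participant_scale
  limb_model(humerus_length = 300 * s, forearm_length = 260 * s,
             thorax_height = 500 * s,
             clavicle_offset = c(0, -40, 180) * s,
             c7_offset = c(-60, 20, 0) * s,
             hand_offset = c(30, -80, 0) * s)
}

#' @export
print.limb_model <- function(x, ...) {
  cat(sprintf("limb_model: humerus %.1f mm, forearm %.1f mm, thorax %.1f mm\n",
              x$humerus_length, x$forearm_length, x$thorax_height))
  for (nm in names(x$limits))
    cat(sprintf("  %-22s [%6.1f, %6.1f] deg\n", nm, x$limits[[nm]][1L],
                x$limits[[nm]][2L]))
  invisible(x)
}

.check_pose <- function(model, pose) {
  pose <- as.numeric(pose)
  if (length(pose) != 5L)
    stop("pose must have 5 coordinates (", paste(.POSE_NAMES, collapse = ", "),
         ")", call. = FALSE)
  names(pose) <- .POSE_NAMES
  for (nm in .POSE_NAMES) {
    l <- model$limits[[nm]]
    if (pose[[nm]] < l[1L] - 1e-9 || pose[[nm]] > l[2L] + 1e-9)
      stop(sprintf("limit violation: %s = %.3f outside [%.1f, %.1f]",
                   nm, pose[[nm]], l[1L], l[2L]), call. = FALSE)
  }
  pose
}

# Batched forward kinematics. poses: n x 5 matrix (degrees).
# Returns list(keypoints = n x 6 x 3 array, quats = n x 3 x 4 array
# with segments thorax, humerus, forearm).
.fk_batch <- function(model, poses) {
  poses <- rbind(poses)
  n <- nrow(poses)
  q_hum <- .quat_rows_multiply(
    .quat_rows_multiply(.quat_axis_rows("y", poses[, 1L]),
                        .quat_axis_rows("x", -poses[, 2L])),
    .quat_axis_rows("y", poses[, 3L]))
  q_fore <- .quat_rows_multiply(
    .quat_rows_multiply(q_hum, .quat_axis_rows("z", poses[, 4L])),
    .quat_axis_rows("y", poses[, 5L]))
  S <- matrix(model$clavicle_offset, n, 3L, byrow = TRUE)
  elbow <- S + .quat_rows_rotate(q_hum, c(0, -model$humerus_length, 0))
  wrist <- elbow + .quat_rows_rotate(q_fore, c(0, -model$forearm_length, 0))
  hand <- wrist + .quat_rows_rotate(q_fore, model$hand_offset)
  kp <- array(NA_real_, c(n, 6L, 3L),
              dimnames = list(NULL, .KEYPOINT_NAMES, c("x", "y", "z")))
  kp[, "sternum", ] <- matrix(0, n, 3L)
  kp[, "c7_proxy", ] <- matrix(model$c7_offset, n, 3L, byrow = TRUE)
  kp[, "shoulder", ] <- S
  kp[, "elbow", ] <- elbow
  kp[, "wrist", ] <- wrist
  kp[, "hand", ] <- hand
  qq <- array(NA_real_, c(n, 3L, 4L),
              dimnames = list(NULL, c("thorax", "humerus", "forearm"), NULL))
  qq[, "thorax", ] <- matrix(c(1, 0, 0, 0), n, 4L, byrow = TRUE)
  qq[, "humerus", ] <- q_hum
  qq[, "forearm", ] <- q_fore
  list(keypoints = kp, quats = qq)
}

#' Forward kinematics of the upper-limb model
#'
#' Maps joint coordinates to named keypoint positions and segment
#' orientations. Keypoints are `sternum`, `c7_proxy`, `shoulder`, `elbow`,
#' `wrist`, `hand`; segments are `thorax`, `humerus`, `forearm`.
#'
#' @param model a [limb_model()].
#' @param pose numeric length-5: plane of elevation, angle of elevation,
#'   shoulder rotation, elbow flexion, pronation (degrees). Must lie within
#'   the model's joint limits.
#' @return list with `keypoints` (6 x 3 matrix, mm) and `orientations`
#'   (named list of unit quaternions).
#' @export
forward_kinematics <- function(model, pose) {
  pose <- .check_pose(model, pose)
  fk <- .fk_batch(model, matrix(pose, 1L, 5L))
  kp <- matrix(fk$keypoints[1L, , ], 6L, 3L,
               dimnames = list(.KEYPOINT_NAMES, c("x", "y", "z")))
  orient <- lapply(c(thorax = "thorax", humerus = "humerus",
                     forearm = "forearm"),
                   function(s) quat_canonical(fk$quats[1L, s, ]))
  list(keypoints = kp, orientations = orient)
}

#' Shoulder angles from a thorax-to-humerus rotation matrix
#'
#' Decomposes by intrinsic Y-X-Y and converts to the right-arm reporting
#' convention in which elevation is positive (internally a negative X
#' rotation): the canonical decomposition of
#' `Ry(plane) Rx(-elev) Ry(rot)` is `(plane + 180, elev, rot + 180)`, so both
#' Y angles are shifted back by 180 and wrapped to `(-180, 180]`. At
#' gimbal-degenerate orientations (elevation 0 or 180) the outer angles are
#' not separable; there the decomposition's convention (rotation 0, plane
#' carrying the free Y rotation) is reported unshifted.
#'
#' @param R 3x3 rotation matrix (thorax to humerus).
#' @return length-3 numeric: plane of elevation, angle of elevation, shoulder
#'   rotation (degrees), with attribute `degenerate`.
#' @export
shoulder_angles_from_matrix <- function(R) {
  e <- euler_intrinsic(R, "YXY")
  sh <- .shoulder_rows(list(a1 = e[1L], a2 = e[2L], a3 = e[3L],
                            degenerate = attr(e, "degenerate")))
  out <- c(sh$plane, sh$elev, sh$rot)
  attr(out, "degenerate") <- sh$degenerate
  out
}

# convert raw Y-X-Y decomposition rows to the right-arm shoulder convention
.shoulder_rows <- function(sh) {
  wrap <- function(a) ((a + 180) %% 360) - 180
  deg <- sh$degenerate
  list(plane = ifelse(deg, wrap(sh$a1), wrap(sh$a1 - 180)),
       elev = sh$a2,
       rot = ifelse(deg, 0, wrap(sh$a3 - 180)),
       degenerate = deg)
}

#' Scale a model from recorded keypoint distances
#'
#' Sets the humerus length to the median over valid frames of the
#' shoulder-elbow distance and the forearm length to the median elbow-wrist
#' distance; remaining dimensions are scaled by the mean of the two length
#' ratios. A frame is valid when shoulder, elbow and wrist are all flagged
#' valid.
#'
#' @param template a [limb_model()] providing the reference proportions.
#' @param keypoints a [keypoint_series()] containing `shoulder`, `elbow` and
#'   `wrist`.
#' @return a scaled [limb_model()].
#' @export
scale_model_from_keypoints <- function(template, keypoints) {
  stopifnot(inherits(template, "limb_model"),
            inherits(keypoints, "keypoint_series"))
  need <- c("shoulder", "elbow", "wrist")
  if (!all(need %in% dimnames(keypoints$points)[[2L]]))
    stop("keypoints must contain shoulder, elbow and wrist", call. = FALSE)
  ok <- keypoints$valid[, "shoulder"] & keypoints$valid[, "elbow"] &
    keypoints$valid[, "wrist"]
  if (sum(ok) < 30L)
    stop("insufficient data: need at least 30 valid frames for scaling",
         call. = FALSE)
  S <- keypoints$points[ok, "shoulder", , drop = TRUE]
  E <- keypoints$points[ok, "elbow", , drop = TRUE]
  W <- keypoints$points[ok, "wrist", , drop = TRUE]
  hum <- median(sqrt(rowSums((E - S)^2)))
  fore <- median(sqrt(rowSums((W - E)^2)))
  r <- mean(c(hum / template$humerus_length, fore / template$forearm_length))
  limb_model(humerus_length = hum, forearm_length = fore,
             thorax_height = template$thorax_height * r,
             clavicle_offset = template$clavicle_offset * r,
             c7_offset = template$c7_offset * r,
             hand_offset = template$hand_offset * r,
             limits = template$limits)
}

#' Joint-axis independence diagnostic (dot-product test)
#'
#' Computes the world-frame unit vectors of the six rotation axes of the
#' intrinsic decomposition chain at a pose — shoulder plane (thorax Y),
#' shoulder elevation (rotated X), shoulder axial rotation (humerus Y), elbow
#' flexion (humerus Z), the fixed carrying-angle axis (rotated forearm X) and
#' forearm pronation (forearm Y) — and counts how many are pairwise
#' non-parallel. With the elbow extended the pronation axis is collinear with
#' the shoulder axial-rotation axis, leaving five independent axes; a
#' generically flexed elbow separates them. (At exactly 90 degrees of flexion
#' the fixed carrying-angle axis in turn rotates onto the axial-rotation
#' axis, so full separation requires a generic flexion angle.)
#'
#' @param model a [limb_model()].
#' @param pose length-5 pose (degrees), within limits.
#' @param tol parallelism tolerance: axes with `|dot| >= 1 - tol` against an
#'   earlier axis are counted as dependent.
#' @return list with `axes` (6 x 3 matrix of unit vectors), `pairs`
#'   (data frame of axis pairs and `|dot|`) and `n_independent`.
#' @export
axis_independence_test <- function(model, pose, tol = 1e-3) {
  pose <- .check_pose(model, pose)
  Rp <- rot_y(pose[[1L]])
  Rpe <- Rp %*% rot_x(-pose[[2L]])
  Rh <- Rpe %*% rot_y(pose[[3L]])
  Rhf <- Rh %*% rot_z(pose[[4L]])
  ax <- rbind(shoulder_plane = c(0, 1, 0),
              shoulder_elevation = as.numeric(Rp %*% c(1, 0, 0)),
              shoulder_axial = as.numeric(Rh %*% c(0, 1, 0)),
              elbow_flexion = as.numeric(Rh %*% c(0, 0, 1)),
              elbow_carrying = as.numeric(Rhf %*% c(1, 0, 0)),
              pronation = as.numeric(Rhf %*% c(0, 1, 0)))
  ax <- ax / sqrt(rowSums(ax^2))
  nm <- rownames(ax)
  pairs <- expand.grid(a = seq_len(6L), b = seq_len(6L))
  pairs <- pairs[pairs$a < pairs$b, ]
  pairs$abs_dot <- abs(rowSums(ax[pairs$a, , drop = FALSE] *
                                 ax[pairs$b, , drop = FALSE]))
  indep <- logical(6L)
  for (i in seq_len(6L)) {
    indep[i] <- TRUE
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (indep[j] && abs(sum(ax[i, ] * ax[j, ])) >= 1 - tol) {
        indep[i] <- FALSE
        break
      }
    }
  }
  list(axes = ax,
       pairs = data.frame(axis_a = nm[pairs$a], axis_b = nm[pairs$b],
                          abs_dot = pairs$abs_dot),
       n_independent = sum(indep))
}

#' Write / read a limb model as a plain-text config
#'
#' `key: value` lines; lengths in mm, limits in degrees.
#'
#' @param model a [limb_model()].
#' @param path file path.
#' @return `read_limb_model` returns a [limb_model()];
#'   `write_limb_model` returns `path` invisibly.
#' @export
write_limb_model <- function(model, path) {
  num <- function(x) paste(format(x, digits = 15, trim = TRUE),
                           collapse = " ")
  lines <- c(paste0("humerus_length: ", num(model$humerus_length)),
             paste0("forearm_length: ", num(model$forearm_length)),
             paste0("thorax_height: ", num(model$thorax_height)),
             paste0("clavicle_offset: ", num(model$clavicle_offset)),
             paste0("c7_offset: ", num(model$c7_offset)),
             paste0("hand_offset: ", num(model$hand_offset)),
             vapply(names(model$limits), function(nm)
               paste0("limit_", nm, ": ", num(model$limits[[nm]])),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_limb_model
#' @export
read_limb_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- lapply(kv, function(p)
    as.numeric(strsplit(trimws(paste(p[-1L], collapse = ":")), "\\s+")[[1L]]))
  names(vals) <- keys
  lim <- vals[grepl("^limit_", keys)]
  names(lim) <- sub("^limit_", "", names(lim))
  limb_model(humerus_length = vals$humerus_length,
             forearm_length = vals$forearm_length,
             thorax_height = vals$thorax_height,
             clavicle_offset = vals$clavicle_offset,
             c7_offset = vals$c7_offset,
             hand_offset = vals$hand_offset,
             limits = lim)
}
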