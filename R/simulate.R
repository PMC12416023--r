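# Simulation of the two measurement systems.
#
# The reference channel emulates a high-rate marker-based system: 120 Hz,
# sub-millimetre keypoint noise, no latency, no frame-convention offsets.
# The markerless channel emulates a single depth-camera body tracker: 30 Hz,
# centimetre-scale keypoint noise inflated along the camera depth axis,
# orientation noise, a constant inter-system latency, fixed device-convention
# rotations of the segment frames, and occasional keypoint misdetections
# (flagged invalid and grossly displaced).

# run expr with a local RNG seed, restoring global state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Measurement-noise specification
#'
#' @param keypoint_sd isotropic keypoint noise SD, mm.
#' @param orientation_sd orientation noise SD, degrees (applied as small
#'   rotations about uniformly random axes, then renormalized).
#' @param latency constant inter-system latency, seconds: a sample
#'   timestamped `t` carries the pose at `t - latency`.
#' @param misdetection_prob per-frame, per-keypoint probability of
#'   misdetection.
#' @param misdetection_sd displacement SD (mm) applied to misdetected
#'   keypoints, which are flagged invalid.
#' @param frame_offsets named list of unit quaternions (thorax, humerus,
#'   forearm): constant device-convention rotation of each segment frame,
#'   applied in the segment's own frame. `default_frame_offsets()` gives the
#'   default; use `NULL` for identity.
#' @param depth_axis_mult multiplier on keypoint noise along the camera depth
#'   axis (anterior X for a frontal placement, lateral Z for sagittal).
#' @param seed integer RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(keypoint_sd = 10, orientation_sd = 3, latency = 0.15,
                       misdetection_prob = 0.02, misdetection_sd = 150,
                       frame_offsets = default_frame_offsets(),
                       depth_axis_mult = 2, seed = 1L) {
  if (keypoint_sd < 0 || orientation_sd < 0 || misdetection_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (misdetection_prob < 0 || misdetection_prob > 1)
    stop("misdetection_prob must be in [0, 1]", call. = FALSE)
  if (is.null(frame_offsets))
    frame_offsets <- list(thorax = c(1, 0, 0, 0), humerus = c(1, 0, 0, 0),
                          forearm = c(1, 0, 0, 0))
  structure(list(keypoint_sd = keypoint_sd, orientation_sd = orientation_sd,
                 latency = latency, misdetection_prob = misdetection_prob,
                 misdetection_sd = misdetection_sd,
                 frame_offsets = lapply(frame_offsets, quat_normalize),
                 depth_axis_mult = depth_axis_mult,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Noise specification for the marker-based reference channel
#'
#' Sub-millimetre noise, no latency, no offsets, no misdetection.
#'
#' @param keypoint_sd keypoint noise SD, mm.
#' @param seed integer RNG seed.
#' @return a [noise_spec()].
#' @export
reference_noise_spec <- function(keypoint_sd = 0.5, seed = 1L) {
  noise_spec(keypoint_sd = keypoint_sd, orientation_sd = 0, latency = 0,
             misdetection_prob = 0, misdetection_sd = 0,
             frame_offsets = NULL, depth_axis_mult = 1, seed = seed)
}

#' Default device-convention segment frame offsets
#'
#' Constant rotations a body-tracking device applies to its segment frames
#' relative to the ISB definitions. The coordinate-frame method undoes them
#' with matching realignment rotations.
#'
#' @return named list of unit quaternions.
#' @export
default_frame_offsets <- function() {
  list(thorax = quat_from_axis_angle(c(1, 0, 0), 90),
       humerus = quat_from_axis_angle(c(0, 1, 0), 90),
       forearm = quat_from_axis_angle(c(0, 0, 1), 90))
}

#' Realignment rotations that undo a set of frame offsets
#'
#' @param frame_offsets named list of unit quaternions (as in
#'   [noise_spec()]).
#' @return named list of conjugate quaternions, suitable for
#'   [cf_joint_angles()].
#' @export
realignment_from_offsets <- function(frame_offsets) {
  lapply(frame_offsets, quat_conjugate)
}

# scale the stochastic components of a noise spec (latency and frame offsets
# are systematics and are kept)
.scale_noise <- function(noise, scale) {
  noise$keypoint_sd <- noise$keypoint_sd * scale
  noise$orientation_sd <- noise$orientation_sd * scale
  noise$misdetection_sd <- noise$misdetection_sd * scale
  noise$misdetection_prob <- noise$misdetection_prob * min(1, scale)
  noise
}

# ground-truth table from script poses
.truth_table <- function(time, poses, rate, movement, participant) {
  joint_angle_table(
    time,
    list(plane_of_elevation = poses[, 1L], angle_of_elevation = poses[, 2L],
         shoulder_rotation = poses[, 3L], elbow_flexion = poses[, 4L],
         pronation = poses[, 5L]),
    rate = rate, method = "truth", movement = movement,
    participant = participant)
}

# core simulator shared by both channels
.simulate_channel <- function(script, model, rate, noise, placement) {
  time <- seq(0, script$duration, by = 1 / rate)
  poses <- script$fun(time - noise$latency)
  fk <- .fk_batch(model, poses)
  kp <- fk$keypoints
  qq <- fk$quats
  n <- length(time)
  nk <- dim(kp)[2L]
  valid <- matrix(TRUE, n, nk)

  .with_seed(noise$seed, {
    if (noise$keypoint_sd > 0) {
      sds <- rep(noise$keypoint_sd, 3L)
      depth_axis <- if (identical(placement, "sagittal")) 3L else 1L
      sds[depth_axis] <- sds[depth_axis] * noise$depth_axis_mult
      for (a in 1:3)
        kp[, , a] <- kp[, , a] + matrix(rnorm(n * nk, 0, sds[a]), n, nk)
    }
    if (noise$misdetection_prob > 0) {
      miss <- matrix(runif(n * nk) < noise$misdetection_prob, n, nk)
      if (any(miss)) {
        valid[miss] <- FALSE
        for (a in 1:3)
          kp[, , a][miss] <- kp[, , a][miss] +
            rnorm(sum(miss), 0, noise$misdetection_sd)
      }
    }
    if (noise$orientation_sd > 0) {
      for (s in seq_len(dim(qq)[2L])) {
        ax <- matrix(rnorm(3L * n), n, 3L)
        ax <- ax / sqrt(rowSums(ax^2))
        ang <- rnorm(n, 0, noise$orientation_sd) * .DEG / 2
        qn <- cbind(cos(ang), sin(ang) * ax)
        qq[, s, ] <- .quat_rows_normalize(
          .quat_rows_multiply(qn, qq[, s, , drop = TRUE]))
      }
    }
  })
  # device-convention offsets rotate each segment frame in its own frame
  segs <- dimnames(qq)[[2L]]
  for (s in seq_along(segs)) {
    off <- noise$frame_offsets[[segs[s]]]
    if (!is.null(off) && quat_angle(quat_canonical(off), c(1, 0, 0, 0)) > 0)
      qq[, s, ] <- .quat_rows_multiply(qq[, s, , drop = TRUE], off)
  }
  list(time = time, poses = poses, keypoints = kp, quats = qq, valid = valid)
}

#' Simulate the marker-based reference channel
#'
#' Samples the movement script at the reference rate, applies the (low)
#' reference noise, and returns the measured keypoints and orientations along
#' with the ground-truth joint-angle table.
#'
#' @param script a [generate_movement()] script.
#' @param model a [limb_model()].
#' @param rate sampling rate, Hz (default 120).
#' @param noise a [noise_spec()]; defaults to [reference_noise_spec()].
#' @param participant participant id carried as metadata.
#' @return list with `keypoints` ([keypoint_series()]), `orientations`
#'   ([orientation_series()]) and `truth` ([joint_angle_table()]).
#' @export
simulate_reference <- function(script, model, rate = 120,
                               noise = reference_noise_spec(),
                               participant = NA_character_) {
  stopifnot(inherits(script, "movement_script"), inherits(model, "limb_model"))
  ch <- .simulate_channel(script, model, rate, noise, placement = "none")
  list(keypoints = keypoint_series(ch$time, ch$keypoints, rate,
                                   valid = ch$valid),
       orientations = orientation_series(ch$time, ch$quats, rate),
       truth = .truth_table(ch$time, ch$poses, rate, script$name,
                            participant))
}

#' Simulate the single-camera markerless channel
#'
#' Samples the script at the markerless rate with the full markerless error
#' structure: latency (timestamps lead the carried pose by `latency`
#' seconds), depth-weighted keypoint noise, orientation noise,
#' device-convention frame offsets and misdetections.
#'
#' @param script a [generate_movement()] script.
#' @param model a [limb_model()].
#' @param rate sampling rate, Hz (default 30).
#' @param noise a [noise_spec()].
#' @param placement `"frontal"` or `"sagittal"`; selects the camera depth
#'   axis for noise inflation.
#' @return list with `keypoints` ([keypoint_series()]) and `orientations`
#'   ([orientation_series()]).
#' @export
simulate_markerless <- function(script, model, rate = 30,
                                noise = noise_spec(),
                                placement = script$placement) {
  stopifnot(inherits(script, "movement_script"), inherits(model, "limb_model"))
  if (!placement %in% c("frontal", "sagittal"))
    stop("placement must be 'frontal' or 'sagittal'", call. = FALSE)
  ch <- .simulate_channel(script, model, rate, noise, placement)
  list(keypoints = keypoint_series(ch$time, ch$keypoints, rate,
                                   valid = ch$valid),
       orientations = orientation_series(ch$time, ch$quats, rate))
}
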