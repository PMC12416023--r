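# Scripted ground-truth movements.
#
# Ten tasks: five physiological (planar) movements that isolate single joint
# angles, and five functional activities of daily living defined as smooth
# periodic splines through documented waypoints. All trajectories are
# periodic over one cycle (default 4 s, a slow deliberate pace) and repeat
# `repetitions` times; every script starts and ends at its stated start
# posture. The resting posture keeps the shoulder at 5 degrees of elevation
# (arm hanging slightly off the torso) and the elbow at 5 degrees of flexion
# (a relaxed arm is never fully locked out), so the ground truth stays off
# the Y-X-Y gimbal band and at least 1 degree inside every joint limit -- the
# preconditions under which noise-free angle recovery is guaranteed.

.PLANAR_MOVEMENTS <- c("shoulder_abduction", "shoulder_flexion",
                       "elbow_flexion", "shoulder_rotation",
                       "pronation_supination")
.ADL_MOVEMENTS <- c("brush_hair", "perineal_care", "collect_change",
                    "drink_from_cup", "eat_with_spoon")

.REST_ELEV <- 5   # deg, resting shoulder elevation
.REST_ELBOW <- 5  # deg, resting elbow flexion

#' Names of the ten scripted movements
#' @return character vector (five planar tasks, then five ADL tasks).
#' @export
movement_names <- function() c(.PLANAR_MOVEMENTS, .ADL_MOVEMENTS)

#' Task-type of a movement
#' @param name movement name(s).
#' @return `"planar"` or `"adl"` per element.
#' @export
movement_task_type <- function(name) {
  ifelse(name %in% .PLANAR_MOVEMENTS, "planar",
         ifelse(name %in% .ADL_MOVEMENTS, "adl", NA_character_))
}

# C1 bump: 0 outside [t0, t0+w], peak * sin^2 at centre
.bump <- function(u, t0, w, peak) {
  inside <- u >= t0 & u <= t0 + w
  out <- numeric(length(u))
  out[inside] <- peak * sin(pi * (u[inside] - t0) / w)^2
  out
}

# default peak amplitudes (deg) for the planar tasks
.default_peaks <- function() {
  list(shoulder_abduction = 150, shoulder_flexion = 150,
       shoulder_flexion_back = 40, elbow_flexion = 130,
       shoulder_rotation = 60, pronation_supination = 80)
}

# ADL waypoints: fraction of cycle x (plane, elev, rot, elbow, pronation)
.adl_waypoints <- function() {
  base <- c(0, .REST_ELEV, 0, .REST_ELBOW, 0)
  list(
    brush_hair = rbind(
      c(0.00, base), c(0.15, 60, 50, -10, 40, 0), c(0.30, 85, 95, -30, 70, 0),
      c(0.45, 90, 110, -40, 95, 0), c(0.55, 85, 100, -20, 80, 0),
      c(0.70, 60, 50, -10, 40, 0), c(1.00, base)),
    perineal_care = rbind(
      c(0.00, base), c(0.25, -40, 25, -20, 25, 0),
      c(0.50, -70, 35, -45, 45, 0), c(0.75, -40, 25, -20, 25, 0),
      c(1.00, base)),
    collect_change = rbind(
      c(0.00, base), c(0.20, 75, 55, -10, 30, 0), c(0.40, 80, 60, -20, 45, 0),
      c(0.60, 30, 25, -30, 80, 0), c(0.80, 10, 10, -10, 30, 0),
      c(1.00, base)),
    drink_from_cup = rbind(
      c(0.00, base), c(0.20, 80, 60, -10, 45, 0), c(0.40, 75, 45, -20, 110, 0),
      c(0.50, 75, 40, -25, 125, 0), c(0.60, 75, 45, -20, 110, 0),
      c(0.80, 80, 60, -10, 45, 0), c(1.00, base)),
    eat_with_spoon = rbind(
      c(0.00, base), c(0.15, 80, 55, -10, 40, 0), c(0.30, 75, 40, -20, 120, 0),
      c(0.45, 78, 50, -15, 70, 0), c(0.60, 75, 40, -20, 120, 0),
      c(0.80, 80, 55, -10, 40, 0), c(1.00, base)))
}

# builds function(u in [0, cycle)) -> n x 5 pose matrix for one cycle
.movement_cycle_fun <- function(name, cycle, peaks) {
  rest <- .REST_ELEV
  if (name %in% .ADL_MOVEMENTS) {
    wp <- .adl_waypoints()[[name]]
    tt <- wp[, 1L] * cycle
    fns <- lapply(2:6, function(col)
      splinefun(tt, wp[, col], method = "periodic"))
    return(function(u) {
      cbind(fns[[1L]](u), pmax(1.5, fns[[2L]](u)), fns[[3L]](u),
            pmax(1.5, fns[[4L]](u)), fns[[5L]](u), deparse.level = 0)
    })
  }
  switch(
    name,
    shoulder_abduction = function(u) {
      elev <- rest + .bump(u, 0.05 * cycle, 0.9 * cycle,
                           peaks$shoulder_abduction - rest)
      cbind(0 * u, elev, 0 * u, .REST_ELBOW + 0 * u, 0 * u,
            deparse.level = 0)
    },
    shoulder_flexion = function(u) {
      # forward raise at plane +90, then a smaller raise behind the torso
      # (plane -90); the plane transitions while the arm is near rest
      plane <- .bump(u, 0.000 * cycle, 0.50 * cycle, 90) -
        .bump(u, 0.505 * cycle, 0.49 * cycle, 90)
      elev <- rest +
        .bump(u, 0.075 * cycle, 0.35 * cycle, peaks$shoulder_flexion - rest) +
        .bump(u, 0.575 * cycle, 0.35 * cycle,
              peaks$shoulder_flexion_back - rest)
      cbind(plane, elev, 0 * u, .REST_ELBOW + 0 * u, 0 * u,
            deparse.level = 0)
    },
    elbow_flexion = function(u) {
      flex <- .REST_ELBOW + .bump(u, 0.05 * cycle, 0.9 * cycle,
                                  peaks$elbow_flexion - .REST_ELBOW)
      cbind(0 * u, rest + 0 * u, 0 * u, flex, 0 * u, deparse.level = 0)
    },
    shoulder_rotation = function(u) {
      rot <- .bump(u, 0.025 * cycle, 0.45 * cycle, peaks$shoulder_rotation) -
        .bump(u, 0.525 * cycle, 0.45 * cycle, peaks$shoulder_rotation)
      cbind(0 * u, rest + 0 * u, rot, 90 + 0 * u, 0 * u, deparse.level = 0)
    },
    pronation_supination = function(u) {
      pro <- .bump(u, 0.025 * cycle, 0.45 * cycle,
                   peaks$pronation_supination) -
        .bump(u, 0.525 * cycle, 0.45 * cycle, peaks$pronation_supination)
      cbind(0 * u, rest + 0 * u, 0 * u, 90 + 0 * u, pro, deparse.level = 0)
    },
    stop("unknown movement: ", name, call. = FALSE))
}

#' Generate a scripted movement
#'
#' @param name one of [movement_names()].
#' @param cycle_duration duration of one repetition, seconds (default 4 s, a
#'   slow pace).
#' @param repetitions number of congruent repetitions (default 3).
#' @param peaks optional named list overriding default peak amplitudes
#'   (degrees) for the planar tasks (`shoulder_abduction`,
#'   `shoulder_flexion`, `shoulder_flexion_back`, `elbow_flexion`,
#'   `shoulder_rotation`, `pronation_supination`).
#' @param placement camera placement label carried as metadata
#'   (`"frontal"` or `"sagittal"`).
#' @return object of class `movement_script`: list with `name`, `duration`
#'   (s), `repetitions`, `cycle_duration`, `placement`, `task_type` and
#'   `fun(t)`, which maps a vector of times (s) to an `n x 5` matrix of joint
#'   coordinates (degrees), periodic over the cycle.
#' @export
generate_movement <- function(name, cycle_duration = 4, repetitions = 3,
                              peaks = NULL, placement = "frontal") {
  if (!name %in% movement_names())
    stop("unknown movement: ", name, call. = FALSE)
  if (repetitions < 1L) stop("repetitions must be >= 1", call. = FALSE)
  pk <- modifyList(.default_peaks(), if (is.null(peaks)) list() else peaks)
  cyc <- .movement_cycle_fun(name, cycle_duration, pk)
  fun <- function(t) {
    u <- t %% cycle_duration
    poses <- cyc(u)
    colnames(poses) <- .POSE_NAMES
    poses
  }
  script <- structure(
    list(name = name, duration = cycle_duration * repetitions,
         repetitions = as.integer(repetitions),
         cycle_duration = cycle_duration, placement = placement,
         task_type = movement_task_type(name), fun = fun),
    class = "movement_script")
  .validate_script(script)
  script
}

# trajectories must respect the default joint limits on a dense grid
.validate_script <- function(script) {
  lim <- default_joint_limits()
  u <- seq(0, script$cycle_duration, length.out = 401L)
  poses <- script$fun(u)
  for (i in seq_along(.POSE_NAMES)) {
    l <- lim[[.POSE_NAMES[i]]]
    if (any(poses[, i] < l[1L] - 1e-6) || any(poses[, i] > l[2L] + 1e-6))
      stop("movement script violates joint limits on ", .POSE_NAMES[i],
           call. = FALSE)
  }
  invisible(script)
}

#' @export
print.movement_script <- function(x, ...) {
  cat(sprintf("movement_script '%s' (%s): %d x %.1f s, placement %s\n",
              x$name, x$task_type, x$repetitions, x$cycle_duration,
              x$placement))
  invisible(x)
}
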