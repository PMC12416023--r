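# End-to-end experiment orchestration:
# simulate -> compute angles -> sync -> difference -> agreement -> report.

#' Experiment configuration
#'
#' Defaults mirror the study protocol: 12 participants with anthropometric
#' scales drawn from 0.8-1.2, the 10 scripted movements, 2 camera placements,
#' 3 repetitions per recording, a 120 Hz reference channel and a 30 Hz
#' markerless channel, CF and IK methods, 5 Hz/30 Hz and 8 Hz/120 Hz
#' zero-phase Butterworth filters.
#'
#' @param participants number of participants.
#' @param scale_range range of anthropometric scale factors.
#' @param movements movement names (subset of [movement_names()]).
#' @param placements camera placements.
#' @param repetitions repetitions per recording.
#' @param cycle_duration seconds per repetition.
#' @param ref_rate,mkl_rate sampling rates, Hz.
#' @param noise named list of [noise_spec()] per placement (a single spec is
#'   replicated).
#' @param ref_noise reference-channel [noise_spec()].
#' @param ik an [ik_settings()] for the markerless channel.
#' @param ref_ik an [ik_settings()] for the reference channel (defaults to
#'   [reference_ik_settings()]: full marker set, pronation free).
#' @param cf_alpha CF SLERP-smoothing weight.
#' @param mkl_cutoff,ref_cutoff filter cutoffs, Hz.
#' @param methods methods to evaluate (`"CF"`, `"IK"`).
#' @param noise_scale multiplier on all stochastic noise components (latency
#'   and frame offsets are systematics and are kept).
#' @param seed master seed; per-trial seeds are derived deterministically
#'   from it and the trial indices.
#' @param max_lag sync search half-window, seconds.
#' @param out_dir optional output directory for the report bundle.
#' @param verbose print per-trial progress.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(participants = 12L,
                              scale_range = c(0.8, 1.2),
                              movements = movement_names(),
                              placements = c("frontal", "sagittal"),
                              repetitions = 3L, cycle_duration = 4,
                              ref_rate = 120, mkl_rate = 30,
                              noise = noise_spec(),
                              ref_noise = reference_noise_spec(),
                              ik = ik_settings(), ref_ik = reference_ik_settings(),
                              cf_alpha = 0.5,
                              mkl_cutoff = 5, ref_cutoff = 8,
                              methods = c("CF", "IK"), noise_scale = 1,
                              seed = 1L, max_lag = 2, out_dir = NULL,
                              verbose = FALSE) {
  if (!all(movements %in% movement_names()))
    stop("unknown movements: ",
         paste(setdiff(movements, movement_names()), collapse = ", "),
         call. = FALSE)
  if (participants < 2L) stop("need at least 2 participants", call. = FALSE)
  if (ref_rate <= 0 || mkl_rate <= 0) stop("rates must be positive",
                                           call. = FALSE)
  if (!all(methods %in% c("CF", "IK")))
    stop("methods must be a subset of CF, IK", call. = FALSE)
  if (is.null(seed)) stop("a master seed must be set", call. = FALSE)
  if (inherits(noise, "noise_spec"))
    noise <- setNames(rep(list(noise), length(placements)), placements)
  if (!all(placements %in% names(noise)))
    stop("noise must be specified for every placement", call. = FALSE)
  structure(list(participants = as.integer(participants),
                 scale_range = scale_range, movements = movements,
                 placements = placements,
                 repetitions = as.integer(repetitions),
                 cycle_duration = cycle_duration, ref_rate = ref_rate,
                 mkl_rate = mkl_rate, noise = noise, ref_noise = ref_noise,
                 ik = ik, ref_ik = ref_ik, cf_alpha = cf_alpha,
                 mkl_cutoff = mkl_cutoff,
                 ref_cutoff = ref_cutoff, methods = methods,
                 noise_scale = noise_scale, seed = as.integer(seed),
                 max_lag = max_lag, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "experiment_config")
}

#' Deterministic per-trial seed derivation
#'
#' Combines the master seed with participant, movement and placement indices
#' through a fixed integer hash so trials are reproducible and mutually
#' independent.
#'
#' @param master master seed (integer).
#' @param participant,movement,placement 1-based indices.
#' @return integer seed in `[1, 2^31 - 1)`.
#' @export
derive_trial_seed <- function(master, participant, movement, placement) {
  m <- 2147483629
  s <- (as.numeric(master) %% m +
          7919 * participant + 104729 * movement + 15485863 * placement) %% m
  as.integer(s + 1)
}

.log <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
  invisible(NULL)
}

#' Run the full simulated validation experiment
#'
#' For every participant x placement x movement: simulates the reference and
#' markerless channels, scales the limb model from each channel's keypoints,
#' computes reference angles (IK on the reference keypoints at 120 Hz) and
#' markerless angles by each method, time-synchronises by cross-correlation,
#' and pools the per-frame angle differences per participant. The pooled
#' difference sets (placements x movements x angle sets per method) are then
#' summarised by repeated-measures Bland-Altman statistics, and the four
#' comparison ANOVAs (method within placement, placement within method) are
#' computed on the per-set RMSE values.
#'
#' @param config an [experiment_config()].
#' @return object of class `uplimb_experiment`: list with
#'   `difference_sets` (list per method of [difference_set()]s),
#'   `agreement` (data frame, one row per difference set), `comparisons`
#'   (`methods_by_placement`, `placements_by_method` ANOVA lists), `summary`
#'   (aggregated [report_table()]), `excluded` (failed-trial count) and
#'   `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  scales <- .with_seed(config$seed,
                       runif(config$participants, config$scale_range[1L],
                             config$scale_range[2L]))
  template <- default_model(1)
  acc <- list()   # key -> participant -> list of diff vectors
  excluded <- 0L
  sync_fallbacks <- 0L
  for (pi in seq_len(config$participants)) {
    pid <- sprintf("P%02d", pi)
    model_true <- default_model(scales[pi])
    for (pli in seq_along(config$placements)) {
      pl <- config$placements[pli]
      for (mi in seq_along(config$movements)) {
        mv <- config$movements[mi]
        seedt <- derive_trial_seed(config$seed, pi, mi, pli)
        res <- tryCatch(
          .run_trial(config, template, model_true, pid, pl, mv, seedt),
          error = function(e) e)
        if (inherits(res, "error")) {
          excluded <- excluded + 1L
          .log(config, "trial excluded (%s %s %s): %s", pid, pl, mv,
               conditionMessage(res))
          next
        }
        sync_fallbacks <- sync_fallbacks + res$sync_fallbacks
        for (me in names(res$diffs)) {
          for (ch in angle_channels()) {
            key <- paste(me, pl, mv, ch, sep = "|")
            if (is.null(acc[[key]])) acc[[key]] <- list()
            acc[[key]][[pid]] <- c(acc[[key]][[pid]], res$diffs[[me]][[ch]])
          }
        }
        .log(config, "trial done: %s %s %s", pid, pl, mv)
      }
    }
  }
  diffsets <- list()
  rows <- list()
  for (key in names(acc)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    keep <- acc[[key]][lengths(acc[[key]]) >= 2L]
    if (length(keep) < 2L) next
    ds <- difference_set(keep, method = parts[1L], placement = parts[2L],
                         movement = parts[3L], angle_set = parts[4L])
    diffsets[[parts[1L]]][[paste(parts[-1L], collapse = "|")]] <- ds
    ba <- bland_altman(ds)
    rows[[key]] <- data.frame(
      method = parts[1L], placement = parts[2L], movement = parts[3L],
      angle_set = parts[4L], task_type = movement_task_type(parts[3L]),
      bias = ba$bias, SD = ba$SD, loa_lower = ba$loa_lower,
      loa_upper = ba$loa_upper, RMSE = ba$RMSE,
      n_participants = ba$n_participants, n_obs = ba$n_obs,
      stringsAsFactors = FALSE)
  }
  agreement <- do.call(rbind, rows)
  rownames(agreement) <- NULL
  comparisons <- list(methods_by_placement = compare_methods(agreement),
                      placements_by_method = compare_planes(agreement))
  summary_tab <- report_table(agreement)
  out <- structure(list(difference_sets = diffsets, agreement = agreement,
                        comparisons = comparisons, summary = summary_tab,
                        excluded = excluded,
                        sync_fallbacks = sync_fallbacks, config = config),
                   class = "uplimb_experiment")
  if (!is.null(config$out_dir)) write_report_bundle(out, config$out_dir)
  out
}

# one participant x placement x movement recording, both methods
.run_trial <- function(config, template, model_true, pid, pl, mv, seedt) {
  script <- generate_movement(mv, cycle_duration = config$cycle_duration,
                              repetitions = config$repetitions,
                              placement = pl)
  ref_noise <- .scale_noise(config$ref_noise, config$noise_scale)
  ref_noise$seed <- seedt
  mkl_noise <- .scale_noise(config$noise[[pl]], config$noise_scale)
  mkl_noise$seed <- seedt + 1L
  ref <- simulate_reference(script, model_true, config$ref_rate, ref_noise,
                            participant = pid)
  mkl <- simulate_markerless(script, model_true, config$mkl_rate, mkl_noise,
                             placement = pl)
  ref_model <- scale_model_from_keypoints(template, ref$keypoints)
  ref_angles <- compute_reference_angles(
    ref$keypoints, ref_model, config$ref_ik,
    filter = filter_spec(4L, config$ref_cutoff, config$ref_rate),
    movement = mv, placement = pl, participant = pid)
  diffs <- list()
  fallbacks <- 0L
  for (me in config$methods) {
    tab <- if (me == "CF") {
      cf_joint_angles(mkl$orientations,
                      realignment =
                        realignment_from_offsets(mkl_noise$frame_offsets),
                      alpha = config$cf_alpha, out_rate = config$ref_rate,
                      movement = mv, placement = pl, participant = pid)
    } else {
      mkl_model <- scale_model_from_keypoints(template, mkl$keypoints)
      ik_joint_angles(mkl$keypoints, mkl_model, config$ik,
                      filter = filter_spec(4L, config$mkl_cutoff,
                                           config$mkl_rate),
                      out_rate = config$ref_rate, movement = mv,
                      placement = pl, participant = pid)
    }
    al <- withCallingHandlers(
      align_angle_tables(tab, ref_angles, max_lag = config$max_lag),
      warning = function(w) {
        if (grepl("near-constant", conditionMessage(w))) {
          fallbacks <<- fallbacks + 1L
          invokeRestart("muffleWarning")
        }
      })
    diffs[[me]] <- build_difference_sets(al$test, al$reference)
  }
  list(diffs = diffs, sync_fallbacks = fallbacks)
}

#' Aggregated agreement summary table
#'
#' Averages bias, SD, LoA bounds and RMSE over difference sets, by placement,
#' angle type and task type (All / Planar / ADL), per method — the standard
#' reporting layout for this analysis. An `"average"` angle-type row pools
#' all four angle sets.
#'
#' @param agreement data frame of per-set agreement statistics (from
#'   [run_experiment()]).
#' @return data frame with columns `placement`, `angle_type`, `task_type`,
#'   `method`, `bias`, `SD`, `loa_lower`, `loa_upper`, `RMSE`, `n_sets`.
#'   Cells with no difference sets are reported as `NA` with a warning.
#' @export
report_table <- function(agreement) {
  need <- c("method", "placement", "movement", "angle_set", "bias", "SD",
            "loa_lower", "loa_upper", "RMSE")
  if (!is.data.frame(agreement) || !all(need %in% names(agreement)))
    stop("agreement must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ag <- agreement
  if (!"task_type" %in% names(ag))
    ag$task_type <- movement_task_type(ag$movement)
  rows <- list()
  cell_mean <- function(sub, placement, angle_type, task_type, method) {
    if (nrow(sub) == 0L) {
      warning(sprintf("no difference sets for %s/%s/%s/%s",
                      placement, angle_type, task_type, method),
              call. = FALSE)
      return(data.frame(placement = placement, angle_type = angle_type,
                        task_type = task_type, method = method,
                        bias = NA_real_, SD = NA_real_,
                        loa_lower = NA_real_, loa_upper = NA_real_,
                        RMSE = NA_real_, n_sets = 0L))
    }
    data.frame(placement = placement, angle_type = angle_type,
               task_type = task_type, method = method,
               bias = mean(sub$bias), SD = mean(sub$SD),
               loa_lower = mean(sub$loa_lower),
               loa_upper = mean(sub$loa_upper), RMSE = mean(sub$RMSE),
               n_sets = nrow(sub))
  }
  for (pl in unique(ag$placement)) {
    for (me in unique(ag$method)) {
      base <- ag[ag$placement == pl & ag$method == me, ]
      rows[[length(rows) + 1L]] <- cell_mean(base, pl, "average", "all", me)
      for (an in unique(ag$angle_set)) {
        sub <- base[base$angle_set == an, ]
        rows[[length(rows) + 1L]] <- cell_mean(sub, pl, an, "all", me)
        for (tt in c("planar", "adl")) {
          rows[[length(rows) + 1L]] <-
            cell_mean(sub[sub$task_type == tt, ], pl, an, tt, me)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the report bundle of an experiment
#'
#' Writes `diffsets.csv` (per-set, per-participant summaries),
#' `agreement.csv` (one row per difference set), `comparisons.json` (the
#' four comparison ANOVAs) and `summary.csv` (the aggregated table).
#'
#' @param experiment a `uplimb_experiment` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(experiment, dir) {
  stopifnot(inherits(experiment, "uplimb_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drows <- list()
  for (me in names(experiment$difference_sets)) {
    for (ds in experiment$difference_sets[[me]]) {
      for (p in names(ds$diffs)) {
        d <- ds$diffs[[p]]
        drows[[length(drows) + 1L]] <- data.frame(
          method = ds$method, placement = ds$placement,
          movement = ds$movement, angle_set = ds$angle_set, participant = p,
          n_obs = length(d), mean_diff = mean(d), sd_diff = sd(d))
      }
    }
  }
  wcsv <- function(x, f) write.table(
    x, file.path(dir, f), sep = ",", row.names = FALSE, quote = FALSE)
  wcsv(do.call(rbind, drows), "diffsets.csv")
  wcsv(experiment$agreement, "agreement.csv")
  wcsv(experiment$summary, "summary.csv")
  an2l <- function(a) a[c("F", "p", "eta2p", "cohens_f", "df_between",
                          "df_within", "alpha")]
  jsonlite::write_json(
    list(methods_by_placement =
           lapply(experiment$comparisons$methods_by_placement, an2l),
         placements_by_method =
           lapply(experiment$comparisons$placements_by_method, an2l),
         excluded_trials = experiment$excluded),
    file.path(dir, "comparisons.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.uplimb_experiment <- function(x, ...) {
  cat(sprintf("uplimb_experiment: %d methods, %d difference sets each\n",
              length(x$difference_sets),
              length(x$difference_sets[[1L]])))
  cat(sprintf("  participants: %d, movements: %d, placements: %s\n",
              x$config$participants, length(x$config$movements),
              paste(x$config$placements, collapse = "/")))
  cat(sprintf("  excluded trials: %d\n", x$excluded))
  for (me in names(x$difference_sets)) {
    sub <- x$agreement[x$agreement$method == me, ]
    cat(sprintf("  %s: mean RMSE %.2f deg, mean |bias| %.2f deg\n", me,
                mean(sub$RMSE), mean(abs(sub$bias))))
  }
  invisible(x)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `read_experiment_config` returns an [experiment_config()];
#'   `write_experiment_config` returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  ns2l <- function(ns) {
    u <- unclass(ns)
    u$frame_offsets <- lapply(u$frame_offsets, as.numeric)
    u
  }
  lst <- unclass(config)
  lst$noise <- lapply(lst$noise, ns2l)
  lst$ref_noise <- ns2l(lst$ref_noise)
  lst$ik <- unclass(lst$ik)
  lst$ik$weights <- as.list(lst$ik$weights)
  lst$ref_ik <- unclass(lst$ref_ik)
  lst$ref_ik$weights <- as.list(lst$ref_ik$weights)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  l2ns <- function(l) do.call(noise_spec, l)
  noise <- lapply(lst$noise, l2ns)
  ik <- lst$ik
  ik$weights <- unlist(ik$weights)
  lst$ref_ik$weights <- unlist(lst$ref_ik$weights)
  experiment_config(
    participants = lst$participants,
    scale_range = as.numeric(lst$scale_range),
    movements = unlist(lst$movements),
    placements = unlist(lst$placements),
    repetitions = lst$repetitions, cycle_duration = lst$cycle_duration,
    ref_rate = lst$ref_rate, mkl_rate = lst$mkl_rate, noise = noise,
    ref_noise = l2ns(lst$ref_noise), ik = do.call(ik_settings, ik),
    ref_ik = do.call(ik_settings, lst$ref_ik),
    cf_alpha = lst$cf_alpha, mkl_cutoff = lst$mkl_cutoff,
    ref_cutoff = lst$ref_cutoff, methods = unlist(lst$methods),
    noise_scale = lst$noise_scale, seed = lst$seed, max_lag = lst$max_lag,
    out_dir = lst$out_dir, verbose = lst$verbose)
}
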