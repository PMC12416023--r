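# Repeated-measures Bland-Altman agreement, RMSE, and comparison ANOVAs.
#
# For each difference set (one method x placement x movement x angle set),
# a one-way ANOVA with participant as the factor partitions the variance of
# the angle differences into between-participant and within-participant
# (residual) components:
#   MS_participant = SS_between / (k - 1),  MS_residual = SS_within / (N - k)
#   var_between = max(0, (MS_participant - MS_residual) / n_bar)
#   var_total = var_between + MS_residual,  SD = sqrt(var_total)
# with n_bar the average number of observations per participant. The bias is
# the grand mean of the pooled differences, the limits of agreement are
# bias +- 1.96 SD, and the RMSE is sqrt(MS_residual), a measure of
# within-participant variability.

#' Grouped angle differences for one agreement analysis
#'
#' @param diffs named list: one numeric vector of angle differences
#'   (degrees) per participant. At least 2 participants with at least 2
#'   observations each.
#' @param method,placement,movement,angle_set labels.
#' @return object of class `difference_set`.
#' @export
difference_set <- function(diffs, method = NA_character_,
                           placement = NA_character_,
                           movement = NA_character_,
                           angle_set = NA_character_) {
  if (!is.list(diffs) || length(diffs) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  if (is.null(names(diffs)) || any(!nzchar(names(diffs))))
    stop("participant lists must be named", call. = FALSE)
  nobs <- vapply(diffs, length, integer(1))
  if (any(nobs < 2L))
    stop("each participant needs at least 2 observations", call. = FALSE)
  if (any(vapply(diffs, function(x) any(!is.finite(x)), logical(1))))
    stop("differences must be finite", call. = FALSE)
  structure(list(diffs = lapply(diffs, as.numeric), method = method,
                 placement = placement, movement = movement,
                 angle_set = angle_set),
            class = "difference_set")
}

#' @export
print.difference_set <- function(x, ...) {
  cat(sprintf("difference_set [%s %s %s %s]: %d participants, %d obs\n",
              x$method, x$placement, x$movement, x$angle_set,
              length(x$diffs), sum(lengths(x$diffs))))
  invisible(x)
}

#' Repeated-measures variance partition of a difference set
#'
#' One-way ANOVA with participant as the factor, followed by the
#' variance-components step: the between-participant variance is
#' `(MS_participant - MS_residual) / n_bar` (clamped at 0), the total
#' variance adds back the residual mean square, and the SD is its square
#' root.
#'
#' @param ds a [difference_set()].
#' @param nbar_method how to average observations per participant:
#'   `"mean"` (arithmetic, `N / k`; default) or `"anova_n0"`
#'   (`(N - sum(n_i^2) / N) / (k - 1)`, the unbalanced-ANOVA effective n).
#' @return list with `MS_participant`, `MS_residual`, `var_between`,
#'   `var_total`, `SD`, `n_bar`, `df_between`, `df_within`.
#' @export
variance_partition <- function(ds, nbar_method = c("mean", "anova_n0")) {
  stopifnot(inherits(ds, "difference_set"))
  nbar_method <- match.arg(nbar_method)
  x <- unlist(ds$diffs, use.names = FALSE)
  ni <- lengths(ds$diffs)
  k <- length(ni)
  N <- sum(ni)
  gm <- mean(x)
  mi <- vapply(ds$diffs, mean, numeric(1))
  ss_between <- sum(ni * (mi - gm)^2)
  ss_within <- sum(vapply(seq_len(k), function(i)
    sum((ds$diffs[[i]] - mi[i])^2), numeric(1)))
  ms_p <- ss_between / (k - 1)
  ms_r <- ss_within / (N - k)
  nbar <- switch(nbar_method,
                 mean = N / k,
                 anova_n0 = (N - sum(ni^2) / N) / (k - 1))
  var_between <- max(0, (ms_p - ms_r) / nbar)
  var_total <- var_between + ms_r
  list(MS_participant = ms_p, MS_residual = ms_r,
       var_between = var_between, var_total = var_total,
       SD = sqrt(var_total), n_bar = nbar, df_between = k - 1,
       df_within = N - k)
}

#' Repeated-measures Bland-Altman agreement statistics
#'
#' Bias is the grand mean of the pooled differences; the 95% limits of
#' agreement are `bias +- 1.96 * SD`, with SD from [variance_partition()];
#' RMSE is the square root of the residual (within-participant) mean square.
#'
#' @inheritParams variance_partition
#' @return object of class `agreement_result`: list with `bias`, `SD`,
#'   `loa_lower`, `loa_upper`, `RMSE`, the variance components, and
#'   `n_participants`, `n_obs`, plus the set labels.
#' @export
bland_altman <- function(ds, nbar_method = c("mean", "anova_n0")) {
  vp <- variance_partition(ds, nbar_method)
  x <- unlist(ds$diffs, use.names = FALSE)
  bias <- mean(x)
  structure(list(bias = bias, SD = vp$SD,
                 loa_lower = bias - 1.96 * vp$SD,
                 loa_upper = bias + 1.96 * vp$SD,
                 RMSE = sqrt(vp$MS_residual),
                 MS_participant = vp$MS_participant,
                 MS_residual = vp$MS_residual,
                 var_between = vp$var_between, var_total = vp$var_total,
                 n_bar = vp$n_bar,
                 n_participants = length(ds$diffs),
                 n_obs = length(x),
                 method = ds$method, placement = ds$placement,
                 movement = ds$movement, angle_set = ds$angle_set),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "agreement [%s %s %s %s]: bias %.2f (SD %.2f), LoA [%.2f, %.2f], RMSE %.2f deg\n",
    x$method, x$placement, x$movement, x$angle_set, x$bias, x$SD,
    x$loa_lower, x$loa_upper, x$RMSE))
  invisible(x)
}

#' One-way ANOVA with partial eta-squared and Cohen's f
#'
#' Standard fixed-effects one-way ANOVA computed from explicit sums of
#' squares; the p-value is the upper tail of the F distribution. The effect
#' size is partial eta-squared `SS_between / (SS_between + SS_within)` and
#' Cohen's `f = sqrt(eta2p / (1 - eta2p))`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @param alpha significance level recorded in the result.
#' @return object of class `anova_result`: `F`, `p`, `eta2p`, `cohens_f`,
#'   `df_between`, `df_within`, `alpha`, `group_means`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  ni <- lengths(groups)
  if (any(ni < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("group values must be finite", call. = FALSE)
  k <- length(groups)
  N <- sum(ni)
  gm <- mean(x)
  mi <- vapply(groups, mean, numeric(1))
  ss_b <- sum(ni * (mi - gm)^2)
  ss_w <- sum(vapply(seq_len(k), function(i)
    sum((groups[[i]] - mi[i])^2), numeric(1)))
  df_b <- k - 1
  df_w <- N - k
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  if (ms_w <= 0 && ss_b <= 0) {
    Fstat <- 0; p <- 1
  } else if (ms_w <= 0) {
    stop("degenerate groups: zero within-group variance with nonzero effect",
         call. = FALSE)
  } else {
    Fstat <- ms_b / ms_w
    p <- pf(Fstat, df_b, df_w, lower.tail = FALSE)
  }
  eta2p <- if (ss_b + ss_w > 0) ss_b / (ss_b + ss_w) else 0
  structure(list(F = Fstat, p = p, eta2p = eta2p,
                 cohens_f = sqrt(eta2p / max(1 - eta2p, .Machine$double.eps)),
                 df_between = df_b, df_within = df_w, alpha = alpha,
                 group_means = mi),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "one-way ANOVA: F(%d, %d) = %.3f, p = %.4g, eta2p = %.3f, Cohen's f = %.3f\n",
    x$df_between, x$df_within, x$F, x$p, x$eta2p, x$cohens_f))
  invisible(x)
}

.agreement_df_check <- function(results) {
  need <- c("method", "placement", "movement", "angle_set", "RMSE")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    stop("results must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  results
}

#' Compare methods by RMSE within each camera placement
#'
#' One one-way ANOVA per placement with method as the factor, on the RMSE
#' values pooled across the movement x angle-set difference sets of that
#' placement.
#'
#' @param results data frame of agreement results (as from
#'   [run_experiment()]'s `agreement` element) with columns `method`,
#'   `placement`, `movement`, `angle_set`, `RMSE`.
#' @param alpha significance level.
#' @return named list of [anova_oneway()] results, one per placement.
#' @export
compare_methods <- function(results, alpha = 0.05) {
  results <- .agreement_df_check(results)
  out <- list()
  for (pl in unique(results$placement)) {
    sub <- results[results$placement == pl, ]
    groups <- split(sub$RMSE, sub$method)
    if (length(unique(lengths(groups))) != 1L)
      stop("mismatched difference-set counts across methods in placement ",
           pl, call. = FALSE)
    out[[pl]] <- anova_oneway(groups, alpha = alpha)
  }
  out
}

#' Compare camera placements by RMSE within each method
#'
#' One one-way ANOVA per method with placement as the factor.
#'
#' @inheritParams compare_methods
#' @return named list of [anova_oneway()] results, one per method.
#' @export
compare_planes <- function(results, alpha = 0.05) {
  results <- .agreement_df_check(results)
  out <- list()
  for (me in unique(results$method)) {
    sub <- results[results$method == me, ]
    groups <- split(sub$RMSE, sub$placement)
    if (length(unique(lengths(groups))) != 1L)
      stop("mismatched difference-set counts across placements for method ",
           me, call. = FALSE)
    out[[me]] <- anova_oneway(groups, alpha = alpha)
  }
  out
}
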