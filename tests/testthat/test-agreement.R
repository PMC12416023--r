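# Repeated-measures variance partition, Bland-Altman, comparison ANOVAs.

test_that("zero-variance difference sets collapse to zero spread", {
  ds <- difference_set(list(P1 = rep(3, 5), P2 = rep(3, 7)))
  vp <- variance_partition(ds)
  expect_equal(vp$MS_participant, 0)
  expect_equal(vp$MS_residual, 0)
  expect_equal(vp$SD, 0)
  ba <- bland_altman(ds)
  expect_equal(ba$bias, 3)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(3, 3))
  expect_equal(ba$RMSE, 0)
})

test_that("mean squares match a hand-written sums-of-squares oracle", {
  diffs <- list(P1 = c(1.2, 0.8, 1.5, 1.1), P2 = c(2.4, 2.0, 2.6, 2.2),
                P3 = c(-0.5, 0.1, -0.2, -0.6))
  ds <- difference_set(diffs)
  vp <- variance_partition(ds)
  or <- brute_force_ss(diffs)
  expect_equal(vp$MS_participant, or$ms_between, tolerance = 1e-10)
  expect_equal(vp$MS_residual, or$ms_within, tolerance = 1e-10)
  nbar <- 4
  vb <- max(0, (or$ms_between - or$ms_within) / nbar)
  expect_equal(vp$var_between, vb, tolerance = 1e-10)
  expect_equal(vp$SD, sqrt(vb + or$ms_within), tolerance = 1e-10)
  ba <- bland_altman(ds)
  expect_equal(ba$bias, or$grand_mean, tolerance = 1e-10)
  expect_equal(ba$loa_lower, or$grand_mean - 1.96 * vp$SD, tolerance = 1e-10)
  expect_equal(ba$RMSE, sqrt(or$ms_within), tolerance = 1e-10)
})

test_that("agreement matches brute force on 100 random unbalanced fixtures", {
  set.seed(101)
  for (i in 1:100) {
    ds <- random_diffset()
    vp <- variance_partition(ds)
    or <- brute_force_ss(ds$diffs)
    expect_equal(vp$MS_participant, or$ms_between, tolerance = 1e-10)
    expect_equal(vp$MS_residual, or$ms_within, tolerance = 1e-10)
    expect_equal(bland_altman(ds)$bias, or$grand_mean, tolerance = 1e-10)
  }
})

test_that("identical participant means clamp the between variance to zero", {
  set.seed(103)
  sigma <- 2.5
  diffs <- lapply(1:12, function(i) {
    x <- rnorm(200, 0, sigma)
    x - mean(x)            # identical (zero) participant means
  })
  names(diffs) <- sprintf("P%02d", 1:12)
  vp <- variance_partition(difference_set(diffs))
  expect_equal(vp$var_between, 0)
  expect_lt(abs(vp$SD - sigma) / sigma, 0.05)
})

test_that("known variance components and LoA coverage are recovered", {
  set.seed(107)
  bias <- 2; sd_b <- 3; sd_w <- 4
  diffs <- lapply(1:12, function(i) bias + rnorm(1, 0, sd_b) +
                    rnorm(500, 0, sd_w))
  names(diffs) <- sprintf("P%02d", 1:12)
  ds <- difference_set(diffs)
  ba <- bland_altman(ds)
  expect_lt(abs(ba$bias - bias) / bias, 0.5)   # bias has only 12 df; loose
  expect_lt(abs(ba$SD - 5) / 5, 0.15)          # sqrt(9 + 16) = 5; the
  # between-participant component carries only 11 df, so ~20% relative
  # sampling error at one sigma
  x <- unlist(ds$diffs)
  cover <- mean(x >= ba$loa_lower & x <= ba$loa_upper)
  expect_gte(cover, 0.94)
  expect_lte(cover, 0.96)
})

test_that("the alternative unbalanced-ANOVA n0 is available", {
  set.seed(109)
  ds <- random_diffset()
  ni <- lengths(ds$diffs)
  n0 <- (sum(ni) - sum(ni^2) / sum(ni)) / (length(ni) - 1)
  expect_equal(variance_partition(ds, "anova_n0")$n_bar, n0)
  expect_equal(variance_partition(ds, "mean")$n_bar, mean(ni))
})

test_that("difference-set contracts are enforced", {
  expect_error(difference_set(list(P1 = c(1, 2))), "2 participants")
  expect_error(difference_set(list(P1 = c(1, 2), P2 = 3)),
               "2 observations")
})

test_that("one-way ANOVA matches aov and the t-squared identity", {
  g <- list(a = c(1, 2, 3, 2.5), b = c(2, 3, 4, 3.2), c = c(0, 1, 0.5, 0.7))
  res <- anova_oneway(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-8)
  or <- brute_force_ss(g)
  expect_equal(res$eta2p, or$ss_between / (or$ss_between + or$ss_within),
               tolerance = 1e-10)
  expect_equal(res$cohens_f, sqrt(res$eta2p / (1 - res$eta2p)),
               tolerance = 1e-12)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(113)
  x <- rnorm(15, 0, 2); y <- rnorm(11, 1, 2)
  res2 <- anova_oneway(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  # identical groups
  res0 <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res0$F, 0)
  expect_equal(res0$eta2p, 0)
  expect_equal(res0$cohens_f, 0)
})

test_that("statistics are scale-equivariant", {
  set.seed(127)
  ds <- random_diffset()
  c_ <- -3.7
  ds2 <- ds
  ds2$diffs <- lapply(ds$diffs, function(x) c_ * x)
  a <- bland_altman(ds); b <- bland_altman(ds2)
  expect_equal(b$bias, c_ * a$bias, tolerance = 1e-10)
  expect_equal(b$SD, abs(c_) * a$SD, tolerance = 1e-10)
  expect_equal(b$RMSE, abs(c_) * a$RMSE, tolerance = 1e-10)
  expect_equal(sort(c(b$loa_lower, b$loa_upper)),
               sort(c_ * c(a$loa_lower, a$loa_upper)), tolerance = 1e-10)
  g <- list(a = rnorm(10), b = rnorm(10, 1))
  r1 <- anova_oneway(g)
  r2 <- anova_oneway(lapply(g, function(x) c_ * x))
  expect_equal(r2$F, r1$F, tolerance = 1e-10)
  expect_equal(r2$eta2p, r1$eta2p, tolerance = 1e-10)
})

test_that("method and placement comparisons run per stratum", {
  set.seed(131)
  grid <- expand.grid(method = c("CF", "IK"),
                      placement = c("frontal", "sagittal"),
                      movement = sprintf("m%02d", 1:10),
                      angle_set = sprintf("a%d", 1:4),
                      stringsAsFactors = FALSE)
  grid$RMSE <- rnorm(nrow(grid), 10, 2)
  cm <- compare_methods(grid)
  expect_named(cm, c("frontal", "sagittal"))
  expect_identical(cm$frontal$df_within, 78L + 0L)
  # identical RMSEs give F = 0
  grid0 <- grid
  grid0$RMSE[grid0$method == "IK"] <- grid0$RMSE[grid0$method == "CF"]
  expect_equal(compare_methods(grid0)$frontal$F, 0)
  # constant shift produces matching group means
  grid2 <- grid
  grid2$RMSE[grid2$method == "IK"] <-
    grid2$RMSE[grid2$method == "CF"] - 2
  cm2 <- compare_methods(grid2)
  expect_gt(cm2$frontal$F, 0)
  expect_equal(unname(diff(cm2$frontal$group_means)), -2, tolerance = 1e-10)
  cp <- compare_planes(grid)
  expect_named(cp, c("CF", "IK"))
  expect_error(compare_methods(grid[-1, ]), "mismatched")
})
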