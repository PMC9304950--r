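test_that("the p-factor reduces to its degenerate constructions", {
  set.seed(81)
  x <- rnorm(300)
  pf <- p_factor(cbind(a = x, b = x, c = x))
  expect_equal(pf$var_explained, 1)
  expect_equal(pf$scores, as.numeric(scale(x)), tolerance = 1e-8)
  # independent columns: isotropy
  y <- matrix(rnorm(4000 * 5), 4000)
  pf2 <- p_factor(y)
  expect_equal(pf2$var_explained, 1 / 5, tolerance = 0.15)
  # sign convention and unit norm
  expect_gt(mean(pf2$loadings), 0)
  expect_equal(sum(pf2$loadings^2), 1)
  expect_warning(p_factor(cbind(x, const = 1)), "zero-variance")
})

test_that("a one-factor structure is recovered by the p-factor", {
  set.seed(82)
  n <- 3000; m <- 6; lam <- 0.6
  g <- rnorm(n)
  y <- lam * matrix(g, n, m) + sqrt(1 - lam^2) * matrix(rnorm(n * m), n)
  pf <- p_factor(y)
  expect_equal(unname(pf$loadings), rep(1 / sqrt(m), m), tolerance = 0.1)
  expect_gt(abs(cor(pf$scores, g)), 0.85)
  # invariant (up to sign) to column rescaling
  pf2 <- p_factor(sweep(y, 2, c(1, 10, 0.1, 2, 5, 0.5), `*`))
  expect_gt(abs(cor(pf$scores, pf2$scores)), 0.999)
})

test_that("incremental GPS variance equals the squared partial correlation", {
  set.seed(83)
  n <- 2000
  cov1 <- rnorm(n)
  g <- rnorm(n)
  y <- 0.5 * cov1 + 0.09 * g + rnorm(n, sd = sqrt(1 - 0.25 - 0.0081))
  out <- gps_regression(y, g, data.frame(cov1 = cov1))
  # oracle: squared partial correlation of y and g given cov1
  ry <- resid(lm(y ~ cov1)); rg <- resid(lm(g ~ cov1))
  pr2 <- cor(ry, rg)^2 * (1 - out$r2_base)
  expect_equal(out$delta_r2, pr2, tolerance = 1e-10)
  expect_gte(out$delta_r2, 0)
  # the low-prediction regime: under 1% of variance
  expect_lt(out$delta_r2, 0.01)
  expect_gt(out$delta_r2, 0.002)
})

test_that("an unrelated GPS explains nothing and permutes uniformly", {
  set.seed(84)
  n <- 800
  out <- gps_regression(rnorm(n), rnorm(n), n_perm = 99, seed = 1)
  expect_lt(out$delta_r2, 0.01)
  expect_gt(out$p_perm, 0.05)
})

test_that("extreme grouping matches normal tail shares and flags edge cases", {
  set.seed(85)
  z <- rnorm(40000)
  g <- extreme_groups(z)
  expect_equal(sum(g == "low", na.rm = TRUE) / length(z), pnorm(-1),
               tolerance = 0.05)
  expect_equal(sum(g == "high", na.rm = TRUE) / length(z), pnorm(-1),
               tolerance = 0.05)
  # labels invariant to location shift
  expect_identical(g, extreme_groups(z + 100))
  expect_warning(g0 <- extreme_groups(rep(0, 10)), "no variance")
  expect_true(all(is.na(g0)))
})

test_that("trajectory contrasts reflect construction", {
  set.seed(86)
  n <- 2000
  y <- matrix(rnorm(n * 3), n)
  sel <- rnorm(n)
  grp <- extreme_groups(sel)
  # group-blind waves: no contrast
  tc <- trajectory_contrast(y, grp)
  expect_lt(max(abs(tc$d)), 0.2)
  expect_gt(tc$interaction$p_value, 0.001)
  # baseline selection: truncated-normal oracle for the baseline gap
  y2 <- cbind(0.8 * sel + sqrt(1 - 0.64) * rnorm(n), y[, 2:3])
  tc2 <- trajectory_contrast(y2, grp)
  gap_oracle <- 0.8 * 2 * dnorm(1) / pnorm(-1)
  sd_within <- sqrt(1 - 0.64 * (1 - (1 + dnorm(1) / pnorm(-1) -
                                       (dnorm(1) / pnorm(-1))^2)))
  expect_gt(tc2$d[1], 0)
  expect_equal(unname(tc2$d[1]), gap_oracle / sd_within, tolerance = 0.1)
})

test_that("environmental correlates recover a generating correlation", {
  set.seed(87)
  n <- 3000
  env <- rnorm(n)
  ph <- 0.21 * env + sqrt(1 - 0.21^2) * rnorm(n)
  out <- environment_correlates(ph, env)
  expect_equal(out$r, 0.21, tolerance = 0.2)
  expect_true(out$lower < out$r & out$r < out$upper)
  expect_equal(environment_correlates(env, env)$r, 1)
  expect_lt(abs(environment_correlates(rnorm(n), env)$r), 3 / sqrt(n))
  expect_error(environment_correlates(rep(1, 10), rnorm(10)), "constant")
})

test_that("attrition checks detect selective retention", {
  co <- quick_cohort(n_pairs = 3000, n_waves = 1, seed = 88)
  out <- attrition_check(co, co, "y_t1")
  expect_equal(out$std_diff, 0)
  set.seed(89)
  mcar <- co[sample(nrow(co), 3000), ]
  expect_lt(abs(attrition_check(co, mcar, "y_t1")$std_diff), 0.08)
  # retain only below-median baseline: truncation oracle for the mean shift
  trunc <- co[co$y_t1 < median(co$y_t1), ]
  out3 <- attrition_check(co, trunc, "y_t1")
  expect_equal(out3$std_diff, -dnorm(0) / 0.5, tolerance = 0.1)
})
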