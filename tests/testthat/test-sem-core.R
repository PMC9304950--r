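# closed-form Gaussian deviance at the ML moments
gaussian_deviance <- function(y) {
  n <- nrow(y); p <- ncol(y)
  s_ml <- cov(y) * (n - 1) / n
  n * (p * log(2 * pi) + determinant(s_ml)$modulus[1] + p)
}

test_that("saturated FIML on complete data equals the closed-form deviance", {
  set.seed(41)
  y <- MASS::mvrnorm(300, c(1, -0.5, 0), cs_corr(3, 0.4))
  sat <- saturated_model(paste0("v", 1:3))
  fit <- fit_ml(sat, y, n_restarts = 1)
  expect_true(fit$converged)
  expect_equal(fit$deviance, gaussian_deviance(y), tolerance = 1e-6)
  # recovered moments match sample moments
  imp <- sat$implied(fit$estimates)[[1]]
  expect_equal(imp$mean, colMeans(y), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(imp$cov, cov(y) * 299 / 300, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("all-missing rows contribute nothing to the deviance", {
  set.seed(42)
  y <- MASS::mvrnorm(50, c(0, 0), diag(2))
  sat <- saturated_model(c("a", "b"))
  theta <- c(0, 0, 1, 0, 1)
  d1 <- fiml_deviance(sat, theta, y)
  d2 <- fiml_deviance(sat, theta, rbind(y, c(NA, NA), c(NA, NA)))
  expect_equal(d1, d2)
  # deviance invariant to row order
  d3 <- fiml_deviance(sat, theta, y[sample(50), ])
  expect_equal(d1, d3)
})

test_that("FIML with missing data beats listwise moments and stays finite", {
  set.seed(43)
  y <- MASS::mvrnorm(400, c(0, 0, 0), cs_corr(3, 0.5))
  y[sample(length(y), 200)] <- NA
  y <- y[rowSums(!is.na(y)) > 0, ]
  sat <- saturated_model(paste0("v", 1:3))
  fit <- fit_ml(sat, y, n_restarts = 1)
  expect_true(fit$converged)
  expect_true(is.finite(fit$deviance))
  expect_gt(fit$n_patterns[1], 1)
})

test_that("a structured model recovers its generating parameters", {
  # two-group common-variance model: N(mu_g, s^2) per group
  set.seed(44)
  model <- structured_model(
    c("mu1", "mu2", "s"), start = c(0, 0, 1),
    implied = function(th) list(
      list(mean = th[1], cov = matrix(th[3]^2)),
      list(mean = th[2], cov = matrix(th[3]^2))),
    var_names = list("x", "x"), lower = c(-Inf, -Inf, 1e-6))
  data <- list(matrix(rnorm(4000, 1, 1.5)), matrix(rnorm(4000, -1, 1.5)))
  fit <- fit_ml(model, data, n_restarts = 1)
  expect_equal(unname(fit$estimates),
               c(1, -1, 1.5), tolerance = 0.05)
  # nested model (equal means) cannot beat the full model
  nested <- structured_model(
    c("mu", "s"), start = c(0, 1),
    implied = function(th) list(
      list(mean = th[1], cov = matrix(th[2]^2)),
      list(mean = th[1], cov = matrix(th[2]^2))),
    var_names = list("x", "x"), lower = c(-Inf, 1e-6))
  nfit <- fit_ml(nested, data, n_restarts = 1)
  expect_gte(nfit$deviance, fit$deviance)
  test <- lrt(fit, nfit)
  expect_equal(test$df, 1)
  expect_lt(test$p_value, 1e-10)
})

test_that("profile intervals match Wald intervals in the quadratic case", {
  # known-variance Gaussian mean: profile CI must equal xbar +/- 1.96/sqrt(n)
  set.seed(45)
  x <- matrix(rnorm(200, 0.3))
  model <- structured_model(
    "mu", start = 0,
    implied = function(th) list(list(mean = th[1], cov = matrix(1))),
    var_names = list("x"))
  fit <- fit_ml(model, x, n_restarts = 0)
  ci <- profile_ci(fit, "mu")
  se <- 1 / sqrt(200)
  expect_equal(ci$lower, mean(x) - qnorm(0.975) * se, tolerance = 1e-3)
  expect_equal(ci$upper, mean(x) + qnorm(0.975) * se, tolerance = 1e-3)
  # degenerate level
  ci0 <- profile_ci(fit, "mu", level = 0)
  expect_equal(ci0$lower, ci0$upper)
})

test_that("identical models give a zero likelihood-ratio statistic", {
  set.seed(46)
  x <- matrix(rnorm(100))
  sat <- saturated_model("x")
  f1 <- fit_ml(sat, x, n_restarts = 0)
  out <- lrt(f1, f1, df = 1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("the null LRT statistic is chi-square distributed", {
  set.seed(47)
  # independence vs saturated on truly independent bivariate normals
  sat <- saturated_model(c("a", "b"))
  ind <- structured_model(
    c("mu1", "mu2", "s1", "s2"), start = c(0, 0, 1, 1),
    implied = function(th) list(
      list(mean = th[1:2], cov = diag(th[3:4]^2))),
    var_names = list(c("a", "b")), lower = c(-Inf, -Inf, 1e-6, 1e-6))
  stats <- replicate(300, {
    y <- matrix(rnorm(300), ncol = 2)
    f1 <- fit_ml(sat, y, n_restarts = 0)
    f0 <- fit_ml(ind, y, n_restarts = 0)
    lrt(f1, f0)$statistic
  })
  ks <- stats::ks.test(stats, "pchisq", df = 1)
  expect_gt(ks$p.value, 0.01)
  # power grows with effect size
  power_at <- function(rho) {
    mean(replicate(60, {
      y <- MASS::mvrnorm(150, c(0, 0), cs_corr(2, rho))
      f1 <- fit_ml(sat, y, n_restarts = 0)
      f0 <- fit_ml(ind, y, n_restarts = 0)
      lrt(f1, f0)$p_value < 0.05
    }))
  }
  expect_lt(power_at(0), power_at(0.5) + 1e-9)
  expect_gt(power_at(0.5), 0.9)
})
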