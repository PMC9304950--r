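test_that("Falconer estimates invert the model-implied correlations", {
  expect_equal(unlist(falconer(0.5, 0.5)), c(a2 = 0, c2 = 0.5, e2 = 0.5))
  expect_equal(unlist(falconer(1, 0.5)), c(a2 = 1, c2 = 0, e2 = 0))
  expect_equal(unlist(falconer(0.40, 0.235)),
               c(a2 = 0.33, c2 = 0.07, e2 = 0.60))
  expect_warning(falconer(0.2, 0.3), "outside")
})

test_that("twin correlations behave under degenerate construction", {
  co <- quick_cohort(n_pairs = 200, n_waves = 1, ace = c(1, 0, 0), seed = 51)
  tc <- twin_correlations(co)
  expect_equal(tc$r[tc$zygosity == "MZ"], 1, tolerance = 1e-10)
  # invariant to co-twin ordering
  sw <- co; sw$twin <- 3L - sw$twin
  expect_equal(twin_correlations(sw)$r, tc$r)
})

test_that("the univariate ACE model recovers generating components", {
  cfg <- quick_config(n_pairs = 5000, n_waves = 1, ace = c(0.6, 0.2, 0.2),
                      seed = 52)
  co <- residualize(simulate_cohort(cfg))
  f <- fit_univariate_ace(co, "y", 1, ci = FALSE, n_restarts = 1)
  expect_true(f$converged)
  expect_equal(sum(f$components), 1, tolerance = 1e-6)
  expect_equal(unname(f$components), c(0.6, 0.2, 0.2), tolerance = 0.15)
  # nesting: ACE fits at least as well as AE and CE
  ae <- fit_univariate_ace(co, "y", 1, submodel = "AE", ci = FALSE,
                           n_restarts = 1)
  ce <- fit_univariate_ace(co, "y", 1, submodel = "CE", ci = FALSE,
                           n_restarts = 1)
  expect_lte(f$deviance, ae$deviance + 1e-6)
  expect_lte(f$deviance, ce$deviance + 1e-6)
})

test_that("FIML keeps pairs with a missing co-twin", {
  cfg <- quick_config(n_pairs = 800, n_waves = 1, seed = 53)
  co <- residualize(simulate_cohort(cfg))
  drop_rows <- sample(which(co$twin == 2), 300)
  co$y_t1[drop_rows] <- NA
  f <- fit_univariate_ace(co, "y", 1, ci = FALSE, n_restarts = 1)
  expect_true(f$converged)
  expect_equal(unname(sum(f$fit$n)), 1600) # all pairs retained
  expect_gt(max(f$fit$n_patterns), 1)
})

test_that("profile intervals for heritability cover the generating value", {
  set.seed(54)
  hits <- replicate(120, {
    cfg <- quick_config(n_pairs = 250, n_waves = 1,
                        seed = sample.int(1e6, 1))
    co <- residualize(simulate_cohort(cfg))
    f <- fit_univariate_ace(co, "y", 1, ci = TRUE, n_restarts = 0)
    f$ci["a2", 1] <= 0.33 && 0.33 <= f$ci["a2", 2]
  })
  cover <- mean(hits)
  expect_gt(cover, 0.88)
  expect_lte(cover, 1)
})

test_that("correlated-factors fits recover the factor correlations", {
  cfg <- quick_config(n_pairs = 2500, n_waves = 2, rho_a = 1, seed = 55)
  co <- residualize(simulate_cohort(cfg))
  cf <- fit_correlated_factors(co, "y", 1:2, ci = FALSE, n_restarts = 1)
  expect_true(cf$converged)
  expect_equal(cf$rG[1, 2], 1, tolerance = 0.05)
  expect_equal(cf$rE[1, 2], 0.41, tolerance = 0.2)
  expect_equal(cf$rG, t(cf$rG))
  expect_true(all(diag(cf$rG) == 1))
  expect_true(all(abs(cf$rG) <= 1 + 1e-8))
})

test_that("Cholesky and correlated-factors models share one likelihood", {
  cfg <- quick_config(n_pairs = 600, n_waves = 3, rho_a = 0.9, seed = 56)
  co <- residualize(simulate_cohort(cfg))
  cf <- fit_correlated_factors(co, "y", 1:3, ci = FALSE, n_restarts = 2)
  ch <- fit_cholesky(co, "y", 1:3, n_restarts = 2)
  expect_equal(ch$deviance, cf$deviance, tolerance = 1e-5)
  # same derived genetic covariance structure
  expect_equal(ch$rG, cf$rG, tolerance = 0.1)
  # per-wave total A variance agrees between parameterizations
  a_ch <- rowSums(ch$L_A^2)
  a_cf <- unname(cf$fit$estimates[paste0("a", 1:3)])^2
  expect_equal(unname(a_ch), a_cf, tolerance = 0.05)
})

test_that("unit genetic correlation leaves no genetic innovation", {
  cfg <- quick_config(n_pairs = 2500, n_waves = 2, rho_a = 1, seed = 57)
  co <- residualize(simulate_cohort(cfg))
  ch <- fit_cholesky(co, "y", 1:2, n_restarts = 1)
  expect_lt(ch$innovation[2, "A"], 0.1)
  expect_true(all(ch$innovation >= 0 & ch$innovation <= 1))
})
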