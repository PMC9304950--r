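test_that("degenerate variance decompositions behave as constructed", {
  # pure genetic determination: MZ co-twins coincide
  co <- quick_cohort(n_pairs = 100, ace = c(1, 0, 0), seed = 1)
  mz <- co[co$zygosity == "MZ", ]
  expect_lt(max(abs(mz$y_t1[mz$twin == 1] - mz$y_t1[mz$twin == 2])), 1e-10)

  # pure noise: both intraclass correlations vanish
  co <- quick_cohort(n_pairs = 4000, ace = c(0, 0, 1), seed = 2)
  tc <- twin_correlations(co, waves = 1)
  expect_lt(max(abs(tc$r)), 3 / sqrt(4000))
})

test_that("intraclass correlations match the model-implied values", {
  co <- quick_cohort(n_pairs = 8000, seed = 3)
  tc <- twin_correlations(co, waves = 1)
  tol <- 4 / sqrt(8000)
  expect_equal(tc$r[tc$zygosity == "MZ"], 0.40, tolerance = tol / 0.4)
  expect_equal(tc$r[tc$zygosity == "DZ"], 0.235, tolerance = tol / 0.235)
})

test_that("cross-wave phenotypic correlation follows the path-traced value", {
  cfg <- quick_config(n_pairs = 6000, n_waves = 2, seed = 4)
  co <- simulate_cohort(cfg)
  expected <- 0.33 * 0.95 + 0.07 * 0.90 + 0.60 * 0.41
  r <- cor(co$y_t1, co$y_t2)
  expect_equal(r, expected, tolerance = 0.05 / expected)
})

test_that("the generator is seed-reproducible and variance-stable", {
  cfg <- sim_config(n_mz_pairs = 300, n_dz_pairs = 300, n_waves = 3,
                    measures = c("a", "b"),
                    wave_shifts = c(0, 0.5, 1), seed = 9)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  co3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(co1$a_t1, co3$a_t1))
  # mean structure does not alter variance
  for (col in c("a_t1", "a_t2", "a_t3"))
    expect_equal(var(co1[[col]]), 1, tolerance = 0.15)
  # cross-measure correlation near the configured value
  expect_equal(cor(co1$a_t1, co1$b_t1), 0.40, tolerance = 0.25)
})

test_that("attrition mechanisms delete the right cells", {
  cfg <- quick_config(n_pairs = 200, n_waves = 2, seed = 5,
                      attrition = list(retention = c(1, 1),
                                       mechanism = "MCAR"))
  co <- simulate_cohort(cfg)
  expect_identical(apply_attrition(co, cfg, seed = 1), co)

  cfg <- quick_config(n_pairs = 5000, n_waves = 2, seed = 5,
                      attrition = list(retention = c(1, 0.5),
                                       mechanism = "MCAR"))
  co <- apply_attrition(simulate_cohort(cfg), cfg, seed = 6)
  expect_false(anyNA(co$y_t1))
  frac <- mean(is.na(co$y_t2))
  expect_equal(frac, 0.5, tolerance = 4 / sqrt(10000) / 0.5)

  cfg <- quick_config(n_pairs = 4000, n_waves = 2, seed = 5,
                      attrition = list(retention = c(1, 0.7),
                                       mechanism = "MAR", mar_slope = 1))
  co0 <- simulate_cohort(cfg)
  co <- apply_attrition(co0, cfg, seed = 7)
  kept <- !is.na(co$y_t2)
  # selection against high baseline scorers lowers the retained baseline mean
  expect_lt(mean(co$y_t1[kept]), mean(co$y_t1) - 0.05)
})

test_that("latent classes are drawn at their mixing proportions", {
  cfg <- quick_config(n_pairs = 100, n_waves = 5, seed = 8,
                      profiles = list(proportions = 1,
                                      offsets = matrix(0, 1, 5)))
  co <- simulate_cohort(cfg)
  co1 <- inject_profiles(co, cfg, seed = 1)
  expect_equal(co1$y_t3, co$y_t3)

  props <- c(0.729, 0.216, 0.055)
  offs <- rbind(rep(0, 5), c(0, 2, 0, 0, 0), c(0, 2, 2, 2, 2))
  cfg <- quick_config(n_pairs = 5000, n_waves = 5, seed = 8,
                      profiles = list(proportions = props, offsets = offs))
  co <- inject_profiles(simulate_cohort(cfg), cfg, seed = 2)
  cls <- cohort_truth(co)$class
  n <- length(cls)
  for (k in 1:3)
    expect_lt(abs(mean(cls == k) - props[k]),
              4 * sqrt(props[k] * (1 - props[k]) / n))
  # offsets land on the assigned individuals
  expect_equal(mean(co$y_t2[cls == 3]) - mean(co$y_t2[cls == 1]), 2,
               tolerance = 0.15)
})

test_that("simulated polygenic scores have twin structure and the stated
           correlation with the genetic factor", {
  cfg <- quick_config(n_pairs = 4000, n_waves = 1, rho_a = 1, rho_c = 1,
                      rho_e = 1, seed = 12,
                      gps = list(list(name = "null", cor = 0),
                                 list(name = "dep", cor = 0.1)))
  co <- simulate_gps(simulate_cohort(cfg), cfg, seed = 13)
  n <- nrow(co)
  expect_lt(abs(cor(co$gps_null, co$y_t1)), 3 / sqrt(n))
  # path tracing: r(GPS, phenotype) = cor * sqrt(a2)
  expect_equal(cor(co$gps_dep, co$y_t1), 0.1 * sqrt(0.33),
               tolerance = 3 / sqrt(n) / (0.1 * sqrt(0.33)))
  mz <- co[co$zygosity == "MZ", ]
  expect_lt(max(abs(mz$gps_dep[mz$twin == 1] - mz$gps_dep[mz$twin == 2])),
            1e-10)
  dz <- co[co$zygosity == "DZ", ]
  expect_equal(cor(dz$gps_dep[dz$twin == 1], dz$gps_dep[dz$twin == 2]),
               0.5, tolerance = 0.1)
})
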