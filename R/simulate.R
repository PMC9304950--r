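#' Simulate a synthetic twin cohort
#'
#' Generates a wide per-individual table of twin pairs with the covariance
#' structure of the classical twin design. For each measure, per-wave latent
#' additive-genetic (A), shared-environmental (C) and nonshared-environmental
#' (E) factors are drawn jointly per family under the Kronecker structure
#' (pair relatedness x cross-wave correlation): A correlates 1 within MZ
#' pairs and 0.5 within DZ pairs, C correlates 1 within pairs, E is
#' uncorrelated between co-twins. The phenotype at wave w is
#' `sqrt(a2_w) A + sqrt(c2_w) C + sqrt(e2_w) E` plus the configured mean
#' structure, so each measure-wave has population variance 1 before mean
#' shifts.
#'
#' Latent truth (baseline A factor scores, and class labels once
#' [inject_profiles()] has run) is kept in a sidecar table available via
#' [cohort_truth()]; it is written separately by [write_cohort()] and never
#' appears among the analysis-facing columns.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to the seed stored in `config`.
#' @return A `data.frame` with columns `family_id`, `twin` (1 or 2),
#'   `zygosity` (`"MZ"`/`"DZ"`), `sex` (`"F"`/`"M"`), `age`, and
#'   `<measure>_t<wave>` phenotype columns; truth sidecar in
#'   `attr(, "truth")`.
#' @export
#' @examples
#' cfg <- sim_config(n_mz_pairs = 50, n_dz_pairs = 50, n_waves = 2,
#'                   measures = "anxiety", seed = 1)
#' head(simulate_cohort(cfg))
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)

  W <- config$n_waves
  M <- length(config$measures)
  MW <- M * W
  corr_m <- if (M > 1) cs_corr(M, config$measure_cor) else matrix(1, 1, 1)
  sig_a <- kronecker(corr_m, config$corr_a)
  sig_c <- kronecker(corr_m, config$corr_c)
  sig_e <- kronecker(corr_m, config$corr_e)

  draw <- function(n, sigma) {
    if (n == 0) return(matrix(0, 0, nrow(sigma)))
    MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
  }

  gen_group <- function(n_pairs, zyg) {
    if (zyg == "MZ") {
      a <- draw(n_pairs, sig_a)
      a1 <- a; a2 <- a
    } else {
      pair2 <- matrix(c(1, 0.5, 0.5, 1), 2)
      aj <- draw(n_pairs, kronecker(pair2, sig_a))
      a1 <- aj[, seq_len(MW), drop = FALSE]
      a2 <- aj[, MW + seq_len(MW), drop = FALSE]
    }
    cc <- draw(n_pairs, sig_c)
    e1 <- draw(n_pairs, sig_e)
    e2 <- draw(n_pairs, sig_e)
    list(a1 = a1, a2 = a2, c1 = cc, c2 = cc, e1 = e1, e2 = e2)
  }

  n_mz <- config$n_mz_pairs
  n_dz <- config$n_dz_pairs
  lat_mz <- gen_group(n_mz, "MZ")
  lat_dz <- gen_group(n_dz, "DZ")

  # sexes: MZ co-twins identical; DZ drawn independently (same-sex with
  # probability one half)
  sex_mz <- sample(c("F", "M"), n_mz, replace = TRUE)
  sex_dz1 <- sample(c("F", "M"), n_dz, replace = TRUE)
  sex_dz2 <- sample(c("F", "M"), n_dz, replace = TRUE)
  age_mz <- runif(n_mz, config$age_range[1], config$age_range[2])
  age_dz <- runif(n_dz, config$age_range[1], config$age_range[2])

  paths <- sqrt(config$ace) # n_waves x 3 path coefficients

  build_pheno <- function(a, c_, e, sex) {
    y <- matrix(NA_real_, nrow(a), MW)
    for (m in seq_len(M)) {
      idx <- (m - 1) * W + seq_len(W)
      ym <- sweep(a[, idx, drop = FALSE], 2, paths[, 1], `*`) +
        sweep(c_[, idx, drop = FALSE], 2, paths[, 2], `*`) +
        sweep(e[, idx, drop = FALSE], 2, paths[, 3], `*`)
      if (config$skew) ym <- scale(exp(ym))
      ym <- sweep(ym, 2, config$wave_shifts, `+`)
      ym <- ym + config$sex_effect * (ifelse(sex == "F", 0.5, -0.5))
      y[, idx] <- ym
    }
    y
  }

  y_mz1 <- build_pheno(lat_mz$a1, lat_mz$c1, lat_mz$e1, sex_mz)
  y_mz2 <- build_pheno(lat_mz$a2, lat_mz$c2, lat_mz$e2, sex_mz)
  y_dz1 <- build_pheno(lat_dz$a1, lat_dz$c1, lat_dz$e1, sex_dz1)
  y_dz2 <- build_pheno(lat_dz$a2, lat_dz$c2, lat_dz$e2, sex_dz2)

  fam_mz <- seq_len(n_mz)
  fam_dz <- n_mz + seq_len(n_dz)
  # measure-major, matching the latent column layout
  pheno_names <- paste0(rep(config$measures, each = W), "_t",
                        rep(seq_len(W), M))

  assemble <- function(fam, twin, zyg, sex, age, y) {
    d <- data.frame(family_id = fam, twin = twin, zygosity = zyg,
                    sex = sex, age = age, stringsAsFactors = FALSE)
    y <- as.data.frame(y)
    names(y) <- pheno_names
    cbind(d, y)
  }

  cohort <- rbind(
    assemble(fam_mz, 1L, "MZ", sex_mz, age_mz, y_mz1),
    assemble(fam_mz, 2L, "MZ", sex_mz, age_mz, y_mz2),
    assemble(fam_dz, 1L, "DZ", sex_dz1, age_dz, y_dz1),
    assemble(fam_dz, 2L, "DZ", sex_dz2, age_dz, y_dz2)
  )
  cohort <- cohort[order(cohort$family_id, cohort$twin), ]
  rownames(cohort) <- NULL

  # sidecar truth: baseline A factor score per measure
  a_base <- rbind(
    lat_mz$a1[, (seq_len(M) - 1) * W + 1, drop = FALSE],
    lat_mz$a2[, (seq_len(M) - 1) * W + 1, drop = FALSE],
    lat_dz$a1[, (seq_len(M) - 1) * W + 1, drop = FALSE],
    lat_dz$a2[, (seq_len(M) - 1) * W + 1, drop = FALSE]
  )
  truth <- data.frame(
    family_id = c(fam_mz, fam_mz, fam_dz, fam_dz),
    twin = c(rep(1L, n_mz), rep(2L, n_mz), rep(1L, n_dz), rep(2L, n_dz))
  )
  a_base <- as.data.frame(a_base)
  names(a_base) <- paste0("A_", config$measures)
  truth <- cbind(truth, a_base)
  truth$class <- NA_integer_
  truth <- truth[order(truth$family_id, truth$twin), ]
  rownames(truth) <- NULL

  attr(cohort, "truth") <- truth
  attr(cohort, "measures") <- config$measures
  attr(cohort, "n_waves") <- W
  cohort
}

#' Truth sidecar of a simulated cohort
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @return The sidecar `data.frame` (baseline A factor scores and, after
#'   [inject_profiles()], latent class labels), or `NULL` for cohorts read
#'   from disk without one.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

pheno_cols <- function(cohort, measures = NULL, waves = NULL) {
  meas <- measures %||% attr(cohort, "measures") %||%
    unique(sub("_t[0-9]+$", "",
               grep("_t[0-9]+$", names(cohort), value = TRUE)))
  nw <- waves %||% seq_len(attr(cohort, "n_waves") %||%
    max(as.integer(sub(".*_t", "",
                       grep("_t[0-9]+$", names(cohort), value = TRUE)))))
  list(measures = meas, waves = nw)
}

#' Assign latent trajectory classes and add their mean offsets
#'
#' Each individual is assigned one latent class with the configured mixing
#' proportions; the class's per-wave mean-offset vector (in s.d. units) is
#' added to every measure's trajectory. True class labels are stored in the
#' truth sidecar only, so recovery tests cannot leak them.
#'
#' @param cohort Cohort from [simulate_cohort()].
#' @param config The [sim_config()] carrying `profiles`.
#' @param seed Integer seed.
#' @return The modified cohort.
#' @export
inject_profiles <- function(cohort, config, seed = NULL) {
  prof <- config$profiles
  if (is.null(prof)) stop("config has no profile spec")
  if (ncol(prof$offsets) != config$n_waves)
    stop("profile offset vectors must have length n_waves")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(cohort)
  k <- length(prof$proportions)
  cls <- sample.int(k, n, replace = TRUE, prob = prof$proportions)
  pc <- pheno_cols(cohort)
  for (m in pc$measures) {
    for (w in pc$waves) {
      col <- paste0(m, "_t", w)
      cohort[[col]] <- cohort[[col]] + prof$offsets[cls, w]
    }
  }
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    truth$class <- cls
    attr(cohort, "truth") <- truth
  } else {
    attr(cohort, "truth") <- data.frame(family_id = cohort$family_id,
                                        twin = cohort$twin, class = cls)
  }
  cohort
}

#' Delete wave data according to an attrition process
#'
#' Waves 2 and later are set missing (all measures of an individual at that
#' wave) with probability `1 - retention[w]`. Under `"MCAR"` deletion is
#' independent of everything; under `"MAR"` the retention probability is
#' `plogis(qlogis(retention[w]) - mar_slope * z)`, with `z` the individual's
#' standardized mean baseline score, so high baseline scorers are retained
#' less often when `mar_slope > 0`. Baseline (wave 1) is never deleted.
#'
#' @inheritParams inject_profiles
#' @return The cohort with `NA` cells.
#' @export
apply_attrition <- function(cohort, config, seed = NULL) {
  at <- config$attrition
  if (is.null(at)) stop("config has no attrition spec")
  if (any(at$retention <= 0)) stop("retention probabilities must be > 0")
  if (!is.null(seed)) set.seed(seed)

  pc <- pheno_cols(cohort)
  base_cols <- paste0(pc$measures, "_t1")
  zbase <- rowMeans(as.matrix(cohort[, base_cols, drop = FALSE]),
                    na.rm = TRUE)
  zbase <- as.numeric(scale(zbase))
  n <- nrow(cohort)

  for (w in pc$waves[-1]) {
    ret <- at$retention[w]
    p_keep <- if (at$mechanism == "MAR")
      plogis(qlogis(min(ret, 1 - 1e-12)) - at$mar_slope * zbase)
    else rep(ret, n)
    drop <- runif(n) > p_keep
    if (any(drop)) {
      cols <- paste0(pc$measures, "_t", w)
      cohort[drop, cols] <- NA_real_
    }
  }
  cohort
}

#' Attach simulated polygenic scores
#'
#' Each configured score is `cor * A + sqrt(1 - cor^2) * U`, where `A` is the
#' individual's true baseline additive-genetic factor score (first measure)
#' and `U` an independent standard-normal with twin structure (shared within
#' MZ pairs, correlated 0.5 within DZ pairs). Scores are therefore identical
#' within MZ pairs, correlate 0.5 between DZ co-twins, and correlate `cor`
#' with the baseline genetic factor.
#'
#' @inheritParams inject_profiles
#' @return The cohort with `gps_<name>` columns appended.
#' @export
simulate_gps <- function(cohort, config, seed = NULL) {
  gspec <- config$gps
  if (is.null(gspec)) stop("config has no gps spec")
  truth <- attr(cohort, "truth")
  if (is.null(truth) || !any(startsWith(names(truth), "A_")))
    stop("cohort carries no latent truth; GPS require a simulated cohort")
  if (!is.null(seed)) set.seed(seed)

  a_col <- grep("^A_", names(truth), value = TRUE)[1]
  stopifnot(all(truth$family_id == cohort$family_id),
            all(truth$twin == cohort$twin))
  a <- truth[[a_col]]

  fams <- unique(cohort$family_id)
  zyg <- cohort$zygosity[match(fams, cohort$family_id)]
  idx1 <- match(fams, ifelse(cohort$twin == 1L, cohort$family_id, NA))
  idx2 <- match(fams, ifelse(cohort$twin == 2L, cohort$family_id, NA))

  for (g in gspec) {
    if (abs(g$cor) >= 1) stop("|gps correlation| must be < 1")
    u <- numeric(nrow(cohort))
    mz <- zyg == "MZ"
    if (any(mz)) {
      u_pair <- rnorm(sum(mz))
      u[idx1[mz]] <- u_pair
      u[idx2[mz]] <- u_pair
    }
    if (any(!mz)) {
      ud <- MASS::mvrnorm(sum(!mz), c(0, 0),
                          matrix(c(1, 0.5, 0.5, 1), 2))
      if (sum(!mz) == 1) ud <- matrix(ud, 1)
      u[idx1[!mz]] <- ud[, 1]
      u[idx2[!mz]] <- ud[, 2]
    }
    cohort[[paste0("gps_", g$name)]] <- g$cor * a + sqrt(1 - g$cor^2) * u
  }
  cohort
}

#' Simulate an extremes cohort of unrelated individuals
#'
#' Builds a single-twin (unrelated) sample tailored to extreme-group
#' trajectory contrasts: `n_measures` correlated baseline measures loading on
#' a general liability factor, and pandemic waves whose scores are linked to
#' that factor so that the standardized gap at each wave between individuals
#' above +1 s.d. and below -1 s.d. on the baseline first principal component
#' equals a target Cohen's d.
#'
#' The link coefficient solves the truncated-normal selection identity: for a
#' score correlating `r` with the (standard normal) selection variable, the
#' expected high-minus-low gap after +/-1 s.d. selection is
#' `r * 2 * dnorm(1) / pnorm(-1)` and the within-group variance is
#' `1 - r^2 (1 - v)` with `v` the truncated variance, giving
#' `r^2 = d^2 / (gap^2 + (1 - v) d^2)`. The baseline principal component is
#' approximated by the measure mean (exact in the compound-symmetric limit).
#'
#' @param n Number of individuals.
#' @param n_measures Number of baseline measures.
#' @param n_waves Total waves (baseline + pandemic waves).
#' @param measure_cor Cross-measure correlation at each wave.
#' @param wave_gaps Target high-vs-low Cohen's d at waves 2..`n_waves`.
#' @param seed Integer seed.
#' @return A `data.frame` of `id` plus `<measure>_t<wave>` columns; the true
#'   liability factor is in `attr(, "truth")$g`.
#' @export
simulate_extremes_cohort <- function(n, n_measures = 8, n_waves = 5,
                                     measure_cor = 0.40,
                                     wave_gaps = c(0.47, 0.2, 0.2, 0.2),
                                     seed = NULL) {
  stopifnot(length(wave_gaps) == n_waves - 1)
  if (!is.null(seed)) set.seed(seed)
  lam <- measure_cor

  g <- rnorm(n)
  cols <- list()
  for (m in seq_len(n_measures))
    cols[[paste0("m", m, "_t1")]] <- sqrt(lam) * g + sqrt(1 - lam) * rnorm(n)

  # selection moments at the +/-1 s.d. threshold
  zgap <- 2 * dnorm(1) / pnorm(-1)
  vtrunc <- 1 + dnorm(1) / pnorm(-1) - (dnorm(1) / pnorm(-1))^2
  # baseline PC approximated by the measure mean
  r_pc_g <- sqrt(lam / (lam + (1 - lam) / n_measures))

  for (w in 2:n_waves) {
    d <- wave_gaps[w - 1]
    r <- sqrt(d^2 / (zgap^2 + (1 - vtrunc) * d^2))
    beta <- r / r_pc_g
    h <- rnorm(n) # shared wave factor keeps measures correlated
    for (m in seq_len(n_measures)) {
      eps <- sqrt(lam) * h + sqrt(1 - lam) * rnorm(n)
      cols[[paste0("m", m, "_t", w)]] <-
        beta * g + sqrt(1 - beta^2) * eps
    }
  }
  out <- data.frame(id = seq_len(n), cols, check.names = FALSE)
  # order columns measure-major to match the cohort dialect
  ord <- paste0(rep(paste0("m", seq_len(n_measures)), each = n_waves),
                "_t", rep(seq_len(n_waves), n_measures))
  out <- out[, c("id", ord)]
  attr(out, "truth") <- data.frame(id = seq_len(n), g = g)
  attr(out, "measures") <- paste0("m", seq_len(n_measures))
  attr(out, "n_waves") <- n_waves
  out
}
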