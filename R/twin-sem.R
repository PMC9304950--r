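# Wide pair layout for twin modelling: one row per family, columns are
# twin-1 waves then twin-2 waves; a twin without a row contributes NAs and
# is retained through FIML.
twin_wide <- function(cohort, measure, waves) {
  cols <- paste0(measure, "_t", waves)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("phenotype column(s) not found: ",
         paste(missing_cols, collapse = ", "))
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    sub <- cohort[cohort$zygosity == zyg, , drop = FALSE]
    fams <- unique(sub$family_id)
    y1 <- as.matrix(sub[match(fams, ifelse(sub$twin == 1L, sub$family_id,
                                           NA)), cols, drop = FALSE])
    y2 <- as.matrix(sub[match(fams, ifelse(sub$twin == 2L, sub$family_id,
                                           NA)), cols, drop = FALSE])
    m <- cbind(y1, y2)
    colnames(m) <- c(paste0("tw1_", cols), paste0("tw2_", cols))
    out[[zyg]] <- m
  }
  out
}

#' Intraclass twin correlations by zygosity
#'
#' Double-entry Pearson correlations between co-twins, per measure and wave,
#' separately for MZ and DZ pairs, with Fisher-z confidence intervals on the
#' pair count.
#'
#' @param cohort Cohort table (typically after [residualize()]).
#' @param measures,waves Optional subsets.
#' @param level Confidence level.
#' @return A data.frame: `measure`, `wave`, `zygosity`, `r`, `lower`,
#'   `upper`, `n_pairs`. Cells with fewer than 3 complete pairs are `NA`.
#' @export
twin_correlations <- function(cohort, measures = NULL, waves = NULL,
                              level = 0.95) {
  pc <- pheno_cols(cohort, measures, waves)
  de <- suppressMessages(double_enter(cohort))
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (m in pc$measures) for (w in pc$waves) {
    col <- paste0(m, "_t", w)
    for (zyg in c("MZ", "DZ")) {
      sub <- de[de$zygosity == zyg, c(col, paste0(col, "_cotwin"))]
      ok <- complete.cases(sub)
      n_pairs <- sum(ok) / 2
      r <- lo <- hi <- NA_real_
      if (n_pairs >= 3) {
        r <- cor(sub[ok, 1], sub[ok, 2])
        if (n_pairs > 3 && abs(r) < 1) {
          se <- 1 / sqrt(n_pairs - 3)
          lo <- tanh(atanh(r) - z * se)
          hi <- tanh(atanh(r) + z * se)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, wave = w, zygosity = zyg, r = r,
        lower = lo, upper = hi, n_pairs = n_pairs)
    }
  }
  do.call(rbind, rows)
}

#' Falconer moment estimates of ACE components
#'
#' The classical moment solution of the twin design:
#' `a2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`. Estimates are
#' returned unconstrained; values outside `[0, 1]` are flagged with a
#' warning, the constrained SEM estimates being the authoritative ones.
#'
#' @param rmz,rdz Intraclass correlations (vectors recycle).
#' @return A data.frame with columns `a2`, `c2`, `e2`.
#' @export
falconer <- function(rmz, rdz) {
  out <- data.frame(a2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz, e2 = 1 - rmz)
  if (any(out < 0 | out > 1, na.rm = TRUE))
    warning("Falconer estimate(s) outside [0, 1]; reported unconstrained")
  out
}

ace_cov_block <- function(s_a, s_c, s_e, rel) {
  within <- s_a + s_c + s_e
  cross <- rel * s_a + s_c
  rbind(cbind(within, cross), cbind(cross, within))
}

#' Fit the univariate ACE twin model
#'
#' Two-group (MZ/DZ) covariance-structure model at one measure-wave: path
#' coefficients a, c, e with implied within-pair covariance `a^2 + c^2` for
#' MZ and `0.5 a^2 + c^2` for DZ, a mean equated across twins and zygosity
#' groups, and full-information ML so pairs with one missing co-twin still
#' contribute. Standardized components are the squared paths over the total
#' variance, so they sum to 1 by construction.
#'
#' Confidence intervals are likelihood-based on the paths; the standardized
#' bounds divide the squared path bound by the fitted total variance (a
#' close approximation on standardized scores, where the total variance is
#' tightly determined).
#'
#' @param cohort Cohort table (after [residualize()]).
#' @param measure Measure name.
#' @param wave Wave number.
#' @param submodel `"ACE"` (default) or a nested `"AE"`, `"CE"`, `"E"`.
#' @param ci Compute profile confidence intervals for the components.
#' @param level Confidence level.
#' @param n_restarts,seed Passed to [fit_ml()].
#' @return An `"ace_fit"` list: `components` (standardized a2, c2, e2),
#'   `paths`, `ci` (3 x 2 matrix or NULL), `ci_censored`, `deviance`,
#'   `converged`, `n_pairs`, and the underlying `fit`.
#' @export
fit_univariate_ace <- function(cohort, measure, wave, submodel = "ACE",
                               ci = TRUE, level = 0.95,
                               n_restarts = 2, seed = 1) {
  submodel <- match.arg(submodel, c("ACE", "AE", "CE", "E"))
  data <- twin_wide(cohort, measure, wave)
  free <- c(a = grepl("A", submodel), c = grepl("C", submodel), e = TRUE)
  par_names <- c(names(free)[free], "mu")
  start <- c(c(a = 0.55, c = 0.3, e = 0.75)[free], mu = 0)

  implied <- function(theta) {
    th <- setNames(rep(0, 3), c("a", "c", "e"))
    th[names(free)[free]] <- theta[seq_len(sum(free))]
    mu <- theta[length(theta)]
    s_a <- th["a"]^2; s_c <- th["c"]^2; s_e <- th["e"]^2
    list(
      MZ = list(mean = rep(mu, 2),
                cov = ace_cov_block(s_a, s_c, s_e, 1)),
      DZ = list(mean = rep(mu, 2),
                cov = ace_cov_block(s_a, s_c, s_e, 0.5))
    )
  }
  model <- structured_model(
    par_names, start, implied,
    var_names = lapply(data, colnames),
    lower = c(rep(0, sum(free)), -10), upper = c(rep(10, sum(free)), 10))
  fit <- fit_ml(model, data, n_restarts = n_restarts, seed = seed)

  paths <- setNames(rep(0, 3), c("a", "c", "e"))
  paths[names(free)[free]] <- fit$estimates[seq_len(sum(free))]
  v <- sum(paths^2)
  comps <- setNames(paths^2 / v, c("a2", "c2", "e2"))

  ci_mat <- NULL; censored <- NULL
  if (ci) {
    ci_mat <- matrix(NA_real_, 3, 2,
                     dimnames = list(c("a2", "c2", "e2"),
                                     c("lower", "upper")))
    censored <- matrix(FALSE, 3, 2,
                       dimnames = dimnames(ci_mat))
    for (p in names(free)[free]) {
      pc_ <- profile_ci(fit, p, level)
      row <- paste0(p, "2")
      ci_mat[row, ] <- sort(c(pc_$lower, pc_$upper)^2 / v)
      censored[row, ] <- c(pc_$lower_censored, pc_$upper_censored)
    }
  }

  structure(list(
    measure = measure, wave = wave, submodel = submodel,
    components = comps, paths = paths, total_variance = v,
    ci = ci_mat, ci_censored = censored,
    deviance = fit$deviance, converged = fit$converged,
    n_pairs = fit$n, fit = fit
  ), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("<ace_fit> %s wave %s (%s): a2=%.3f c2=%.3f e2=%.3f  -2lnL=%.2f%s\n",
              x$measure, x$wave, x$submodel, x$components[1],
              x$components[2], x$components[3], x$deviance,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

# Shared builder for the multivariate two-group twin models. `component_cov`
# maps theta to the A, C, E covariance matrices (W x W) and the wave means.
multivariate_twin_fit <- function(cohort, measure, waves, par_names, start,
                                  lower, upper, component_cov,
                                  n_restarts, seed) {
  data <- twin_wide(cohort, measure, waves)
  implied <- function(theta) {
    cc <- component_cov(theta)
    list(
      MZ = list(mean = rep(cc$mu, 2),
                cov = ace_cov_block(cc$s_a, cc$s_c, cc$s_e, 1)),
      DZ = list(mean = rep(cc$mu, 2),
                cov = ace_cov_block(cc$s_a, cc$s_c, cc$s_e, 0.5))
    )
  }
  model <- structured_model(par_names, start, implied,
                            var_names = lapply(data, colnames),
                            lower = lower, upper = upper)
  fit_ml(model, data, n_restarts = n_restarts, seed = seed)
}

cov2cor_safe <- function(s) {
  d <- sqrt(pmax(diag(s), 1e-12))
  r <- s / tcrossprod(d)
  diag(r) <- 1
  r
}

#' Fit the multivariate correlated-factors twin model
#'
#' Joint two-group model over several waves of one measure, parameterized in
#' per-wave A, C, E paths and the cross-wave correlations of each factor:
#' the genetic correlation rG, shared-environmental rC and
#' nonshared-environmental rE. Cross-twin cross-wave covariances weight the
#' A terms by 1 (MZ) or 0.5 (DZ) and the C terms by 1.
#'
#' @inheritParams fit_univariate_ace
#' @param waves Wave numbers (>= 2).
#' @param ci Compute profile confidence intervals on the factor
#'   correlations (default only for bivariate fits, where it is cheap).
#' @return A `"corr_factors_fit"` list: `rG`, `rC`, `rE` (wave x wave
#'   matrices), `components` (per-wave standardized a2/c2/e2 matrix),
#'   `ci` (per-correlation intervals when requested), `deviance`,
#'   `converged`, and the underlying `fit`.
#' @export
fit_correlated_factors <- function(cohort, measure, waves,
                                   ci = length(waves) == 2, level = 0.95,
                                   n_restarts = 2, seed = 1) {
  w <- length(waves)
  if (w < 2) stop("need at least 2 waves")
  np <- w * (w - 1) / 2
  pair_idx <- which(upper.tri(matrix(0, w, w)), arr.ind = TRUE)

  par_names <- c(paste0("a", waves), paste0("c", waves), paste0("e", waves),
                 paste0("ra_", pair_idx[, 1], pair_idx[, 2]),
                 paste0("rc_", pair_idx[, 1], pair_idx[, 2]),
                 paste0("re_", pair_idx[, 1], pair_idx[, 2]),
                 paste0("mu", waves))
  start <- c(rep(0.55, w), rep(0.3, w), rep(0.75, w),
             rep(0.5, 3 * np), rep(0, w))
  lower <- c(rep(0, 3 * w), rep(-0.999, 3 * np), rep(-10, w))
  upper <- c(rep(10, 3 * w), rep(0.999, 3 * np), rep(10, w))

  build_corr <- function(rv) {
    m <- diag(w)
    m[cbind(pair_idx[, 1], pair_idx[, 2])] <- rv
    m[cbind(pair_idx[, 2], pair_idx[, 1])] <- rv
    m
  }
  component_cov <- function(theta) {
    a <- theta[seq_len(w)]
    c_ <- theta[w + seq_len(w)]
    e <- theta[2 * w + seq_len(w)]
    ra <- theta[3 * w + seq_len(np)]
    rc <- theta[3 * w + np + seq_len(np)]
    re <- theta[3 * w + 2 * np + seq_len(np)]
    mu <- theta[3 * w + 3 * np + seq_len(w)]
    list(s_a = tcrossprod(a) * build_corr(ra),
         s_c = tcrossprod(c_) * build_corr(rc),
         s_e = tcrossprod(e) * build_corr(re),
         mu = mu)
  }
  fit <- multivariate_twin_fit(cohort, measure, waves, par_names, start,
                               lower, upper, component_cov,
                               n_restarts, seed)

  cc <- component_cov(fit$estimates)
  tot <- diag(cc$s_a) + diag(cc$s_c) + diag(cc$s_e)
  comps <- cbind(a2 = diag(cc$s_a) / tot, c2 = diag(cc$s_c) / tot,
                 e2 = diag(cc$s_e) / tot)
  rownames(comps) <- paste0("t", waves)
  wl <- paste0("t", waves)
  dimn <- list(wl, wl)

  ci_list <- NULL
  if (ci) {
    ci_list <- list()
    for (p in grep("^r[ace]_", par_names, value = TRUE))
      ci_list[[p]] <- profile_ci(fit, p, level)
  }

  structure(list(
    measure = measure, waves = waves,
    rG = structure(cov2cor_safe(cc$s_a), dimnames = dimn),
    rC = structure(cov2cor_safe(cc$s_c), dimnames = dimn),
    rE = structure(cov2cor_safe(cc$s_e), dimnames = dimn),
    components = comps, ci = ci_list,
    deviance = fit$deviance, converged = fit$converged, fit = fit
  ), class = "corr_factors_fit")
}

#' @export
print.corr_factors_fit <- function(x, ...) {
  cat(sprintf("<corr_factors_fit> %s waves %s  -2lnL=%.2f%s\n",
              x$measure, paste(x$waves, collapse = ","), x$deviance,
              if (x$converged) "" else "  [NOT converged]"))
  cat("rG:\n"); print(round(x$rG, 3))
  cat("rE:\n"); print(round(x$rE, 3))
  invisible(x)
}

#' Fit the Cholesky (triangular) multivariate twin decomposition
#'
#' Likelihood-equivalent reparameterization of the correlated-factors model
#' in which each factor's covariance is a lower-triangular path matrix times
#' its transpose. The wave-specific ("innovation") proportion of, say,
#' genetic variance at wave w is the squared diagonal path over the total
#' genetic variance at that wave: the share of genetic variance independent
#' of all earlier waves.
#'
#' @inheritParams fit_correlated_factors
#' @return A `"cholesky_fit"` list: `L_A`, `L_C`, `L_E` (lower-triangular
#'   path matrices), `innovation` (wave x component matrix of innovation
#'   proportions), derived `rG`/`rC`/`rE`, `deviance`, `converged`, `fit`.
#' @export
fit_cholesky <- function(cohort, measure, waves, n_restarts = 2, seed = 1) {
  w <- length(waves)
  if (w < 2) stop("need at least 2 waves")
  tri <- which(lower.tri(matrix(0, w, w), diag = TRUE), arr.ind = TRUE)
  tri <- tri[order(tri[, 2], tri[, 1]), , drop = FALSE]
  ntri <- nrow(tri)
  lab <- paste0(tri[, 1], tri[, 2])

  par_names <- c(paste0("la_", lab), paste0("lc_", lab),
                 paste0("le_", lab), paste0("mu", waves))
  diag_par <- tri[, 1] == tri[, 2]
  start1 <- ifelse(diag_par, 0.5, 0.2)
  start <- c(start1 * 1.1, start1 * 0.5, start1 * 1.4, rep(0, w))
  # diagonal paths non-negative to identify the factors
  lower1 <- ifelse(diag_par, 0, -10)
  lower <- c(lower1, lower1, lower1, rep(-10, w))
  upper <- rep(10, length(par_names))

  build_l <- function(v) {
    l <- matrix(0, w, w)
    l[cbind(tri[, 1], tri[, 2])] <- v
    l
  }
  component_cov <- function(theta) {
    la <- build_l(theta[seq_len(ntri)])
    lc <- build_l(theta[ntri + seq_len(ntri)])
    le <- build_l(theta[2 * ntri + seq_len(ntri)])
    mu <- theta[3 * ntri + seq_len(w)]
    list(s_a = tcrossprod(la), s_c = tcrossprod(lc),
         s_e = tcrossprod(le), mu = mu)
  }
  fit <- multivariate_twin_fit(cohort, measure, waves, par_names, start,
                               lower, upper, component_cov,
                               n_restarts, seed)

  la <- build_l(fit$estimates[seq_len(ntri)])
  lc <- build_l(fit$estimates[ntri + seq_len(ntri)])
  le <- build_l(fit$estimates[2 * ntri + seq_len(ntri)])
  innov <- function(l) diag(l)^2 / pmax(rowSums(l^2), 1e-12)
  wl <- paste0("t", waves)
  dimn <- list(wl, wl)

  structure(list(
    measure = measure, waves = waves,
    L_A = structure(la, dimnames = dimn),
    L_C = structure(lc, dimnames = dimn),
    L_E = structure(le, dimnames = dimn),
    innovation = cbind(A = innov(la), C = innov(lc), E = innov(le)),
    rG = structure(cov2cor_safe(tcrossprod(la)), dimnames = dimn),
    rC = structure(cov2cor_safe(tcrossprod(lc)), dimnames = dimn),
    rE = structure(cov2cor_safe(tcrossprod(le)), dimnames = dimn),
    deviance = fit$deviance, converged = fit$converged, fit = fit
  ), class = "cholesky_fit")
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat(sprintf("<cholesky_fit> %s waves %s  -2lnL=%.2f%s\n",
              x$measure, paste(x$waves, collapse = ","), x$deviance,
              if (x$converged) "" else "  [NOT converged]"))
  cat("innovation proportions:\n")
  print(round(x$innovation, 3))
  invisible(x)
}
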