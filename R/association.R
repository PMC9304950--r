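#' General liability (p) factor by principal components
#'
#' First principal component of the column-standardized complete-case
#' matrix, the usual phenotypic or genomic general-psychopathology factor.
#' The loading sign is fixed so the mean loading is positive; scores are
#' standardized (mean 0, s.d. 1). Zero-variance columns are dropped with a
#' warning.
#'
#' @param scores Individuals x variables matrix or data.frame.
#' @return A `"p_factor"` list: `loadings` (unit-norm), `scores`
#'   (`NA` for incomplete rows), `var_explained` (first-component share),
#'   `n_complete`, `dropped` (removed column names).
#' @export
p_factor <- function(scores) {
  x <- as.matrix(scores)
  if (ncol(x) < 2) stop("need at least 2 variables")
  sds <- apply(x, 2, sd, na.rm = TRUE)
  dropped <- colnames(x)[!is.na(sds) & sds < 1e-12]
  if (length(dropped)) {
    warning("zero-variance column(s) dropped: ",
            paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  cc <- complete.cases(x)
  if (sum(cc) < ncol(x)) stop("fewer complete rows than variables")
  pc <- prcomp(x[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1]
  if (mean(load) < 0) load <- -load
  sc_cc <- as.numeric(scale(x[cc, , drop = FALSE]) %*% load)
  sc_cc <- as.numeric(scale(sc_cc))
  out <- rep(NA_real_, nrow(x))
  out[cc] <- sc_cc
  list(loadings = load,
       scores = out,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
       n_complete = sum(cc),
       dropped = dropped)
}

#' Incremental variance explained by a polygenic score
#'
#' Difference in R-squared between the covariates-only and the
#' covariates-plus-score ordinary least-squares models, on complete cases;
#' use one individual per family (see [select_one_per_pair()]) so rows are
#' unrelated. An optional permutation p-value shuffles the score residual
#' structure by permuting the GPS across individuals.
#'
#' @param pheno Numeric outcome vector.
#' @param gps Numeric polygenic-score vector.
#' @param covariates Optional matrix/data.frame of adjustment covariates
#'   (sex, age, ancestry PCs, batch, ...).
#' @param n_perm Number of permutations for the p-value (0 = none).
#' @param seed Seed for the permutations.
#' @return A list: `delta_r2`, `r2_base`, `r2_full`, `n`, and `p_perm`
#'   when requested.
#' @export
gps_regression <- function(pheno, gps, covariates = NULL, n_perm = 0,
                           seed = 1) {
  df <- data.frame(.y = pheno, .g = gps)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (v in names(covariates))
      if (is.character(covariates[[v]]))
        covariates[[v]] <- factor(covariates[[v]])
    df <- cbind(df, covariates)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  cov_terms <- if (is.null(covariates)) "1"
  else paste(names(covariates), collapse = " + ")
  f_base <- as.formula(paste(".y ~", cov_terms))
  f_full <- as.formula(paste(".y ~", cov_terms, "+ .g"))
  fit_base <- lm(f_base, data = df)
  if (!is.null(covariates) && fit_base$rank < length(coef(fit_base)))
    warning("collinear covariates; design is rank-deficient")
  fit_full <- lm(f_full, data = df)
  r2 <- function(f) 1 - sum(resid(f)^2) / sum((df$.y - mean(df$.y))^2)
  delta <- r2(fit_full) - r2(fit_base)

  out <- list(delta_r2 = delta, r2_base = r2(fit_base),
              r2_full = r2(fit_full), n = n)
  if (n_perm > 0) {
    set.seed(seed)
    perm <- replicate(n_perm, {
      dfp <- df
      dfp$.g <- sample(dfp$.g)
      r2(lm(f_full, data = dfp)) - out$r2_base
    })
    out$p_perm <- (1 + sum(perm >= delta)) / (n_perm + 1)
  }
  out
}

#' Extreme-group labels at a standard-deviation threshold
#'
#' Standardizes the scores and labels individuals strictly below
#' `-threshold_sd` as `"low"` and strictly above `+threshold_sd` as
#' `"high"`; the middle is `NA` and boundary values fall in the middle.
#'
#' @param scores Numeric vector.
#' @param threshold_sd Threshold in s.d. units.
#' @return A character vector (`"low"`, `"high"`, `NA`); an empty extreme
#'   group raises a warning.
#' @export
extreme_groups <- function(scores, threshold_sd = 1) {
  sdv <- sd(scores, na.rm = TRUE)
  if (!is.finite(sdv) || sdv < 1e-12) {
    warning("scores have no variance; both extreme groups empty")
    return(rep(NA_character_, length(scores)))
  }
  z <- (scores - mean(scores, na.rm = TRUE)) / sdv
  out <- rep(NA_character_, length(scores))
  out[z < -threshold_sd] <- "low"
  out[z > threshold_sd] <- "high"
  if (!any(out == "low", na.rm = TRUE) || !any(out == "high", na.rm = TRUE))
    warning("an extreme group is empty at threshold ", threshold_sd)
  out
}

#' Per-wave extreme-group contrast of a trajectory
#'
#' High-minus-low group means and Cohen's d at every wave, plus the
#' group-by-time repeated-measures MANOVA interaction (same machinery as
#' [rm_manova()], with group in place of sex).
#'
#' @param waves_data Individuals x waves matrix.
#' @param groups Labels from [extreme_groups()] (same length as rows).
#' @return An `"extreme_contrast"` list: `n` (group sizes), `means`
#'   (group x wave), `d` (per-wave high - low Cohen's d), `interaction`
#'   (MANOVA row for group:time).
#' @export
trajectory_contrast <- function(waves_data, groups) {
  y <- as.matrix(waves_data)
  stopifnot(length(groups) == nrow(y))
  keep <- !is.na(groups)
  if (!any(groups[keep] == "low") || !any(groups[keep] == "high"))
    stop("both extreme groups must be non-empty")
  y <- y[keep, , drop = FALSE]
  g <- factor(groups[keep], levels = c("low", "high"))

  means <- rbind(low = colMeans(y[g == "low", , drop = FALSE], na.rm = TRUE),
                 high = colMeans(y[g == "high", , drop = FALSE],
                                 na.rm = TRUE))
  d <- vapply(seq_len(ncol(y)), function(w)
    cohens_d(y[g == "low", w], y[g == "high", w]), numeric(1))
  names(d) <- colnames(y) %||% paste0("t", seq_len(ncol(y)))

  man <- rm_manova(y, sex = g)
  inter <- man[man$effect == "time:sex", ]
  inter$effect <- "group:time"

  structure(list(n = table(g), means = means, d = d,
                 interaction = inter),
            class = "extreme_contrast")
}

#' Correlation of a phenotype with an environmental composite
#'
#' Pearson correlation with a Fisher-z confidence interval on
#' pairwise-complete observations.
#'
#' @param pheno,env_composite Numeric vectors.
#' @param level Confidence level.
#' @return A list: `r`, `lower`, `upper`, `n`, `p_value`.
#' @export
environment_correlates <- function(pheno, env_composite, level = 0.95) {
  ok <- !is.na(pheno) & !is.na(env_composite)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(pheno[ok]) < 1e-12 || sd(env_composite[ok]) < 1e-12)
    stop("constant input; correlation undefined")
  ct <- cor.test(pheno[ok], env_composite[ok], conf.level = level)
  list(r = unname(ct$estimate),
       lower = ct$conf.int[1], upper = ct$conf.int[2],
       n = sum(ok), p_value = ct$p.value)
}

#' Compare a retained subsample against the full sample
#'
#' Per-variable means and standard deviations in the full and retained
#' samples with the standardized difference
#' `(mean_retained - mean_full) / sd_full`, the usual attrition-bias check.
#'
#' @param full Full cohort table.
#' @param retained Subset of `full` (rows with wave data retained).
#' @param variables Column names to compare.
#' @return A data.frame: `variable`, `n_full`, `n_retained`, `mean_full`,
#'   `mean_retained`, `sd_full`, `sd_retained`, `std_diff`.
#' @export
attrition_check <- function(full, retained, variables) {
  missing_v <- setdiff(variables, intersect(names(full), names(retained)))
  if (length(missing_v))
    stop("variable(s) not present in both tables: ",
         paste(missing_v, collapse = ", "))
  rows <- lapply(variables, function(v) {
    xf <- full[[v]][!is.na(full[[v]])]
    xr <- retained[[v]][!is.na(retained[[v]])]
    data.frame(variable = v, n_full = length(xf), n_retained = length(xr),
               mean_full = mean(xf), mean_retained = mean(xr),
               sd_full = sd(xf), sd_retained = sd(xr),
               std_diff = (mean(xr) - mean(xf)) / sd(xf))
  })
  do.call(rbind, rows)
}
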