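#' Residualize phenotypes on covariates and standardize
#'
#' For every measure-wave column, fits an ordinary least-squares regression
#' on the covariates over the non-missing rows, and replaces the column by
#' the standardized residuals (mean 0, s.d. 1 in the estimation sample).
#' Correcting for sex and age before twin modelling avoids inflating
#' shared-environment estimates, since co-twins share age exactly and MZ
#' co-twins share sex.
#'
#' Rows missing a covariate are excluded from the fit but still receive a
#' residual from the fitted model when the phenotype is observed. Missing
#' phenotype cells stay missing. A constant phenotype column is flagged with
#' a warning and returned as all-zero residuals.
#'
#' @param cohort Wide cohort table (see [simulate_cohort()]).
#' @param covariates Character vector of covariate column names.
#' @return The cohort with phenotype columns replaced by standardized
#'   residuals; class `"residualized"` is prepended.
#' @export
residualize <- function(cohort, covariates = c("sex", "age")) {
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "))
  pc <- pheno_cols(cohort)
  cov_df <- cohort[, covariates, drop = FALSE]
  for (v in covariates)
    if (is.character(cov_df[[v]])) cov_df[[v]] <- factor(cov_df[[v]])

  for (m in pc$measures) {
    for (w in pc$waves) {
      col <- paste0(m, "_t", w)
      y <- cohort[[col]]
      obs <- !is.na(y)
      if (sum(obs) < 3) {
        warning("fewer than 3 non-missing values in ", col,
                "; left unchanged")
        next
      }
      if (sd(y[obs]) < 1e-12) {
        warning("constant phenotype column ", col,
                "; residuals set to zero")
        cohort[[col]][obs] <- 0
        next
      }
      dat <- cbind(.y = y, cov_df)
      # drop covariates constant in the estimation sample to keep OLS
      # full-rank
      fit_rows <- obs & complete.cases(cov_df)
      keep <- vapply(covariates, function(v) {
        x <- dat[fit_rows, v]
        length(unique(x[!is.na(x)])) > 1
      }, logical(1))
      form <- if (any(keep))
        as.formula(paste(".y ~", paste(covariates[keep], collapse = " + ")))
      else .y ~ 1
      fit <- lm(form, data = dat[fit_rows, , drop = FALSE])
      pred <- rep(NA_real_, nrow(dat))
      pred_rows <- obs & (if (any(keep)) complete.cases(cov_df) else TRUE)
      pred[pred_rows] <- stats::predict(fit,
                                        newdata = dat[pred_rows, , drop = FALSE])
      res <- y - pred
      # phenotype observed but covariate missing: fall back to centring only
      res[obs & is.na(res)] <- y[obs & is.na(res)] - mean(y[fit_rows])
      mu <- mean(res[obs], na.rm = TRUE)
      sdv <- sd(res[obs], na.rm = TRUE)
      cohort[[col]] <- (res - mu) / sdv
    }
  }
  class(cohort) <- unique(c("residualized", class(cohort)))
  cohort
}

#' Select one twin per pair at random
#'
#' Yields a table of unrelated individuals by picking, reproducibly for a
#' given seed, one member of every family uniformly at random.
#'
#' @param cohort Cohort table.
#' @param seed Integer seed.
#' @return A `data.frame` with exactly one row per `family_id`.
#' @export
select_one_per_pair <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- unique(cohort$family_id)
  pick <- sample(c(1L, 2L), length(fams), replace = TRUE)
  keep <- cohort$twin == pick[match(cohort$family_id, fams)]
  # families represented by a single row fall back to that row
  one_row <- ave(seq_along(cohort$family_id), cohort$family_id,
                 FUN = length) == 1
  out <- cohort[keep | one_row, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Double-enter complete twin pairs
#'
#' Produces one record per ordered co-twin pair (each complete pair appears
#' twice with the roles swapped), the classical layout for intraclass
#' correlations. Families without both twin rows are dropped; their count is
#' reported via a message.
#'
#' @param cohort Cohort table.
#' @return A `data.frame` with columns `family_id`, `zygosity`, and for every
#'   phenotype column `x` the pair `x` (self) and `x_cotwin`.
#' @export
double_enter <- function(cohort) {
  t1 <- cohort[cohort$twin == 1L, , drop = FALSE]
  t2 <- cohort[cohort$twin == 2L, , drop = FALSE]
  common <- intersect(t1$family_id, t2$family_id)
  dropped <- length(unique(cohort$family_id)) - length(common)
  if (dropped > 0)
    message(dropped, " famil", if (dropped == 1) "y" else "ies",
            " without a complete pair dropped")
  t1 <- t1[match(common, t1$family_id), , drop = FALSE]
  t2 <- t2[match(common, t2$family_id), , drop = FALSE]

  pcols <- grep("_t[0-9]+$", names(cohort), value = TRUE)
  make <- function(self, co) {
    out <- data.frame(family_id = self$family_id,
                      zygosity = self$zygosity,
                      stringsAsFactors = FALSE)
    for (p in pcols) {
      out[[p]] <- self[[p]]
      out[[paste0(p, "_cotwin")]] <- co[[p]]
    }
    out
  }
  out <- rbind(make(t1, t2), make(t2, t1))
  rownames(out) <- NULL
  out
}
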