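#' Cohen's d between two observation samples
#'
#' Standardized mean difference `(mean(b) - mean(a)) / s_pooled`, with the
#' n-weighted pooled standard deviation. The two-sample form (rather than a
#' paired form) is used because wave samples are only partially overlapping
#' under attrition. Positive values mean an increase from `a` to `b`.
#'
#' @param sample_a,sample_b Numeric vectors; `NA`s dropped.
#' @return The standardized difference (scalar).
#' @export
#' @examples
#' cohens_d(rnorm(100), rnorm(100, mean = 0.3))
cohens_d <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 non-missing values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0)
    stop("pooled standard deviation is zero; d is undefined")
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Convert Cohen's d to proportion of variance
#'
#' Equal-group point-biserial conversion `d^2 / (d^2 + 4)`; a d of 0.35
#' corresponds to about 3% of variance.
#'
#' @param d Standardized difference(s).
#' @return Proportion(s) of variance in `[0, 1)`.
#' @export
d_to_variance <- function(d) {
  stopifnot(all(is.finite(d)))
  d^2 / (d^2 + 4)
}

#' Per-wave descriptives and change effect sizes
#'
#' @param cohort Wide cohort table.
#' @param measures Measures to summarize (default: all phenotype columns).
#' @return A list with `descriptives` (measure, wave, n, mean, sd, se) and
#'   `cohens_d` (measure, wave_a, wave_b, d) data frames.
#' @export
effect_table <- function(cohort, measures = NULL) {
  pc <- pheno_cols(cohort, measures)
  desc <- list(); dd <- list()
  for (m in pc$measures) {
    cols <- paste0(m, "_t", pc$waves)
    for (i in seq_along(pc$waves)) {
      y <- cohort[[cols[i]]]
      y <- y[!is.na(y)]
      desc[[length(desc) + 1]] <- data.frame(
        measure = m, wave = pc$waves[i], n = length(y),
        mean = mean(y), sd = sd(y), se = sd(y) / sqrt(length(y)))
    }
    for (i in seq_along(pc$waves)) for (j in seq_along(pc$waves)) {
      if (i >= j) next
      dd[[length(dd) + 1]] <- data.frame(
        measure = m, wave_a = pc$waves[i], wave_b = pc$waves[j],
        d = cohens_d(cohort[[cols[i]]], cohort[[cols[j]]]))
    }
  }
  list(descriptives = do.call(rbind, desc),
       cohens_d = do.call(rbind, dd))
}

# Wilks' lambda test with Rao's F approximation.
wilks_test <- function(H, E, q, df_e) {
  p <- nrow(E)
  lambda <- det(E) / det(E + H)
  lambda <- min(max(lambda, .Machine$double.eps), 1)
  s <- sqrt(ifelse(p^2 + q^2 - 5 > 0,
                   (p^2 * q^2 - 4) / (p^2 + q^2 - 5), 1))
  df1 <- p * q
  df2 <- s * (df_e - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  eta <- 1 - lambda^(1 / min(p, q))
  data.frame(wilks = lambda, F = f, df1 = df1, df2 = df2,
             p_value = pf(f, df1, df2, lower.tail = FALSE),
             partial_eta2 = eta)
}

#' Repeated-measures MANOVA on wave scores
#'
#' Multivariate tests of the within-person time effect, the between-person
#' sex effect, and the time-by-sex interaction, on complete-case rows. Time
#' and interaction are tested on within-person successive-difference
#' contrasts (Wilks' lambda with Rao's F approximation, effect-coded sex so
#' the time test targets the unweighted grand mean); the sex effect is the
#' univariate ANOVA on the per-person wave mean. Partial eta squared is
#' `1 - lambda^(1/s)` with `s = min(p, df_effect)`.
#'
#' @param data Numeric matrix or data.frame, individuals x waves.
#' @param sex Optional factor (2 levels) of the same length; when absent only
#'   the time effect is tested.
#' @return A data.frame of class `"rm_manova"`, one row per effect, with
#'   columns `effect`, `wilks`, `F`, `df1`, `df2`, `p_value`,
#'   `partial_eta2`; the number of dropped incomplete rows is in
#'   `attr(, "n_dropped")`.
#' @export
rm_manova <- function(data, sex = NULL) {
  y <- as.matrix(data)
  p_w <- ncol(y)
  if (p_w < 2) stop("need at least 2 waves")
  keep <- complete.cases(y)
  if (!is.null(sex)) keep <- keep & !is.na(sex)
  n_dropped <- sum(!keep)
  y <- y[keep, , drop = FALSE]
  sex <- if (!is.null(sex)) factor(sex[keep])
  if (!is.null(sex) && nlevels(sex) < 2) sex <- NULL
  n <- nrow(y)
  if (n < p_w + 2) stop("too few complete rows for the multivariate test")

  cmat <- diff(diag(p_w)) # successive-difference contrasts, (p-1) x p
  d <- y %*% t(cmat)
  p <- ncol(d)

  if (is.null(sex)) {
    x <- matrix(1, n, 1)
  } else {
    x <- cbind(1, ifelse(sex == levels(sex)[1], -0.5, 0.5))
  }
  xtx_inv <- solve(crossprod(x))
  b <- xtx_inv %*% crossprod(x, d)
  e_mat <- crossprod(d) - t(b) %*% crossprod(x) %*% b
  df_e <- n - ncol(x)
  if (qr(e_mat)$rank < p)
    stop("singular within-group covariance of wave contrasts (rank ",
         qr(e_mat)$rank, " < ", p, ")")

  test_l <- function(l) {
    lb <- l %*% b
    h <- t(lb) %*% solve(l %*% xtx_inv %*% t(l)) %*% lb
    wilks_test(h, e_mat, nrow(l), df_e)
  }

  out <- cbind(effect = "time", test_l(matrix(c(1, rep(0, ncol(x) - 1)), 1)))
  if (!is.null(sex)) {
    out <- rbind(out, cbind(effect = "time:sex",
                            test_l(matrix(c(0, 1), 1))))
    m <- rowMeans(y)
    fit <- aov(m ~ sex)
    ss <- summary(fit)[[1]]$`Sum Sq`
    lam <- ss[2] / sum(ss)
    fstat <- (ss[1] / 1) / (ss[2] / (n - 2))
    out <- rbind(out, data.frame(
      effect = "sex", wilks = lam, F = fstat, df1 = 1, df2 = n - 2,
      p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
      partial_eta2 = ss[1] / sum(ss)))
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("rm_manova", class(out))
  out
}

#' Cross-wave Pearson correlations with Fisher-z confidence intervals
#'
#' Pairwise-complete correlations between wave scores. Cells with fewer than
#' 3 complete pairs are reported as `NA`.
#'
#' @param data Numeric matrix or data.frame, individuals x waves.
#' @param level Confidence level.
#' @return A list of wave-by-wave matrices: `r`, `lower`, `upper`, `n`.
#' @export
crosswave_correlations <- function(data, level = 0.95) {
  y <- as.matrix(data)
  p <- ncol(y)
  r <- lo <- hi <- nn <- matrix(NA_real_, p, p)
  dimnames(r) <- dimnames(lo) <- dimnames(hi) <- dimnames(nn) <-
    list(colnames(y), colnames(y))
  z <- qnorm(1 - (1 - level) / 2)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ok <- !is.na(y[, i]) & !is.na(y[, j])
    nij <- sum(ok)
    nn[i, j] <- nij
    if (i == j) { r[i, j] <- 1; lo[i, j] <- 1; hi[i, j] <- 1; next }
    if (nij < 3) next
    rij <- cor(y[ok, i], y[ok, j])
    r[i, j] <- rij
    if (nij > 3 && abs(rij) < 1) {
      fz <- atanh(rij)
      se <- 1 / sqrt(nij - 3)
      lo[i, j] <- tanh(fz - z * se)
      hi[i, j] <- tanh(fz + z * se)
    }
  }
  list(r = r, lower = lo, upper = hi, n = nn)
}
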