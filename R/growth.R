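#' Default wave time codes
#'
#' Years since baseline for a five-wave design with a 2018 baseline and
#' pandemic assessments in April, July and October 2020 and March 2021.
#' @param n_waves Number of waves requested.
#' @return Numeric vector of time codes.
#' @export
default_time_codes <- function(n_waves = 5) {
  stopifnot(n_waves >= 1, n_waves <= 5)
  c(0, 2.0, 2.25, 2.5, 2.92)[seq_len(n_waves)]
}

lgc_model <- function(shape, time_codes, free_slope_var = TRUE) {
  w <- length(time_codes)
  q <- if (shape == "linear") 2L else 3L
  if (w < q + 1)
    stop("need at least ", q + 1, " waves for a ", shape, " growth model")
  lambda <- cbind(1, time_codes)
  if (q == 3) lambda <- cbind(lambda, time_codes^2)

  tri <- which(lower.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
  tri <- tri[order(tri[, 2], tri[, 1]), , drop = FALSE]
  if (!free_slope_var) tri <- tri[tri[, 1] == 1 & tri[, 2] == 1, ,
                                  drop = FALSE]
  ntri <- nrow(tri)
  diag_par <- tri[, 1] == tri[, 2]
  fe_names <- c("intercept", "slope", "quadratic")[seq_len(q)]
  par_names <- c(paste0("alpha_", fe_names),
                 paste0("psi_", tri[, 1], tri[, 2]),
                 paste0("theta", seq_len(w)))
  lower <- c(rep(-Inf, q), ifelse(diag_par, 0, -10), rep(0, w))
  upper <- c(rep(Inf, q), rep(10, ntri), rep(10, w))
  start <- c(rep(0, q), ifelse(diag_par, 0.5, 0.05), rep(0.7, w))

  implied <- function(theta) {
    alpha <- theta[seq_len(q)]
    l <- matrix(0, q, q)
    l[cbind(tri[, 1], tri[, 2])] <- theta[q + seq_len(ntri)]
    res <- theta[q + ntri + seq_len(w)]
    psi <- tcrossprod(l)
    list(list(mean = as.numeric(lambda %*% alpha),
              cov = lambda %*% psi %*% t(lambda) + diag(res^2, w)))
  }
  list(model = structured_model(par_names, start, implied,
                                var_names = list(paste0("t", seq_len(w))),
                                lower = lower, upper = upper),
       q = q, tri = tri, lambda = lambda)
}

#' Fit a latent growth curve model
#'
#' Intercept + slope (optionally + quadratic) random-coefficient model over
#' the waves, with factor loadings fixed to the time codes, freely
#' correlated growth factors, heteroscedastic per-wave residual variances,
#' and full-information maximum likelihood over missing waves. The
#' slope-variance likelihood-ratio test refits the model with all
#' slope-factor (co)variances fixed to zero.
#'
#' @param data Individuals x waves matrix (may contain `NA`).
#' @param shape `"linear"` or `"quadratic"`.
#' @param time_codes Numeric wave time codes (default
#'   [default_time_codes()], in years since baseline).
#' @param slope_lrt Run the slope-variance likelihood-ratio test.
#' @param n_restarts,seed Passed to [fit_ml()].
#' @return A `"lgc_fit"` list: `fixed` (growth-factor means), `psi`
#'   (growth-factor covariance matrix), `residual_variances`,
#'   `heywood` (waves whose residual variance was clamped at 0),
#'   `deviance`, `AIC`, `BIC`, `converged`, `slope_lrt`
#'   (statistic/df/p or NULL), and the underlying `fit`.
#' @export
fit_lgc <- function(data, shape = c("linear", "quadratic"),
                    time_codes = default_time_codes(ncol(data)),
                    slope_lrt = TRUE, n_restarts = 2, seed = 1) {
  shape <- match.arg(shape)
  y <- as.matrix(data)
  if (length(time_codes) != ncol(y))
    stop("time_codes must have one entry per wave")
  spec <- lgc_model(shape, time_codes)
  q <- spec$q

  # start the factor means at the OLS polynomial fit to the wave means
  wm <- colMeans(y, na.rm = TRUE)
  xg <- spec$lambda
  spec$model$start[seq_len(q)] <-
    as.numeric(solve(crossprod(xg), crossprod(xg, wm)))

  fit <- fit_ml(spec$model, y, n_restarts = n_restarts, seed = seed)
  est <- fit$estimates
  lmat <- matrix(0, q, q)
  lmat[cbind(spec$tri[, 1], spec$tri[, 2])] <-
    est[q + seq_len(nrow(spec$tri))]
  psi <- tcrossprod(lmat)
  fe_names <- c("intercept", "slope", "quadratic")[seq_len(q)]
  dimnames(psi) <- list(fe_names, fe_names)
  res <- est[q + nrow(spec$tri) + seq_len(ncol(y))]^2
  heywood <- which(res < 1e-10)

  slope_res <- NULL
  if (slope_lrt) {
    spec0 <- lgc_model(shape, time_codes, free_slope_var = FALSE)
    spec0$model$start[1:q] <- spec$model$start[1:q]
    fit0 <- fit_ml(spec0$model, y, n_restarts = n_restarts, seed = seed)
    slope_res <- lrt(fit, fit0)
  }

  structure(list(
    shape = shape, time_codes = time_codes,
    fixed = setNames(est[seq_len(q)], fe_names),
    psi = psi, residual_variances = res, heywood = heywood,
    deviance = fit$deviance, AIC = fit$AIC, BIC = fit$BIC,
    converged = fit$converged, slope_lrt = slope_res, fit = fit
  ), class = "lgc_fit")
}

#' @export
print.lgc_fit <- function(x, ...) {
  cat(sprintf("<lgc_fit> %s  -2lnL=%.2f  AIC=%.2f  BIC=%.2f%s\n",
              x$shape, x$deviance, x$AIC, x$BIC,
              if (x$converged) "" else "  [NOT converged]"))
  cat("fixed effects:\n"); print(round(x$fixed, 4))
  if (!is.null(x$slope_lrt))
    cat(sprintf("slope variance LRT: chi2(%d)=%.2f, p=%.3g\n",
                x$slope_lrt$df, x$slope_lrt$statistic,
                x$slope_lrt$p_value))
  invisible(x)
}

#' Compare linear and quadratic growth models
#'
#' @inheritParams fit_lgc
#' @return A list: `table` (shape, npar, deviance, AIC, BIC, preferred
#'   flags) and `lrt` (quadratic vs linear likelihood-ratio test), plus
#'   both fits.
#' @export
compare_growth <- function(data, time_codes = default_time_codes(ncol(data)),
                           n_restarts = 2, seed = 1) {
  lin <- fit_lgc(data, "linear", time_codes, slope_lrt = FALSE,
                 n_restarts = n_restarts, seed = seed)
  quad <- fit_lgc(data, "quadratic", time_codes, slope_lrt = FALSE,
                  n_restarts = n_restarts, seed = seed)
  tab <- data.frame(
    shape = c("linear", "quadratic"),
    npar = c(lin$fit$npar, quad$fit$npar),
    deviance = c(lin$deviance, quad$deviance),
    AIC = c(lin$AIC, quad$AIC),
    BIC = c(lin$BIC, quad$BIC))
  tab$preferred_AIC <- tab$AIC == min(tab$AIC)
  tab$preferred_BIC <- tab$BIC == min(tab$BIC)
  test <- lrt(quad$fit, lin$fit)
  list(table = tab, lrt = test, linear = lin, quadratic = quad)
}
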