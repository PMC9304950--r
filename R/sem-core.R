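#' Define a multigroup mean/covariance structured model
#'
#' The engine behind the twin and growth models: a named parameter vector
#' with box constraints and a map from parameters to the model-implied mean
#' vector and covariance matrix of each group. Fitted by full-information
#' maximum likelihood ([fit_ml()]), which handles arbitrary missingness
#' patterns row-wise.
#'
#' @param par_names Character vector of unique parameter names.
#' @param start Named (or positionally matched) start values.
#' @param lower,upper Box constraints (recycled).
#' @param implied `function(theta)` returning, per group, a
#'   `list(mean = <numeric p>, cov = <p x p matrix>)`; groups in a list.
#' @param var_names Observed-variable names, one character vector per group.
#' @return An object of class `"structured_model"`.
#' @export
structured_model <- function(par_names, start, implied, var_names,
                             lower = -Inf, upper = Inf) {
  stopifnot(!anyDuplicated(par_names), length(start) == length(par_names))
  structure(list(
    par_names = par_names,
    start = setNames(as.numeric(start), par_names),
    lower = rep_len(lower, length(par_names)),
    upper = rep_len(upper, length(par_names)),
    implied = implied,
    var_names = var_names
  ), class = "structured_model")
}

# Split a data matrix into missingness-pattern blocks. Rows with nothing
# observed are dropped (they contribute 0 to the likelihood).
split_patterns <- function(y) {
  y <- as.matrix(y)
  obs <- !is.na(y)
  key <- apply(obs, 1, function(m) paste(as.integer(m), collapse = ""))
  keep <- rowSums(obs) > 0
  pats <- list()
  for (k in unique(key[keep])) {
    rows <- which(key == k & keep)
    mask <- obs[rows[1], ]
    pats[[k]] <- list(mask = mask,
                      y = y[rows, mask, drop = FALSE],
                      n = length(rows))
  }
  attr(pats, "n_used") <- sum(keep)
  pats
}

dev_patterns <- function(imp, pats) {
  total <- 0
  for (p in pats) {
    mu <- imp$mean[p$mask]
    sg <- imp$cov[p$mask, p$mask, drop = FALSE]
    ch <- tryCatch(chol(sg), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    k <- length(mu)
    logdet <- 2 * sum(log(diag(ch)))
    z <- backsolve(ch, t(p$y) - mu, transpose = TRUE)
    quad <- colSums(z^2)
    total <- total + p$n * (k * log(2 * pi) + logdet) + sum(quad)
  }
  total
}

PENALTY <- 1e10

model_deviance <- function(model, theta, pattern_groups) {
  imp <- model$implied(theta)
  total <- 0
  for (g in seq_along(pattern_groups)) {
    d <- dev_patterns(imp[[g]], pattern_groups[[g]])
    if (is.na(d)) return(PENALTY) # non-PD implied covariance: reject
    total <- total + d
  }
  total
}

#' Full-information ML deviance of a structured model
#'
#' Minus twice the log-likelihood: the sum over rows of the multivariate
#' normal log-density restricted to each row's observed variables, grouped
#' by missingness pattern. All-missing rows contribute 0. A non-positive-
#' definite implied covariance for any pattern yields a large finite penalty
#' so optimizers back away from the inadmissible region.
#'
#' @param model A [structured_model()].
#' @param params Parameter vector (ordered as `model$par_names`).
#' @param data List of per-group data matrices (columns in the order of
#'   `model$var_names`), or a single matrix for one group.
#' @return The deviance (-2 log L), a scalar.
#' @export
fiml_deviance <- function(model, params, data) {
  if (is.matrix(data) || is.data.frame(data)) data <- list(data)
  pats <- lapply(data, split_patterns)
  model_deviance(model, as.numeric(params), pats)
}

#' Fit a structured model by maximum likelihood
#'
#' Quasi-Newton (L-BFGS-B) minimization of the FIML deviance from the
#' model's start values plus seeded jittered random restarts; the best
#' converged solution is kept and its numerical gradient norm checked.
#' Non-convergence is flagged, never silent.
#'
#' @inheritParams fiml_deviance
#' @param n_restarts Number of additional jittered starts.
#' @param seed Seed for the restart jitter.
#' @param reltol Relative deviance convergence tolerance.
#' @param grad_tol Gradient-norm threshold for the convergence flag.
#' @return A `"sem_fit"` list: `estimates`, `deviance` (-2 log L),
#'   `converged`, `gradient_norm`, `npar`, `n` (rows used per group),
#'   `n_patterns`, `AIC`, `BIC`, plus the model and pattern data for
#'   downstream profiling.
#' @export
fit_ml <- function(model, data, n_restarts = 5, seed = 1,
                   reltol = 1e-10, grad_tol = 1e-3) {
  if (is.matrix(data) || is.data.frame(data)) data <- list(data)
  pats <- lapply(data, split_patterns)
  npar <- length(model$par_names)

  fn <- function(theta) model_deviance(model, theta, pats)

  starts <- list(model$start)
  if (n_restarts > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    for (i in seq_len(n_restarts)) {
      jit <- model$start * (1 + 0.3 * rnorm(npar)) + 0.1 * rnorm(npar)
      starts[[i + 1]] <- pmin(pmax(jit, model$lower + 1e-6),
                              model$upper - 1e-6)
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, fn, method = "L-BFGS-B",
            lower = model$lower, upper = model$upper,
            control = list(maxit = 1000, factr = reltol / 1e-15)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= PENALTY / 2)
    stop("optimization failed from all starts")

  theta <- setNames(best$par, model$par_names)
  # numerical gradient (central differences, respecting bounds)
  h <- pmax(1e-5, abs(theta) * 1e-5)
  grad <- vapply(seq_len(npar), function(i) {
    tp <- tm <- theta
    tp[i] <- min(theta[i] + h[i], model$upper[i])
    tm[i] <- max(theta[i] - h[i], model$lower[i])
    if (tp[i] == tm[i]) return(0)
    (fn(tp) - fn(tm)) / (tp[i] - tm[i])
  }, numeric(1))
  at_bound <- theta <= model$lower + 1e-8 | theta >= model$upper - 1e-8
  gnorm <- sqrt(sum(grad[!at_bound]^2))
  n_used <- vapply(pats, function(p) attr(p, "n_used"), numeric(1))

  structure(list(
    estimates = theta,
    deviance = best$value,
    converged = best$convergence == 0 && gnorm < grad_tol * max(1, n_used),
    gradient_norm = gnorm,
    npar = npar,
    n = n_used,
    n_patterns = vapply(pats, length, integer(1)),
    AIC = best$value + 2 * npar,
    BIC = best$value + npar * log(sum(n_used)),
    model = model,
    patterns = pats
  ), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> -2lnL =", format(x$deviance, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$estimates, 4))
  invisible(x)
}

profile_deviance <- function(fit, param, value) {
  model <- fit$model
  i <- match(param, model$par_names)
  free <- setdiff(seq_along(model$par_names), i)
  if (!length(free)) {
    theta <- fit$estimates
    theta[i] <- value
    return(model_deviance(model, theta, fit$patterns))
  }
  fn <- function(th_free) {
    theta <- numeric(length(model$par_names))
    theta[free] <- th_free
    theta[i] <- value
    model_deviance(model, theta, fit$patterns)
  }
  start <- fit$estimates[free]
  opt <- optim(start, fn, method = "L-BFGS-B",
               lower = model$lower[free], upper = model$upper[free],
               control = list(maxit = 500))
  opt$value
}

#' Likelihood-based (profile) confidence interval
#'
#' Bounds where the profile deviance rises by the chi-square(1) quantile
#' above its minimum, located by root finding between the estimate and each
#' box constraint. A bound whose constraint is reached before the deviance
#' threshold is reported at the constraint and flagged boundary-censored.
#'
#' @param fit A converged [fit_ml()] result.
#' @param param Parameter name.
#' @param level Confidence level (0 gives a degenerate interval).
#' @return A list: `lower`, `upper`, `level`, and logical
#'   `lower_censored` / `upper_censored`.
#' @export
profile_ci <- function(fit, param, level = 0.95) {
  stopifnot(inherits(fit, "sem_fit"))
  i <- match(param, fit$model$par_names)
  if (is.na(i)) stop("unknown parameter: ", param)
  est <- fit$estimates[[i]]
  if (level <= 0)
    return(list(lower = est, upper = est, level = level,
                lower_censored = FALSE, upper_censored = FALSE))
  thresh <- fit$deviance + qchisq(level, 1)
  f <- function(v) profile_deviance(fit, param, v) - thresh

  bound_search <- function(direction) {
    box <- if (direction < 0) fit$model$lower[i] else fit$model$upper[i]
    if (!is.finite(box)) { # expand until the deviance threshold is crossed
      step <- max(abs(est), 0.5)
      v <- est
      for (j in 1:40) {
        v <- v + direction * step
        step <- step * 1.6
        if (f(v) > 0) { box <- v; break }
      }
      if (!is.finite(box))
        return(list(value = direction * Inf, censored = TRUE))
    }
    if (f(box) <= 0) return(list(value = box, censored = TRUE))
    root <- uniroot(f, sort(c(est, box)), tol = 1e-4)$root
    list(value = root, censored = FALSE)
  }
  lo <- bound_search(-1)
  hi <- bound_search(1)
  list(lower = lo$value, upper = hi$value, level = level,
       lower_censored = lo$censored, upper_censored = hi$censored)
}

#' Likelihood-ratio test of nested structured models
#'
#' @param full,nested Fits from [fit_ml()]; `nested` must be a constrained
#'   version of `full`.
#' @param df Difference in free parameters (default inferred).
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, nested, df = nested_df(full, nested)) {
  stat <- nested$deviance - full$deviance
  if (stat < -1e-4 * max(1, abs(full$deviance)))
    stop("nested model fits better than the full model by ",
         format(-stat), "; a fit failed")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Saturated multivariate-normal model
#'
#' Free mean vector and unstructured covariance (parameterized by its
#' Cholesky factor, so positivity holds by construction) for a single group.
#' Useful as the unrestricted reference model and for FIML estimation of
#' sample moments under missingness.
#'
#' @param var_names Observed-variable names.
#' @return A [structured_model()].
#' @export
saturated_model <- function(var_names) {
  p <- length(var_names)
  tri <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  tri <- tri[order(tri[, 2], tri[, 1]), , drop = FALSE]
  diag_par <- tri[, 1] == tri[, 2]
  par_names <- c(paste0("mu", seq_len(p)),
                 paste0("l_", tri[, 1], "_", tri[, 2]))
  start <- c(rep(0, p), ifelse(diag_par, 1, 0))
  lower <- c(rep(-Inf, p), ifelse(diag_par, 1e-6, -Inf))
  implied <- function(theta) {
    mu <- theta[seq_len(p)]
    l <- matrix(0, p, p)
    l[cbind(tri[, 1], tri[, 2])] <- theta[p + seq_len(nrow(tri))]
    list(list(mean = mu, cov = tcrossprod(l)))
  }
  structured_model(par_names, start, implied,
                   var_names = list(var_names),
                   lower = lower, upper = Inf)
}

nested_df <- function(full, nested) {
  d <- full$npar - nested$npar
  if (d <= 0) stop("'full' must have more free parameters than 'nested'")
  d
}
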