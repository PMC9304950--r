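#' Single stochastic imputation of missing waves
#'
#' Estimates the multivariate-normal mean and covariance of the wave scores
#' by full-information maximum likelihood, then draws each row's missing
#' cells once from their conditional normal distribution given the row's
#' observed cells. Performed once before fitting all class counts, so every
#' mixture model sees the same completed matrix.
#'
#' @param data Individuals x waves matrix with `NA`s; every row must have at
#'   least one observed wave.
#' @param seed Integer seed for the conditional draws.
#' @return The completed numeric matrix.
#' @export
impute_single <- function(data, seed = NULL) {
  y <- as.matrix(data)
  if (!anyNA(y)) return(y)
  all_miss <- which(rowSums(!is.na(y)) == 0)
  if (length(all_miss))
    stop("row(s) with no observed wave: ",
         paste(head(all_miss, 5), collapse = ", "))
  p <- ncol(y)
  cn <- colnames(y) %||% paste0("w", seq_len(p))

  sat <- saturated_model(cn)
  fit <- fit_ml(sat, y, n_restarts = 0)
  imp <- sat$implied(fit$estimates)[[1]]
  mu <- imp$mean
  sigma <- imp$cov

  if (!is.null(seed)) set.seed(seed)
  obs <- !is.na(y)
  key <- apply(obs, 1, function(m) paste(as.integer(m), collapse = ""))
  for (k in unique(key)) {
    rows <- which(key == k)
    mask <- obs[rows[1], ]
    if (all(mask)) next
    m_obs <- which(mask); m_mis <- which(!mask)
    s_oo_inv <- solve(sigma[m_obs, m_obs, drop = FALSE])
    s_mo <- sigma[m_mis, m_obs, drop = FALSE]
    cond_cov <- sigma[m_mis, m_mis, drop = FALSE] -
      s_mo %*% s_oo_inv %*% t(s_mo)
    ch <- chol((cond_cov + t(cond_cov)) / 2)
    resid_obs <- t(y[rows, m_obs, drop = FALSE]) - mu[m_obs]
    cond_mean <- mu[m_mis] + s_mo %*% s_oo_inv %*% resid_obs
    z <- matrix(rnorm(length(m_mis) * length(rows)), length(m_mis))
    y[rows, m_mis] <- t(cond_mean + t(ch) %*% z)
  }
  y
}

lpa_loglik_parts <- function(y, pi_k, mu, sigma2) {
  n <- nrow(y); k <- length(pi_k)
  ll <- matrix(0, n, k)
  sdw <- sqrt(sigma2)
  for (j in seq_len(k)) {
    lj <- 0
    for (w in seq_len(ncol(y)))
      lj <- lj + dnorm(y[, w], mu[j, w], sdw[w], log = TRUE)
    ll[, j] <- log(pi_k[j]) + lj
  }
  ll
}

lpa_em <- function(y, k, init_mu, tol = 1e-8, max_iter = 500) {
  n <- nrow(y); w <- ncol(y)
  mu <- init_mu
  pi_k <- rep(1 / k, k)
  sigma2 <- apply(y, 2, var) # start at marginal variances
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- lpa_loglik_parts(y, pi_k, mu, sigma2)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(lp - lse)
    nk <- colSums(r)
    if (any(nk < 1)) return(list(degenerate = TRUE))
    pi_k <- nk / n
    mu <- (t(r) %*% y) / nk
    sigma2 <- vapply(seq_len(w), function(ww)
      sum(r * outer(y[, ww], mu[, ww], `-`)^2) / n, numeric(1))
    sigma2 <- pmax(sigma2, 1e-10)
    if (is.finite(ll_old) && ll - ll_old < tol * max(1, abs(ll))) break
    ll_old <- ll
  }
  list(degenerate = FALSE, loglik = ll, trace = trace,
       pi = pi_k, mu = mu, sigma2 = sigma2, posterior = r)
}

#' Fit a longitudinal latent profile model
#'
#' Gaussian mixture over the wave scores with diagonal covariance,
#' class-equated (but wave-specific) variances, fitted by EM from seeded
#' k-means initializations; the best of `n_restarts` converged runs by final
#' log-likelihood is returned. Classes are canonically ordered by their
#' wave-1 mean. Runs that collapse a class below one expected member are
#' discarded and restarted; persistent degeneracy errors.
#'
#' @param data Completed individuals x waves matrix (see [impute_single()]).
#' @param k Number of latent classes (>= 1).
#' @param seed Integer seed for initialization.
#' @param n_restarts Number of k-means-initialized EM runs.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per run.
#' @return An `"lpa_fit"` list: `k`, `prop` (mixing proportions), `mu`
#'   (k x waves class means), `sigma2` (per-wave shared variances),
#'   `loglik`, `loglik_trace`, `npar`, `BIC`, `AIC`, `entropy`,
#'   `posterior` (n x k).
#' @export
fit_lpa <- function(data, k, seed = 1, n_restarts = 20,
                    tol = 1e-8, max_iter = 500) {
  y <- as.matrix(data)
  if (anyNA(y)) stop("matrix has missing cells; run impute_single() first")
  n <- nrow(y); w <- ncol(y)
  if (k < 1) stop("k must be >= 1")
  if (n <= k * w) stop("too few rows for ", k, " classes")

  if (k == 1) {
    mu <- matrix(colMeans(y), 1)
    sigma2 <- apply(y, 2, function(x) mean((x - mean(x))^2))
    ll <- sum(vapply(seq_len(w), function(ww)
      sum(dnorm(y[, ww], mu[1, ww], sqrt(sigma2[ww]), log = TRUE)),
      numeric(1)))
    best <- list(loglik = ll, trace = ll, pi = 1, mu = mu,
                 sigma2 = sigma2, posterior = matrix(1, n, 1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    best <- NULL
    n_degenerate <- 0
    for (r in seq_len(n_restarts)) {
      km <- suppressWarnings(kmeans(y, centers = k, nstart = 1,
                                    iter.max = 50))
      res <- lpa_em(y, k, init_mu = km$centers, tol = tol,
                    max_iter = max_iter)
      if (res$degenerate) { n_degenerate <- n_degenerate + 1; next }
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    if (is.null(best))
      stop("all ", n_restarts, " EM runs degenerated; k = ", k,
           " is too large for these data")
    if (n_degenerate > 0)
      attr(best, "n_degenerate") <- n_degenerate
  }

  ord <- order(best$mu[, 1])
  prop <- best$pi[ord]
  mu <- best$mu[ord, , drop = FALSE]
  post <- best$posterior[, ord, drop = FALSE]
  npar <- k * w + w + (k - 1)
  ent <- if (k == 1) 1 else {
    pl <- post * log(pmax(post, 1e-300))
    1 - sum(-pl) / (n * log(k))
  }
  structure(list(
    k = k, prop = prop, mu = mu, sigma2 = best$sigma2,
    loglik = best$loglik, loglik_trace = best$trace,
    npar = npar,
    BIC = -2 * best$loglik + npar * log(n),
    AIC = -2 * best$loglik + 2 * npar,
    entropy = ent, posterior = post, n = n
  ), class = "lpa_fit")
}

#' @export
print.lpa_fit <- function(x, ...) {
  cat(sprintf("<lpa_fit> k=%d  logLik=%.2f  BIC=%.2f  entropy=%.3f\n",
              x$k, x$loglik, x$BIC, x$entropy))
  cat("mixing proportions:", paste(sprintf("%.3f", x$prop),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Compare latent profile models and select the class count
#'
#' @param models List of [fit_lpa()] results over different `k`.
#' @return A list: `table` (k, loglik, npar, BIC, AIC, entropy, best flag)
#'   and `best` (the lowest-BIC model; ties broken by the smaller k).
#' @export
select_k <- function(models) {
  if (length(models) < 2) stop("need at least 2 fitted models")
  tab <- do.call(rbind, lapply(models, function(m) data.frame(
    k = m$k, loglik = m$loglik, npar = m$npar,
    BIC = m$BIC, AIC = m$AIC, entropy = m$entropy)))
  tab <- tab[order(tab$k), ]
  rownames(tab) <- NULL
  models <- models[order(vapply(models, `[[`, numeric(1), "k"))]
  best_i <- which.min(tab$BIC) # order() put smaller k first: ties -> low k
  tab$best <- seq_len(nrow(tab)) == best_i
  list(table = tab, best = models[[best_i]])
}

#' Modal class assignment and empirical class shares
#'
#' @param model A [fit_lpa()] result.
#' @return A list: `labels` (modal posterior class per individual),
#'   `empirical_prop` (modal shares), `model_prop` (mixing proportions).
#' @export
assign_profiles <- function(model) {
  labels <- max.col(model$posterior, ties.method = "first")
  emp <- tabulate(labels, nbins = model$k) / model$n
  list(labels = labels, empirical_prop = emp, model_prop = model$prop)
}
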