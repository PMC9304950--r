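#' Compound-symmetric correlation matrix
#'
#' Convenience constructor for the equicorrelation matrices used to describe
#' cross-wave structure of the latent A, C and E factors.
#'
#' @param n Matrix dimension (number of waves).
#' @param rho Common off-diagonal correlation.
#' @return An `n` x `n` correlation matrix.
#' @export
#' @examples
#' cs_corr(3, 0.5)
cs_corr <- function(n, rho) {
  stopifnot(n >= 1, rho > -1 / (n - 1 + (n == 1)), rho <= 1)
  m <- matrix(rho, n, n)
  diag(m) <- 1
  m
}

#' Simulation configuration for a synthetic twin cohort
#'
#' Defines the generating model for [simulate_cohort()]: pair counts,
#' per-wave ACE variance proportions, cross-wave correlation matrices of the
#' additive-genetic (A), shared-environmental (C) and nonshared-environmental
#' (E) factors, mean structure (wave shifts and a sex difference), and
#' optional latent trajectory classes, attrition and polygenic scores.
#'
#' Defaults emulate a five-wave young-adult mental-health assessment:
#' 1501 monozygotic and 2380 dizygotic complete pairs, standardized variance
#' components (a2, c2, e2) = (0.33, 0.07, 0.60) at every wave, near-unit
#' cross-wave genetic correlations (0.95), moderate nonshared-environmental
#' cross-wave correlations (0.41), a mean elevation of 0.14 s.d. from wave 2
#' onward, and a sex mean difference of 0.35 s.d.
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of complete MZ / DZ twin pairs.
#' @param n_waves Number of measurement waves.
#' @param measures Character vector of phenotype names.
#' @param ace Length-3 vector `c(a2, c2, e2)` applied to every wave, or an
#'   `n_waves` x 3 matrix for wave-specific components. Must sum to 1 per
#'   wave.
#' @param corr_a,corr_c,corr_e Cross-wave correlation matrices
#'   (`n_waves` x `n_waves`) of the latent A, C and E factors. Must be
#'   symmetric, unit-diagonal and positive semi-definite.
#' @param measure_cor Cross-measure correlation of the latent factors
#'   (compound symmetric across measures, applied at all three levels), so
#'   phenotypes intercorrelate as mental-health symptom scales do.
#' @param wave_shifts Numeric vector of per-wave mean shifts in baseline-s.d.
#'   units (length `n_waves`).
#' @param sex_effect Mean difference (female minus male) in s.d. units,
#'   applied symmetrically about zero.
#' @param age_range Length-2 vector; ages drawn uniformly within it.
#' @param profiles Optional latent-class spec:
#'   `list(proportions = <k>, offsets = <k x n_waves matrix>)`, mean offsets
#'   in s.d. units. Proportions must sum to 1.
#' @param attrition Optional spec `list(retention = <n_waves vector in (0,1]>,
#'   mechanism = "MCAR"|"MAR", mar_slope = <logit slope>)`. Wave 1 retention
#'   must be 1; the MAR mechanism lowers retention for high baseline scorers
#'   when `mar_slope > 0`.
#' @param gps Optional polygenic-score spec: a list of
#'   `list(name = <chr>, cor = <correlation with the baseline A factor>)`.
#' @param skew If `TRUE`, phenotypes are passed through an exponential
#'   transform (then re-centred) to emulate skewed symptom scales. Off by
#'   default; analyses of untransformed scores are the primary surface.
#' @param seed Optional integer seed recorded in the config and used by
#'   [simulate_cohort()].
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_mz_pairs = 1501,
                       n_dz_pairs = 2380,
                       n_waves = 5,
                       measures = c("conduct", "emotional", "hyperactivity",
                                    "peer", "prosocial", "anxiety",
                                    "depression", "selfharm"),
                       ace = c(a2 = 0.33, c2 = 0.07, e2 = 0.60),
                       corr_a = cs_corr(n_waves, 0.95),
                       corr_c = cs_corr(n_waves, 0.90),
                       corr_e = cs_corr(n_waves, 0.41),
                       measure_cor = 0.40,
                       wave_shifts = c(0, rep(0.14, n_waves - 1)),
                       sex_effect = 0.35,
                       age_range = c(21, 25),
                       profiles = NULL,
                       attrition = NULL,
                       gps = NULL,
                       skew = FALSE,
                       seed = NULL) {
  if (n_mz_pairs < 1 || n_dz_pairs < 1)
    stop("need at least one pair of each zygosity")
  if (n_waves < 1) stop("n_waves must be >= 1")
  measures <- as.character(measures)
  if (anyDuplicated(measures)) stop("duplicate measure names")

  if (is.matrix(ace)) {
    if (nrow(ace) != n_waves || ncol(ace) != 3)
      stop("'ace' matrix must be n_waves x 3")
  } else {
    if (length(ace) != 3) stop("'ace' must have 3 elements (a2, c2, e2)")
    ace <- matrix(rep(as.numeric(ace), each = n_waves), n_waves, 3)
  }
  colnames(ace) <- c("a2", "c2", "e2")
  if (any(ace < 0)) stop("variance proportions must be non-negative")
  bad <- which(abs(rowSums(ace) - 1) > 1e-8)
  if (length(bad))
    stop("a2 + c2 + e2 must equal 1 at every wave (violated at wave ",
         bad[1], ")")

  check_corr <- function(m, name) {
    if (!is.matrix(m) || nrow(m) != n_waves || ncol(m) != n_waves)
      stop(sprintf("'%s' must be a %d x %d matrix", name, n_waves, n_waves))
    if (max(abs(m - t(m))) > 1e-10)
      stop(sprintf("'%s' is not symmetric", name))
    if (max(abs(diag(m) - 1)) > 1e-10)
      stop(sprintf("'%s' must have unit diagonal", name))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf("'%s' is not positive semi-definite", name))
    m
  }
  corr_a <- check_corr(corr_a, "corr_a")
  corr_c <- check_corr(corr_c, "corr_c")
  corr_e <- check_corr(corr_e, "corr_e")

  n_meas <- length(measures)
  if (n_meas > 1 &&
      (measure_cor < -1 / (n_meas - 1) + 1e-12 || measure_cor > 1))
    stop("'measure_cor' out of the admissible equicorrelation range")
  if (length(wave_shifts) != n_waves)
    stop("'wave_shifts' must have length n_waves")

  if (!is.null(profiles)) {
    if (is.null(profiles$proportions) || is.null(profiles$offsets))
      stop("'profiles' needs $proportions and $offsets")
    profiles$offsets <- as.matrix(profiles$offsets)
    if (abs(sum(profiles$proportions) - 1) > 1e-8)
      stop("profile mixing proportions must sum to 1")
    if (ncol(profiles$offsets) != n_waves)
      stop("profile offset vectors must have length n_waves")
    if (nrow(profiles$offsets) != length(profiles$proportions))
      stop("one offset row per profile class required")
  }

  if (!is.null(attrition)) {
    ret <- attrition$retention
    if (is.null(ret) || length(ret) != n_waves)
      stop("'attrition$retention' must have length n_waves")
    if (any(ret <= 0) || any(ret > 1))
      stop("retention probabilities must lie in (0, 1]")
    if (ret[1] != 1)
      stop("baseline (wave 1) retention must be 1; baseline is never deleted")
    attrition$mechanism <- match.arg(attrition$mechanism %||% "MCAR",
                                     c("MCAR", "MAR"))
    attrition$mar_slope <- attrition$mar_slope %||% 1
  }

  if (!is.null(gps)) {
    for (g in gps) {
      if (is.null(g$name) || is.null(g$cor))
        stop("each gps entry needs $name and $cor")
      if (abs(g$cor) >= 1)
        stop("|gps correlation| must be < 1 (got ", g$cor, ")")
    }
  }

  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs),
    n_dz_pairs = as.integer(n_dz_pairs),
    n_waves = as.integer(n_waves),
    measures = measures,
    ace = ace,
    corr_a = corr_a, corr_c = corr_c, corr_e = corr_e,
    measure_cor = measure_cor,
    wave_shifts = wave_shifts,
    sex_effect = sex_effect,
    age_range = age_range,
    profiles = profiles,
    attrition = attrition,
    gps = gps,
    skew = isTRUE(skew),
    seed = if (!is.null(seed)) as.integer(seed) else NULL
  ), class = "sim_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  pairs: %d MZ + %d DZ; waves: %d; measures: %d\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_waves, length(x$measures)))
  cat(sprintf("  mean ACE: a2=%.2f c2=%.2f e2=%.2f\n",
              mean(x$ace[, 1]), mean(x$ace[, 2]), mean(x$ace[, 3])))
  cat(sprintf("  classes: %s; attrition: %s; gps: %d\n",
              if (is.null(x$profiles)) "none"
              else length(x$profiles$proportions),
              if (is.null(x$attrition)) "none" else x$attrition$mechanism,
              length(x$gps)))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Plain-text round-trip for [sim_config()]. Matrices may be given either in
#' full or as `{rho: <value>}` shorthand for a compound-symmetric matrix.
#'
#' @param path YAML file path.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  nw <- y$n_waves %||% 5
  as_corr <- function(v) {
    if (is.null(v)) return(NULL)
    if (!is.null(v$rho)) return(cs_corr(nw, v$rho))
    do.call(rbind, v)
  }
  args <- list(
    n_mz_pairs = y$n_mz_pairs %||% 1501,
    n_dz_pairs = y$n_dz_pairs %||% 2380,
    n_waves = nw,
    seed = y$seed
  )
  if (!is.null(y$measures)) args$measures <- unlist(y$measures)
  if (!is.null(y$ace)) args$ace <- unlist(y$ace)
  for (nm in c("corr_a", "corr_c", "corr_e"))
    if (!is.null(y[[nm]])) args[[nm]] <- as_corr(y[[nm]])
  for (nm in c("measure_cor", "wave_shifts", "sex_effect", "age_range",
               "skew"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$profiles))
    args$profiles <- list(proportions = unlist(y$profiles$proportions),
                          offsets = do.call(rbind, y$profiles$offsets))
  if (!is.null(y$attrition))
    args$attrition <- list(retention = unlist(y$attrition$retention),
                           mechanism = y$attrition$mechanism %||% "MCAR",
                           mar_slope = y$attrition$mar_slope %||% 1)
  if (!is.null(y$gps)) args$gps <- y$gps
  do.call(sim_config, args)
}
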