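PIPELINE_STAGES <- c("simulate", "preprocess", "describe", "ace", "rg",
                     "cholesky", "lpa", "lgc", "pfactor", "gps",
                     "extremes", "envcor")

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> analyses on a configuration, and
#' writes per-stage CSV/JSON artifacts plus a single machine-readable
#' `summary.json` to the output directory. Model-based stages (twin models,
#' LPA, growth) run on `measures` (default: the first configured measure);
#' descriptives cover every measure. Any stage failure is recorded, its
#' dependents are skipped, and the bundle's `$errors` reports it.
#'
#' @param config A [sim_config()], or a cohort CSV path to analyse.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages Subset of stages to run (unknown names are rejected before
#'   execution).
#' @param measures Measures for the model-based stages.
#' @param lpa_k Class counts scanned by the LPA stage.
#' @return Invisibly, a list with one element per executed stage, plus
#'   `$log` (seeds, config hash) and `$errors`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1,
                         stages = PIPELINE_STAGES,
                         measures = NULL, lpa_k = 2:4) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  res <- list(errors = list())
  run_stage <- function(name, needs, expr) {
    if (!(name %in% stages)) return(invisible(NULL))
    for (dep in needs) if (is.null(res[[dep]])) {
      res$errors[[name]] <<- paste("skipped: stage", dep, "unavailable")
      return(invisible(NULL))
    }
    out <- tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(out)) res[[name]] <<- out
    invisible(NULL)
  }
  stage_seed <- function(i) seed + 1000L * i

  # --- inputs -------------------------------------------------------------
  if (is.character(config)) {
    res$simulate <- read_cohort(config)
    cfg <- NULL
  } else {
    stopifnot(inherits(config, "sim_config"))
    cfg <- config
    run_stage("simulate", character(0), {
      cohort <- simulate_cohort(cfg, seed = stage_seed(1))
      if (!is.null(cfg$profiles))
        cohort <- inject_profiles(cohort, cfg, seed = stage_seed(2))
      if (!is.null(cfg$gps))
        cohort <- simulate_gps(cohort, cfg, seed = stage_seed(3))
      if (!is.null(cfg$attrition))
        cohort <- apply_attrition(cohort, cfg, seed = stage_seed(4))
      cohort
    })
  }
  cohort <- res$simulate
  all_measures <- attr(cohort, "measures")
  measures <- measures %||% all_measures[1]
  waves <- seq_len(attr(cohort, "n_waves"))

  run_stage("preprocess", "simulate", residualize(cohort))
  rc <- res$preprocess

  run_stage("describe", "simulate", {
    et <- effect_table(cohort)
    mats <- lapply(setNames(nm = measures), function(m) {
      y <- as.matrix(cohort[, paste0(m, "_t", waves)])
      list(manova = rm_manova(y, sex = cohort$sex),
           correlations = crosswave_correlations(y))
    })
    c(et, list(per_measure = mats))
  })

  run_stage("ace", "preprocess", {
    do.call(rbind, lapply(measures, function(m)
      do.call(rbind, lapply(waves, function(w) {
        f <- fit_univariate_ace(rc, m, w, ci = FALSE, seed = stage_seed(5))
        data.frame(measure = m, wave = w, t(f$components),
                   deviance = f$deviance, converged = f$converged)
      }))))
  })

  run_stage("rg", "preprocess",
            lapply(setNames(nm = measures), function(m)
              fit_correlated_factors(rc, m, waves, ci = FALSE,
                                     seed = stage_seed(6))))
  run_stage("cholesky", "preprocess",
            lapply(setNames(nm = measures), function(m)
              fit_cholesky(rc, m, waves, seed = stage_seed(7))))

  run_stage("lpa", "preprocess", {
    lapply(setNames(nm = measures), function(m) {
      sel <- select_one_per_pair(rc, seed = stage_seed(8))
      y <- as.matrix(sel[, paste0(m, "_t", waves)])
      y <- y[rowSums(!is.na(y)) > 0, , drop = FALSE]
      yc <- impute_single(y, seed = stage_seed(9))
      fits <- lapply(lpa_k, function(k)
        fit_lpa(yc, k, seed = stage_seed(10)))
      select_k(fits)
    })
  })

  run_stage("lgc", "preprocess", {
    lapply(setNames(nm = measures), function(m) {
      sel <- select_one_per_pair(rc, seed = stage_seed(11))
      y <- as.matrix(sel[, paste0(m, "_t", waves)])
      y <- y[rowSums(!is.na(y)) > 0, , drop = FALSE]
      compare_growth(y, seed = stage_seed(12))
    })
  })

  run_stage("pfactor", "preprocess", {
    sel <- select_one_per_pair(rc, seed = stage_seed(13))
    pf <- p_factor(sel[, paste0(all_measures, "_t1"), drop = FALSE])
    list(pfactor = pf, sample = sel)
  })

  run_stage("gps", "pfactor", {
    sel <- res$pfactor$sample
    gcols <- grep("^gps_", names(sel), value = TRUE)
    if (!length(gcols)) stop("no gps_ columns present")
    lapply(setNames(nm = gcols), function(g)
      gps_regression(sel[[paste0(measures[1], "_t1")]], sel[[g]],
                     covariates = sel[, c("sex", "age")]))
  })

  run_stage("extremes", "pfactor", {
    sel <- res$pfactor$sample
    grp <- extreme_groups(res$pfactor$pfactor$scores)
    lapply(setNames(nm = measures), function(m)
      trajectory_contrast(as.matrix(sel[, paste0(m, "_t", waves)]), grp))
  })

  run_stage("envcor", "simulate", {
    ecols <- grep("^env_", names(cohort), value = TRUE)
    if (length(ecols))
      lapply(setNames(nm = ecols), function(e)
        environment_correlates(cohort[[paste0(measures[1], "_t2")]],
                               cohort[[e]]))
    else NULL
  })

  # --- log & artifacts ----------------------------------------------------
  cfg_hash <- if (!is.null(cfg)) {
    tf <- tempfile()
    saveRDS(cfg, tf)
    unname(tools::md5sum(tf))
  } else NA_character_
  res$log <- list(seed = seed, config_hash = cfg_hash, stages = stages)

  if (!is.null(out_dir)) {
    if (!is.null(res$simulate) && !is.null(cfg))
      write_cohort(res$simulate, file.path(out_dir, "cohort.csv"),
                   truth_path = file.path(out_dir, "cohort_truth.csv"))
    if (!is.null(res$describe)) {
      write.csv(res$describe$descriptives,
                file.path(out_dir, "descriptives.csv"), row.names = FALSE)
      write.csv(res$describe$cohens_d,
                file.path(out_dir, "cohens_d.csv"), row.names = FALSE)
    }
    if (!is.null(res$ace))
      write.csv(res$ace, file.path(out_dir, "ace.csv"), row.names = FALSE)

    summary_list <- list(
      log = res$log,
      errors = res$errors,
      effect_sizes = res$describe$cohens_d,
      ace = res$ace,
      rG = lapply(res$rg, function(f) f$rG),
      lpa = lapply(res$lpa, function(s) s$table),
      growth = lapply(res$lgc, function(g) g$table),
      extremes = lapply(res$extremes, function(e)
        list(n = as.list(e$n), d = as.list(e$d)))
    )
    jsonlite::write_json(summary_list,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE,
                         na = "null")
  }
  if (length(res$errors))
    warning("stage error(s): ",
            paste(names(res$errors), unlist(res$errors),
                  sep = ": ", collapse = " | "))
  invisible(res)
}
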