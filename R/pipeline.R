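#' Run the QCS pipeline end to end
#'
#' Orchestrates the stages simulate -> features -> consolidate -> stratify ->
#' crossval on one configuration and writes all outputs plus a versioned JSON
#' manifest (configuration, seeds, per-stage outputs and warnings) into the
#' run directory. Re-running with an identical configuration and seed
#' reproduces identical outputs.
#'
#' The configuration is a nested list (or the path of a YAML file with the
#' same structure): `out` (run directory), `seed`, `stages` (subset of the
#' five stage names, in order), `sim` (arguments of [sim_config()]), `grid`
#' (arguments of [expand_feature_grid()]), `consolidate` (`rho`), `stratify`
#' (`readout`, `target`, `min_prevalence`, `B`), `cv` (arguments of
#' [cv_config()]), and - when the simulate stage is skipped - `paths`
#' (`cohort_dir` with the cell/TIL/area tables, `clinical` CSV).
#'
#' @param config Configuration list or path to a YAML file.
#' @return The run directory, invisibly; the manifest is attached as
#'   attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cf <- config
  if (is.null(cf$out)) stop("config must name an output directory ('out')")
  if (is.null(cf$seed)) cf$seed <- 1L
  stages <- cf$stages %||%
    c("simulate", "features", "consolidate", "stratify", "crossval")
  dir.create(cf$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "qcscore",
                   version = as.character(utils::packageVersion("qcscore")),
                   seed = cf$seed, stages = stages, config = config,
                   outputs = list(), warnings = list())
  run_stage <- function(name, fn) {
    withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        manifest$warnings[[length(manifest$warnings) + 1L]] <<-
          paste0(name, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  cohort <- NULL
  samples <- NULL
  clinical <- NULL
  readouts <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sc <- do.call(sim_config, c(cf$sim, list(seed = cf$seed)))
      cohort <<- simulate_cohort(sc)
      samples <<- cohort$samples
      clinical <<- cohort$clinical
      write_cohort_tables(samples, cf$out)
      write.csv(clinical, file.path(cf$out, "clinical.csv"),
                row.names = FALSE)
      manifest$outputs$simulate <<- list(
        n_patients = length(samples),
        planted = cohort$planted[c("cut")],
        files = c("cells.csv", "tils.csv", "areas.csv", "clinical.csv"))
    })
  } else {
    run_stage("load", function() {
      if (is.null(cf$paths$cohort_dir))
        stop("paths$cohort_dir is required when the simulate stage is off")
      samples <<- read_cohort_tables(cf$paths$cohort_dir)
      if (is.null(cf$paths$clinical) || !file.exists(cf$paths$clinical))
        stop("clinical file not found: ",
             cf$paths$clinical %||% "<not set>")
      clinical <<- read.csv(cf$paths$clinical)
    })
  }

  if ("features" %in% stages) {
    run_stage("features", function() {
      specs <- do.call(expand_feature_grid, cf$grid %||% list())
      readouts <<- compute_readout_matrix(samples, specs)
      df <- data.frame(patient_id = rownames(readouts), readouts,
                       check.names = FALSE)
      write.csv(df, file.path(cf$out, "readouts.csv"), row.names = FALSE)
      spec_meta <- lapply(attr(readouts, "specs"), function(s)
        s[setdiff(names(s), NULL)])
      jsonlite::write_json(spec_meta,
                           file.path(cf$out, "readout_specs.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest$outputs$features <<- list(n_readouts = ncol(readouts))
    })
  }

  if ("consolidate" %in% stages) {
    run_stage("consolidate", function() {
      if (is.null(readouts)) stop("features stage must run first")
      m1 <- drop_non_informative(readouts)
      rho <- cf$consolidate$rho %||% 0.99
      m2 <- drop_correlated(m1, rho = rho)
      report <- list(
        n_input = ncol(readouts),
        n_after_non_informative = ncol(m1),
        n_after_correlation = ncol(m2),
        dropped_non_informative = as.list(attr(m1, "dropped")),
        dropped_correlated = attr(m2, "dropped"))
      jsonlite::write_json(report,
                           file.path(cf$out, "consolidation.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      readouts <<- m2
      df <- data.frame(patient_id = rownames(m2), m2, check.names = FALSE)
      write.csv(df, file.path(cf$out, "readouts_unique.csv"),
                row.names = FALSE)
      manifest$outputs$consolidate <<- report[1:3]
    })
  }

  pick_readout <- function() {
    nm <- cf$stratify$readout %||%
      (if (!is.null(cohort)) cohort$planted$feature$name else
         colnames(readouts)[1])
    if (!nm %in% colnames(readouts))
      stop("readout '", nm, "' not present after consolidation")
    nm
  }

  if ("stratify" %in% stages) {
    run_stage("stratify", function() {
      if (is.null(readouts)) stop("features stage must run first")
      nm <- pick_readout()
      target <- cf$stratify$target %||% "logrank"
      cut <- bootstrap_cutpoint(readouts[, nm], clinical, target = target,
                                B = cf$stratify$B %||% 50,
                                min_prevalence =
                                  cf$stratify$min_prevalence %||% 0.2,
                                seed = cf$seed)
      res <- stratify(readouts[, nm], cut, clinical)
      out <- list(readout = nm, target = target, cut = as.numeric(cut),
                  prevalence_pos = res$prevalence_pos,
                  orr_pos = res$orr_pos, orr_neg = res$orr_neg,
                  median_pfs_pos = res$km_pos$median,
                  median_pfs_neg = res$km_neg$median,
                  logrank_chisq = res$logrank_chisq,
                  logrank_p = res$logrank_p)
      jsonlite::write_json(out, file.path(cf$out, "stratification.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      km_df <- rbind(
        data.frame(group = "positive", time = res$km_pos$time,
                   surv = res$km_pos$surv),
        data.frame(group = "negative", time = res$km_neg$time,
                   surv = res$km_neg$surv))
      write.csv(km_df, file.path(cf$out, "km_curves.csv"),
                row.names = FALSE)
      manifest$outputs$stratify <<- out
    })
  }

  if ("crossval" %in% stages) {
    run_stage("crossval", function() {
      if (is.null(readouts)) stop("features stage must run first")
      nm <- pick_readout()
      cvc <- do.call(cv_config, c(cf$cv %||% list(n = 10, m = 99),
                                  list(seed = cf$seed)))
      pv <- permutation_pvalue(readouts[, nm], clinical, cvc)
      out <- list(readout = nm, k = cvc$k, n = cvc$n, m = cvc$m,
                  observed_stat = pv$observed, empirical_p = pv$p,
                  prevalence = pv$cv$prevalence,
                  orr_pos = pv$cv$orr_pos, orr_neg = pv$cv$orr_neg,
                  n_failed_splits = pv$cv$n_failed)
      jsonlite::write_json(out, file.path(cf$out, "cv.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write.csv(data.frame(null_stat = pv$null),
                file.path(cf$out, "cv_null_distribution.csv"),
                row.names = FALSE)
      manifest$outputs$crossval <<- out
    })
  }

  jsonlite::write_json(manifest, file.path(cf$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  out_dir <- cf$out
  attr(out_dir, "manifest") <- manifest
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
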