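#' Cut-point optimisation with a minimum-prevalence constraint
#'
#' Every observed readout value is a candidate binary cut point; patients with
#' a value greater than or equal to the cut form the QCS-positive group. Cuts
#' leaving either group below `min_prevalence` of the cohort are inadmissible.
#' `target = "orr"` maximises the objective response rate in the positive
#' group; `target = "logrank"` maximises the log-rank chi-square between the
#' groups (equivalently, minimises the log-rank p while avoiding p-value
#' underflow ties). Ties are resolved towards the smallest cut.
#'
#' [bootstrap_cutpoint()] stabilises the optimum: `B` bootstrap resamples of
#' the training set are drawn with replacement, the scan is run on each, and
#' the modal cut (smallest on modal ties) is returned.
#'
#' @param values Readout values, one per patient.
#' @param clinical `data.frame` with `pfs_months`, `pfs_event`,
#'   `best_response` aligned with `values`.
#' @param target `"orr"` or `"logrank"`.
#' @param min_prevalence Minimum group prevalence (default 0.2).
#' @param B Number of bootstrap resamples (default 50).
#' @param seed Integer seed for the bootstrap draws.
#' @return The selected cut value. `optimize_cutpoint()` attaches the achieved
#'   target statistic as attribute `"stat"`; `bootstrap_cutpoint()` attaches
#'   the per-resample cuts as attribute `"cuts"`.
#' @export
optimize_cutpoint <- function(values, clinical, target = c("logrank", "orr"),
                              min_prevalence = 0.2) {
  target <- match.arg(target)
  stopifnot(length(values) == nrow(clinical), length(values) >= 5)
  resp <- as.integer(clinical$best_response %in% c("CR", "PR"))
  res <- cpp_scan_cutpoints(as.numeric(values),
                            as.numeric(clinical$pfs_months),
                            as.integer(clinical$pfs_event),
                            resp,
                            ifelse(target == "orr", 0L, 1L),
                            min_prevalence)
  if (is.na(res[["cut"]]))
    stop(sprintf(paste0("no admissible cut point: none of the %d candidate ",
                        "cuts keeps both groups above prevalence %.0f%%"),
                 length(unique(values)), 100 * min_prevalence))
  structure(res[["cut"]], stat = res[["stat"]])
}

#' @rdname optimize_cutpoint
#' @export
bootstrap_cutpoint <- function(values, clinical, target = c("logrank", "orr"),
                               B = 50, min_prevalence = 0.2, seed = NULL) {
  target <- match.arg(target)
  stopifnot(length(values) == nrow(clinical), length(values) >= 5)
  restore <- local_seed(seed)
  on.exit(restore())
  n <- length(values)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  modal_boot_cut(values, clinical, target, min_prevalence, idx)
}

# Shared by bootstrap_cutpoint and the cross-validation loop (which supplies
# pre-drawn index matrices for reproducibility across permutations).
modal_boot_cut <- function(values, clinical, target, min_prevalence, idx) {
  resp <- as.integer(clinical$best_response %in% c("CR", "PR"))
  cuts <- cpp_bootstrap_cuts(as.numeric(values),
                             as.numeric(clinical$pfs_months),
                             as.integer(clinical$pfs_event),
                             resp,
                             ifelse(target == "orr", 0L, 1L),
                             min_prevalence, idx)
  ok <- cuts[!is.na(cuts)]
  if (length(ok) == 0)
    stop("all bootstrap cut-point optimisations failed (no admissible cuts)")
  u <- unique(ok)                      # exact float mode, no name round-trip
  counts <- tabulate(match(ok, u))
  modal <- u[counts == max(counts)]
  structure(min(modal), cuts = cuts)
}

#' Stratify a cohort at a fixed cut point
#'
#' Applies the `value >= cut` positivity convention and summarises the two
#' groups: prevalence, per-group objective response rate, Kaplan-Meier curves,
#' and the log-rank test. If one group is empty the test fields are `NA` and a
#' warning is raised.
#'
#' @param values Readout values.
#' @param cut Cut point (finite).
#' @param clinical Clinical table as in [optimize_cutpoint()].
#' @return List of class `qcs_stratification` with elements `cut`,
#'   `positive` (logical), `prevalence_pos`, `prevalence_neg` (percent),
#'   `orr_pos`, `orr_neg`, `km_pos`, `km_neg`, `logrank_chisq`, `logrank_p`.
#' @export
stratify <- function(values, cut, clinical) {
  stopifnot(is.finite(cut), length(values) == nrow(clinical))
  pos <- values >= cut
  out <- list(cut = cut, positive = pos,
              prevalence_pos = 100 * mean(pos),
              prevalence_neg = 100 * mean(!pos),
              orr_pos = orr(clinical$best_response[pos]),
              orr_neg = orr(clinical$best_response[!pos]),
              km_pos = if (any(pos))
                km_estimate(clinical$pfs_months[pos], clinical$pfs_event[pos]),
              km_neg = if (any(!pos))
                km_estimate(clinical$pfs_months[!pos],
                            clinical$pfs_event[!pos]),
              logrank_chisq = NA_real_, logrank_p = NA_real_)
  if (any(pos) && any(!pos) && sum(clinical$pfs_event) > 0) {
    lr <- logrank_test(clinical$pfs_months, clinical$pfs_event, pos)
    out$logrank_chisq <- lr$chisq
    out$logrank_p <- lr$p
  } else {
    warning("one stratum is empty (or no events); log-rank fields are NA")
  }
  class(out) <- "qcs_stratification"
  out
}

#' @export
print.qcs_stratification <- function(x, ...) {
  cat(sprintf(paste0("<qcs_stratification> cut %.4g | prevalence %.1f%% vs ",
                     "%.1f%% | ORR %.1f%% vs %.1f%% | log-rank p %.3g\n"),
              x$cut, x$prevalence_pos, x$prevalence_neg,
              x$orr_pos, x$orr_neg, x$logrank_p))
  invisible(x)
}
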