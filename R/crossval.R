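#' Cross-validation configuration
#'
#' Parameters of the n-times repeated k-fold cross-validation with
#' permutation-based empirical p-values. The full-fidelity defaults are
#' k = 5 folds, n = 300 repeats and m = 1200 permutations, with a 50-resample
#' bootstrap inside every training fold; examples and tests use smaller n and
#' m.
#'
#' `n_perm` is the number of splits evaluated per permutation. It defaults to
#' `n` so the permuted pipeline is identical to the observed one, which keeps
#' the permutation test exact; it can be lowered for cost control at the price
#' of a conservative p (the null statistic then averages fewer splits and has
#' a heavier tail than the observed statistic).
#'
#' @param k Number of folds (>= 2).
#' @param n Number of repeated random splits.
#' @param m Number of permutations.
#' @param B Bootstrap resamples per training fold.
#' @param target Optimisation target, `"logrank"` or `"orr"`.
#' @param min_prevalence Minimum group prevalence for admissible cuts.
#' @param n_perm Splits per permutation (default `n`).
#' @param seed Integer seed governing splits, bootstrap draws and
#'   permutations.
#' @return List of class `qcs_cv_config`.
#' @export
cv_config <- function(k = 5, n = 300, m = 1200, B = 50,
                      target = c("logrank", "orr"), min_prevalence = 0.2,
                      n_perm = n, seed = 1) {
  target <- match.arg(target)
  stopifnot(k >= 2, n >= 1, m >= 1, B >= 1, n_perm >= 1, n_perm <= n)
  structure(list(k = k, n = n, m = m, B = B, target = target,
                 min_prevalence = min_prevalence, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "qcs_cv_config")
}

# One full CV pass: n_splits repeated k-fold rounds. All randomness (fold
# partitions, bootstrap indices) is drawn from set.seed(seed) in a fixed
# order, so a permuted run with the same seed reuses identical partitions and
# bootstrap draws - the variance-reduction choice for the permutation test.
cv_machinery <- function(values, time, event, resp, k, n_splits, B,
                         target, min_prevalence, seed) {
  npat <- length(values)
  target_i <- ifelse(target == "orr", 0L, 1L)
  restore <- local_seed(seed)
  on.exit(restore())
  labels <- matrix(NA, nrow = n_splits, ncol = npat)
  chisq <- rep(NA_real_, n_splits)
  prev_fold <- matrix(NA_real_, nrow = n_splits, ncol = k)
  orr_pos_fold <- matrix(NA_real_, nrow = n_splits, ncol = k)
  orr_neg_fold <- matrix(NA_real_, nrow = n_splits, ncol = k)
  cuts <- matrix(NA_real_, nrow = n_splits, ncol = k)
  for (s in seq_len(n_splits)) {
    fold <- sample(rep(seq_len(k), length.out = npat))
    lab <- rep(NA, npat)
    failed <- FALSE
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      cut <- cpp_fold_modal_cut(values[tr], time[tr], event[tr], resp[tr],
                                target_i, min_prevalence, B)
      if (is.na(cut)) { failed <- TRUE; next }
      cuts[s, f] <- cut
      pos <- values[te] >= cut
      lab[te] <- pos
      prev_fold[s, f] <- 100 * mean(pos)
      if (any(pos)) orr_pos_fold[s, f] <- 100 * mean(resp[te][pos])
      if (any(!pos)) orr_neg_fold[s, f] <- 100 * mean(resp[te][!pos])
    }
    if (failed) next
    labels[s, ] <- lab
    if (length(unique(lab)) == 2 && sum(event) > 0) {
      chisq[s] <- unname(cpp_logrank(time, event,
                                     as.integer(lab))["chisq"])
    } else {
      chisq[s] <- 0
    }
  }
  list(chisq = chisq, labels = labels, prev_fold = prev_fold,
       orr_pos_fold = orr_pos_fold, orr_neg_fold = orr_neg_fold,
       cuts = cuts, n_failed = sum(is.na(chisq)),
       observed_stat = mean(chisq, na.rm = TRUE))
}

#' Repeated k-fold cross-validation of a cut-point model
#'
#' For each of `n` random splits, the cohort is partitioned into `k` equally
#' sized folds; a bootstrap-stabilised cut point is trained on each set of
#' k - 1 folds and applied to the held-out fold, so every patient is labelled
#' exactly once per split by a model that never saw it. Labels are pooled
#' across the k folds of a split to give the split's cross-validated
#' Kaplan-Meier grouping and pooled log-rank chi-square. Prevalence and
#' per-group ORR are averaged over all n x k test folds. The across-split
#' summary statistic is the mean of the per-split pooled chi-squares; splits
#' whose training fails (no admissible cut in some fold) are excluded with a
#' count.
#'
#' @param values Readout values, one per patient.
#' @param clinical Clinical table with `pfs_months`, `pfs_event`,
#'   `best_response`.
#' @param config A [cv_config()].
#' @return List of class `qcs_cv`: per-split statistics (`chisq`), pooled
#'   label matrix (`labels`, splits x patients), per-split pooled group
#'   summaries (`split_summary` with restricted-mean survival per group),
#'   fold-averaged `prevalence` and `orr_pos`/`orr_neg` (with dispersion),
#'   the across-split `observed_stat` and `n_failed`.
#' @export
repeated_cv <- function(values, clinical, config = cv_config()) {
  stopifnot(inherits(config, "qcs_cv_config"),
            length(values) == nrow(clinical))
  if (length(values) < 2 * config$k)
    stop("cohort must contain at least 2k patients")
  time <- as.numeric(clinical$pfs_months)
  event <- as.integer(clinical$pfs_event)
  resp <- as.integer(clinical$best_response %in% c("CR", "PR"))
  mach <- cv_machinery(values, time, event, resp, config$k, config$n,
                       config$B, config$target, config$min_prevalence,
                       config$seed)
  ok <- which(!is.na(mach$chisq))
  split_summary <- do.call(rbind, lapply(ok, function(s) {
    lab <- as.logical(mach$labels[s, ])
    data.frame(
      split = s, chisq = mach$chisq[s],
      n_pos = sum(lab), n_neg = sum(!lab),
      rmst_pos = if (any(lab))
        km_rmst(km_estimate(time[lab], event[lab]), max(time)) else NA_real_,
      rmst_neg = if (any(!lab))
        km_rmst(km_estimate(time[!lab], event[!lab]), max(time)) else
          NA_real_)
  }))
  structure(list(
    chisq = mach$chisq,
    labels = mach$labels,
    cuts = mach$cuts,
    split_summary = split_summary,
    prevalence = mean(mach$prev_fold, na.rm = TRUE),
    prevalence_sd = sd(as.vector(mach$prev_fold), na.rm = TRUE),
    orr_pos = mean(mach$orr_pos_fold, na.rm = TRUE),
    orr_neg = mean(mach$orr_neg_fold, na.rm = TRUE),
    observed_stat = mach$observed_stat,
    n_failed = mach$n_failed,
    config = config), class = "qcs_cv")
}

#' @export
print.qcs_cv <- function(x, ...) {
  cat(sprintf(paste0("<qcs_cv> %d/%d splits | mean pooled chisq %.3f | ",
                     "prevalence %.1f%% | ORR %.1f%% vs %.1f%%\n"),
              sum(!is.na(x$chisq)), length(x$chisq), x$observed_stat,
              x$prevalence, x$orr_pos, x$orr_neg))
  invisible(x)
}

#' Permutation-based empirical p-value for cross-validated stratification
#'
#' Pooling test-fold labels across folds breaks the independence assumption of
#' the standard log-rank test, so significance is assessed by permutation: the
#' clinical rows (PFS time, event and response together) are permuted `m`
#' times against the fixed readout, the whole cross-validation statistic
#' pipeline is re-run on each permutation with the same fold partitions and
#' bootstrap draws as the observed run, and the empirical p is the add-one
#' estimator `(1 + #\{null >= observed\}) / (m + 1)`.
#'
#' @inheritParams repeated_cv
#' @return List with `p`, `observed`, `null` (vector of permutation
#'   statistics), `m_effective`, and the observed [repeated_cv()] result as
#'   `cv`.
#' @export
permutation_pvalue <- function(values, clinical, config = cv_config()) {
  stopifnot(inherits(config, "qcs_cv_config"))
  if (config$m < 19)
    warning("m < 19 permutations: p resolution is coarser than 0.05")
  cv <- repeated_cv(values, clinical, config)
  obs <- cv$observed_stat
  time <- as.numeric(clinical$pfs_months)
  event <- as.integer(clinical$pfs_event)
  resp <- as.integer(clinical$best_response %in% c("CR", "PR"))
  npat <- length(values)
  restore <- local_seed(config$seed + 1000003L)
  on.exit(restore())
  perms <- replicate(config$m, sample.int(npat), simplify = FALSE)
  null_stats <- vapply(perms, function(pm) {
    mach <- cv_machinery(values, time[pm], event[pm], resp[pm], config$k,
                         config$n_perm, config$B, config$target,
                         config$min_prevalence, config$seed)
    mach$observed_stat
  }, numeric(1))
  ok <- is.finite(null_stats)
  if (!all(ok))
    warning(sum(!ok), " permutations failed entirely and were excluded")
  m_eff <- sum(ok)
  p <- (1 + sum(null_stats[ok] >= obs)) / (m_eff + 1)
  list(p = p, observed = obs, null = null_stats[ok], m_effective = m_eff,
       cv = cv)
}
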