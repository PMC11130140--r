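#' Enumerate the QCS readout grid
#'
#' Expands the full deterministic grid of readout descriptors: membrane-OD
#' quantiles and mean, percentage and density of OD-positive cells over the
#' OD-threshold list, binary SPS over all radius x threshold combinations,
#' continuous SPS over all radius x aggregation combinations, and the stromal
#' TIL density. With the default parameter lists (17 thresholds spanning faint
#' to very strong staining, radii 10/25/50/75 um, quantiles 5..95 in steps of
#' 5 plus the mean) this yields 19 + 1 + 17 + 17 + 68 + 80 + 1 = 203 readouts
#' in a stable, documented order.
#'
#' @param od_thresholds OD positivity thresholds (scaled OD units).
#' @param radii SPS neighbourhood radii in micrometres.
#' @param quantiles Quantile levels in percent for OD and cSPS aggregation.
#' @param families Readout families to include.
#' @return A list of feature specifications; each element has `family` and the
#'   applicable parameters plus a unique `name`.
#' @export
expand_feature_grid <- function(
    od_thresholds = c(6, 8, 10, 12, 15, 20, 25, 30, 40, 50, 60, 70, 80,
                      90, 100, 110, 120),
    radii = c(10, 25, 50, 75),
    quantiles = seq(5, 95, by = 5),
    families = c("od_quantile", "od_mean", "pct_positive",
                 "positive_density", "bsps", "csps", "stil_density")) {
  specs <- list()
  add <- function(spec) specs[[length(specs) + 1L]] <<- spec
  if ("od_quantile" %in% families)
    for (q in quantiles)
      add(list(family = "od_quantile", quantile = q,
               name = sprintf("od_q%02d", q)))
  if ("od_mean" %in% families)
    add(list(family = "od_mean", name = "od_mean"))
  if ("pct_positive" %in% families)
    for (t in od_thresholds)
      add(list(family = "pct_positive", od_threshold = t,
               name = sprintf("pctpos_t%g", t)))
  if ("positive_density" %in% families)
    for (t in od_thresholds)
      add(list(family = "positive_density", od_threshold = t,
               name = sprintf("posdens_t%g", t)))
  if ("bsps" %in% families)
    for (r in radii) for (t in od_thresholds)
      add(list(family = "bsps", radius = r, od_threshold = t,
               name = sprintf("bsps_r%g_t%g", r, t)))
  if ("csps" %in% families)
    for (r in radii) {
      for (q in quantiles)
        add(list(family = "csps", radius = r, aggregation = q,
                 name = sprintf("csps_r%g_q%02d", r, q)))
      add(list(family = "csps", radius = r, aggregation = "mean",
               name = sprintf("csps_r%g_mean", r)))
    }
  if ("stil_density" %in% families)
    add(list(family = "stil_density", name = "stil_density"))
  specs
}

#' Evaluate one feature specification on one sample
#'
#' @param sample A [qcs_sample()].
#' @param spec One element of the list returned by [expand_feature_grid()].
#' @return Scalar readout value.
#' @export
feature_value <- function(sample, spec) {
  switch(spec$family,
    od_quantile      = od_quantile(sample, spec$quantile),
    od_mean          = od_quantile(sample, "mean"),
    pct_positive     = pct_od_positive(sample, spec$od_threshold),
    positive_density = positive_density(sample, spec$od_threshold),
    bsps             = bsps(sample, spec$radius, spec$od_threshold),
    csps             = csps(sample, spec$radius, spec$aggregation),
    stil_density     = stil_density(sample),
    stop("unknown feature family: ", spec$family))
}

#' Compute the patients x readouts matrix
#'
#' Evaluates every feature specification on every sample. Neighbourhood
#' statistics are computed once per (sample, radius) and shared across the
#' SPS readouts of that radius; the shared path returns values identical to
#' the per-feature functions. Per-sample feature failures are recorded as
#' `NA` with the reason attached in the `"failures"` attribute.
#'
#' @param samples List of [qcs_sample()] objects.
#' @param specs List of feature specifications ([expand_feature_grid()]).
#' @return Numeric matrix (rownames = patient ids, colnames = readout names)
#'   with attributes `"specs"` and `"failures"`.
#' @export
compute_readout_matrix <- function(samples, specs) {
  stopifnot(length(samples) >= 1, length(specs) >= 1)
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  nm <- vapply(specs, function(s) s$name, character(1))
  mat <- matrix(NA_real_, nrow = length(samples), ncol = length(specs),
                dimnames = list(pids, NULL))
  colnames(mat) <- make.unique(nm)
  failures <- list()
  radii <- unique(unlist(lapply(specs, function(s) s$radius)))
  for (si in seq_along(samples)) {
    smp <- samples[[si]]
    cells <- smp$cells
    ns_by_r <- list()
    for (r in radii) {
      if (nrow(cells) > 0)
        ns_by_r[[as.character(r)]] <-
          neighbor_stats(cells$x_um, cells$y_um, cells$od_membrane, r)
    }
    for (fi in seq_along(specs)) {
      spec <- specs[[fi]]
      v <- tryCatch({
        if (spec$family == "bsps" && nrow(cells) > 0) {
          ns <- ns_by_r[[as.character(spec$radius)]]
          100 * mean(cells$od_membrane >= spec$od_threshold |
                       ns$max_neigh >= spec$od_threshold)
        } else if (spec$family == "csps" && nrow(cells) > 0) {
          ns <- ns_by_r[[as.character(spec$radius)]]
          vals <- (cells$od_membrane + ns$wsum) / (1 + ns$wtot)
          if (identical(spec$aggregation, "mean")) mean(vals)
          else unname(quantile(vals, as.numeric(spec$aggregation) / 100,
                               type = 7))
        } else {
          feature_value(smp, spec)
        }
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          data.frame(patient_id = smp$patient_id, readout = spec$name,
                     reason = conditionMessage(e))
        NA_real_
      })
      mat[si, fi] <- v
    }
  }
  attr(mat, "specs") <- specs
  attr(mat, "failures") <-
    if (length(failures)) do.call(rbind, failures) else
      data.frame(patient_id = character(), readout = character(),
                 reason = character())
  mat
}
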