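#' Synthetic cohort configuration
#'
#' Describes the statistical structure of a simulated IHC cohort: spatially
#' clustered tumour-cell populations with heterogeneous membrane OD, stromal
#' TILs, and survival/response outcomes linked to a planted readout.
#'
#' Each patient carries a lognormal "expressing" membrane-OD component
#' (per-patient location and scale drawn from the configured ranges) plus a
#' near-zero "negative" component. The negative-cell fraction is drawn from
#' one of two ranges according to the patient's planted biomarker group, which
#' creates a gap in the planted readout between the groups; the midpoint cut
#' inside that gap is the planted cut. With `positive_cell_clustering` the
#' negative cells are routed into whole spatial clusters, which makes the
#' binary spatial proximity score diverge from the plain percentage of
#' positive cells.
#'
#' Progression-free survival is exponential with independent uniform
#' censoring; the hazard of planted-positive patients is `hazard_ratio` times
#' the hazard of planted-negative patients (`baseline_rate`, whose reciprocal
#' times log 2 is the planted-negative median PFS). Response is linked to the
#' same planted grouping through a logistic model; a small fixed fraction of
#' patients is non-evaluable (NE) and counts as non-responders.
#'
#' @param n_patients Number of patients.
#' @param cells_per_patient Integer range (min, max) of tumour cells.
#' @param tissue_extent_um Tissue extent (width, height) in micrometres.
#' @param spatial_process `"thomas"` (parent Poisson + Gaussian offspring) or
#'   `"uniform"`.
#' @param cluster_radius_um Gaussian offspring standard deviation (Thomas).
#' @param cluster_size Mean number of cells per cluster (Thomas).
#' @param positive_cell_clustering Route negative cells into whole clusters.
#' @param od_meanlog_range,od_sdlog_range Ranges of the per-patient lognormal
#'   membrane-OD location and scale (scaled OD units).
#' @param negative_od_mean,negative_od_sd Folded-normal parameters of the
#'   near-zero negative OD component.
#' @param neg_fraction_positive,neg_fraction_negative Ranges of the
#'   negative-cell fraction for planted-positive / planted-negative patients.
#' @param prevalence_positive Fraction of planted-positive patients.
#' @param til_density_range TILs per mm^2 range.
#' @param epithelium_fraction Analysed epithelium area as a fraction of the
#'   tissue extent.
#' @param planted_feature Feature specification (as in
#'   [expand_feature_grid()]) whose value carries the outcome link.
#' @param planted_cut Cut on the planted feature separating the groups.
#' @param hazard_ratio Hazard of planted-positive over planted-negative.
#' @param baseline_rate Exponential PFS rate of the planted-negative group
#'   (per month).
#' @param censoring_max_months Upper bound of the uniform censoring time.
#' @param response_intercept,response_effect Logit intercept (planted-negative
#'   response probability) and planted-positive effect.
#' @param ne_rate Fixed probability of a non-evaluable response.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   cohorts.
#' @return List of class `qcs_sim_config`.
#' @export
sim_config <- function(n_patients = 151,
                       cells_per_patient = c(200L, 1200L),
                       tissue_extent_um = c(1000, 1000),
                       spatial_process = c("thomas", "uniform"),
                       cluster_radius_um = 30,
                       cluster_size = 25,
                       positive_cell_clustering = TRUE,
                       od_meanlog_range = log(c(12, 35)),
                       od_sdlog_range = c(0.3, 0.6),
                       negative_od_mean = 1.0,
                       negative_od_sd = 0.5,
                       neg_fraction_positive = c(0, 0.08),
                       neg_fraction_negative = c(0.30, 0.55),
                       prevalence_positive = 0.76,
                       til_density_range = c(20, 500),
                       epithelium_fraction = 1.0,
                       planted_feature = list(family = "pct_positive",
                                              od_threshold = 6,
                                              name = "pctpos_t6"),
                       planted_cut = 80,
                       hazard_ratio = 0.58,
                       baseline_rate = log(2) / 8.6,
                       censoring_max_months = 36,
                       response_intercept = qlogis(0.30),
                       response_effect = 1.0,
                       ne_rate = 0.03,
                       seed = 1L) {
  spatial_process <- match.arg(spatial_process)
  check_range <- function(r, what, strict_pos = FALSE) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop("malformed range for ", what)
    if (strict_pos && r[2] <= 0) stop(what, " must allow positive values")
  }
  if (n_patients < 1) stop("n_patients must be positive")
  check_range(cells_per_patient, "cells_per_patient")
  if (cells_per_patient[1] < 1)
    stop("cells_per_patient must be at least 1")
  if (any(tissue_extent_um <= 0)) stop("tissue extent must be positive")
  check_range(od_meanlog_range, "od_meanlog_range")
  check_range(od_sdlog_range, "od_sdlog_range")
  check_range(neg_fraction_positive, "neg_fraction_positive")
  check_range(neg_fraction_negative, "neg_fraction_negative")
  check_range(til_density_range, "til_density_range")
  if (hazard_ratio <= 0 || baseline_rate <= 0)
    stop("hazard_ratio and baseline_rate must be positive")
  if (cluster_radius_um <= 0 || cluster_size <= 0)
    stop("cluster parameters must be positive")
  if (epithelium_fraction <= 0 || epithelium_fraction > 1)
    stop("epithelium_fraction must be in (0, 1]")
  structure(as.list(environment())[setdiff(names(as.list(environment())),
                                           "check_range")],
            class = "qcs_sim_config")
}

# Reflect coordinates back into [0, w]; the offspring sd is << w so a single
# reflection suffices, with a final clamp for safety.
reflect_into <- function(x, w) {
  x <- abs(x)
  x <- ifelse(x > w, 2 * w - x, x)
  pmin(pmax(x, 0), w)
}

#' Simulate a cohort of cell tables and linked clinical data
#'
#' Generates one [qcs_sample()] per patient plus a clinical table whose PFS
#' and response are linked to the planted readout (see [sim_config()]). The
#' planted readout value, the realised planted group and the generator's
#' feature gap between the groups are recorded for recovery experiments.
#'
#' @param config A [sim_config()].
#' @return List with `samples` (list of `qcs_sample`), `clinical`
#'   (`data.frame` with `patient_id`, `pfs_months`, `pfs_event`,
#'   `best_response`, `ihc_category`, `planted_value`, `planted_positive`),
#'   and `planted` (feature spec, cut, and realised gap `c(low, high)`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "qcs_sim_config"))
  cf <- config
  restore <- local_seed(cf$seed)
  on.exit(restore())
  W <- cf$tissue_extent_um[1]
  H <- cf$tissue_extent_um[2]
  area_mm2 <- W * H / 1e6
  samples <- vector("list", cf$n_patients)
  clin <- vector("list", cf$n_patients)
  for (p in seq_len(cf$n_patients)) {
    pid <- sprintf("P%03d", p)
    planted_pos <- runif(1) < cf$prevalence_positive
    negfr_range <- if (planted_pos) cf$neg_fraction_positive else
      cf$neg_fraction_negative
    neg_frac <- runif(1, negfr_range[1], negfr_range[2])
    meanlog <- runif(1, cf$od_meanlog_range[1], cf$od_meanlog_range[2])
    sdlog <- runif(1, cf$od_sdlog_range[1], cf$od_sdlog_range[2])
    n_cells <- cf$cells_per_patient[1] +
      sample.int(cf$cells_per_patient[2] - cf$cells_per_patient[1] + 1L,
                 1) - 1L
    # --- spatial positions -------------------------------------------------
    if (cf$spatial_process == "thomas") {
      n_parents <- max(1L, as.integer(round(n_cells / cf$cluster_size)))
      px <- runif(n_parents, 0, W)
      py <- runif(n_parents, 0, H)
      parent <- sample.int(n_parents, n_cells, replace = TRUE)
      x <- reflect_into(px[parent] + rnorm(n_cells, 0, cf$cluster_radius_um),
                        W)
      y <- reflect_into(py[parent] + rnorm(n_cells, 0, cf$cluster_radius_um),
                        H)
    } else {
      parent <- seq_len(n_cells)
      x <- runif(n_cells, 0, W)
      y <- runif(n_cells, 0, H)
    }
    # --- membrane OD: expressing component + near-zero negative cells ------
    n_neg <- round(neg_frac * n_cells)
    neg <- rep(FALSE, n_cells)
    if (n_neg > 0) {
      if (cf$positive_cell_clustering && cf$spatial_process == "thomas") {
        # fill the negative quota cluster by cluster so negatives cluster
        up <- unique(parent)
        ord_parents <- if (length(up) == 1) up else sample(up)
        cell_order <- order(match(parent, ord_parents))
        neg[cell_order[seq_len(n_neg)]] <- TRUE
      } else {
        neg[sample.int(n_cells, n_neg)] <- TRUE
      }
    }
    od_mem <- numeric(n_cells)
    od_mem[!neg] <- rlnorm(sum(!neg), meanlog, sdlog)
    od_mem[neg] <- abs(rnorm(sum(neg), cf$negative_od_mean,
                             cf$negative_od_sd))
    od_cyt <- od_mem * runif(n_cells, 0.2, 0.4)
    od_nuc <- od_mem * runif(n_cells, 0.05, 0.15)
    cells <- data.frame(cell_id = seq_len(n_cells), x_um = x, y_um = y,
                        od_membrane = od_mem, od_cytoplasm = od_cyt,
                        od_nucleus = od_nuc)
    # --- TILs --------------------------------------------------------------
    til_density <- runif(1, cf$til_density_range[1], cf$til_density_range[2])
    n_til <- rpois(1, til_density * area_mm2)
    tils <- data.frame(
      x_um = runif(n_til, 0, W), y_um = runif(n_til, 0, H),
      compartment = ifelse(runif(n_til) < 0.85, "stromal",
                           "intraepithelial"))
    samples[[p]] <- qcs_sample(
      patient_id = pid, cells = cells, tils = tils,
      epithelium_area_mm2 = area_mm2 * cf$epithelium_fraction,
      tumor_center_area_mm2 = area_mm2)
    # --- outcome linked to the realised planted readout --------------------
    planted_value <- feature_value(samples[[p]], cf$planted_feature)
    realized_pos <- planted_value >= cf$planted_cut
    rate <- cf$baseline_rate * ifelse(realized_pos, cf$hazard_ratio, 1)
    t_event <- rexp(1, rate)
    t_cens <- runif(1, 0, cf$censoring_max_months)
    ne <- runif(1) < cf$ne_rate
    responder <- !ne && (runif(1) < plogis(cf$response_intercept +
                                             cf$response_effect *
                                               realized_pos))
    best_response <- if (ne) "NE" else if (responder) {
      if (runif(1) < 0.1) "CR" else "PR"
    } else {
      if (runif(1) < 0.5) "SD" else "PD"
    }
    ihc <- cut(exp(meanlog), breaks = c(-Inf, 8, 20, 40, Inf),
               labels = c("0", "1+", "2+", "3+"))
    clin[[p]] <- data.frame(
      patient_id = pid,
      pfs_months = min(t_event, t_cens),
      pfs_event = as.integer(t_event <= t_cens),
      best_response = best_response,
      ihc_category = as.character(ihc),
      planted_value = planted_value,
      planted_positive = realized_pos)
  }
  clinical <- do.call(rbind, clin)
  gap <- c(low = suppressWarnings(
             max(clinical$planted_value[!clinical$planted_positive])),
           high = suppressWarnings(
             min(clinical$planted_value[clinical$planted_positive])))
  list(samples = samples, clinical = clinical,
       planted = list(feature = cf$planted_feature, cut = cf$planted_cut,
                      gap = gap))
}
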