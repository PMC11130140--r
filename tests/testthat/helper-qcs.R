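# Fixture builders and independent brute-force oracles. The oracles stay
# deliberately naive (all-pairs scans, explicit risk tables, exhaustive
# enumeration) so they share no code with the implementation they check.

random_cell_table <- function(n, extent = 500, od_max = 60) {
  data.frame(cell_id = seq_len(n),
             x_um = runif(n, 0, extent), y_um = runif(n, 0, extent),
             od_membrane = runif(n, 0, od_max),
             od_cytoplasm = runif(n, 0, od_max / 3))
}

random_sample <- function(n, ...) {
  qcs_sample(patient_id = "T1", cells = random_cell_table(n, ...),
             epithelium_area_mm2 = 1, tumor_center_area_mm2 = 1)
}

random_clinical <- function(n) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             pfs_months = round(rexp(n, 0.1), 3),
             pfs_event = rbinom(n, 1, 0.7),
             best_response = sample(c("CR", "PR", "SD", "PD", "NE"), n,
                                    replace = TRUE,
                                    prob = c(0.05, 0.4, 0.25, 0.27, 0.03)))
}

# all-pairs neighbourhood oracle for bSPS / cSPS
bsps_oracle <- function(cells, r, t) {
  n <- nrow(cells)
  hit <- logical(n)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 +
                (cells$y_um - cells$y_um[i])^2)
    nb <- which(d <= r)
    nb <- nb[nb != i]
    hit[i] <- cells$od_membrane[i] >= t ||
      any(cells$od_membrane[nb] >= t)
  }
  100 * mean(hit)
}

csps_oracle <- function(cells, r) {
  n <- nrow(cells)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 +
                (cells$y_um - cells$y_um[i])^2)
    nb <- which(d <= r)
    nb <- nb[nb != i]
    if (r > 0 && length(nb) > 0) {
      w <- 1 - d[nb] / r
      out[i] <- (cells$od_membrane[i] + sum(w * cells$od_membrane[nb])) /
        (1 + sum(w))
    } else {
      out[i] <- cells$od_membrane[i]
    }
  }
  out
}

# explicit risk-table log-rank oracle (chisq), independent of the C++ path
logrank_oracle <- function(times, events, group) {
  g <- as.integer(as.factor(group)) - 1L
  tj <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in tj) {
    at <- times >= t
    n <- sum(at)
    n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O1 - E1)^2 / V
}

# exhaustive cut-point oracle: scans every observed value, evaluates the
# target through survival::survdiff / plain counting
cutpoint_oracle <- function(values, clinical, target, min_prevalence = 0.2) {
  n <- length(values)
  best_cut <- NA_real_
  best_stat <- -Inf
  for (cut in sort(unique(values))) {
    pos <- values >= cut
    if (mean(pos) < min_prevalence || mean(!pos) < min_prevalence) next
    stat <- if (target == "orr") {
      100 * mean(clinical$best_response[pos] %in% c("CR", "PR"))
    } else {
      if (sum(clinical$pfs_event) == 0) 0 else
        survival::survdiff(survival::Surv(clinical$pfs_months,
                                          clinical$pfs_event) ~ pos)$chisq
    }
    if (stat > best_stat) { best_stat <- stat; best_cut <- cut }
  }
  best_cut
}

# Small ready-made segmentation fixture shared by imaging tests. ODs span
# the expressing range (~10-60 scaled OD units): at near-zero OD the 8-bit
# quantisation floor (~0.1 OD units) exceeds 2% relative error by itself,
# so relative-error checks are only meaningful on expressing cells.
make_roi_fixture <- function(seed, n_cells = 120L, extent = 256) {
  cfg <- sim_config(n_patients = 1,
                    cells_per_patient = c(n_cells, n_cells),
                    tissue_extent_um = c(extent, extent),
                    spatial_process = "uniform",
                    od_meanlog_range = log(c(20, 35)),
                    od_sdlog_range = c(0.3, 0.4),
                    neg_fraction_positive = c(0, 0),
                    neg_fraction_negative = c(0, 0),
                    seed = seed)
  coh <- simulate_cohort(cfg)
  render_roi(coh$samples[[1]], seed = seed + 1)
}
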