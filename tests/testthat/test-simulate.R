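# Synthetic cohort generator: contracts, determinism, planted effects.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cells_per_patient = c(0L, 0L)), "at least 1")
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(til_density_range = c(100, 10)), "malformed")
  expect_error(sim_config(hazard_ratio = -1), "positive")
  expect_error(sim_config(tissue_extent_um = c(-5, 100)), "positive")
})

test_that("identical seed and config give identical cohorts", {
  cfg <- sim_config(n_patients = 8, cells_per_patient = c(50L, 120L),
                    seed = 81)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$samples[[3]]$cells, c2$samples[[3]]$cells)
  expect_identical(c1$samples[[5]]$tils, c2$samples[[5]]$tils)
  c3 <- simulate_cohort(sim_config(n_patients = 8,
                                   cells_per_patient = c(50L, 120L),
                                   seed = 82))
  expect_false(identical(c1$clinical$pfs_months, c3$clinical$pfs_months))
})

test_that("all coordinates stay inside the tissue extent", {
  coh <- simulate_cohort(sim_config(n_patients = 10,
                                    cells_per_patient = c(100L, 300L),
                                    tissue_extent_um = c(400, 600),
                                    seed = 83))
  for (s in coh$samples) {
    expect_true(all(s$cells$x_um >= 0 & s$cells$x_um <= 400))
    expect_true(all(s$cells$y_um >= 0 & s$cells$y_um <= 600))
    expect_true(all(s$tils$x_um >= 0 & s$tils$x_um <= 400))
  }
})

test_that("the planted hazard ratio is recovered within 15%", {
  coh <- simulate_cohort(sim_config(n_patients = 600,
                                    cells_per_patient = c(40L, 80L),
                                    hazard_ratio = 3, seed = 84))
  fit <- survival::coxph(survival::Surv(pfs_months, pfs_event) ~
                           planted_positive, data = coh$clinical)
  expect_lt(abs(exp(coef(fit)) - 3) / 3, 0.15)
})

test_that("a null configuration decouples outcome from the planted feature", {
  coh <- simulate_cohort(sim_config(n_patients = 400,
                                    cells_per_patient = c(40L, 80L),
                                    hazard_ratio = 1, response_effect = 0,
                                    seed = 85))
  fit <- survival::coxph(survival::Surv(pfs_months, pfs_event) ~
                           planted_positive, data = coh$clinical)
  expect_gt(summary(fit)$coefficients[, "Pr(>|z|)"], 0.01)
  tab <- table(coh$clinical$planted_positive,
               coh$clinical$best_response %in% c("CR", "PR"))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("positive-cell clustering separates bSPS from %-positive", {
  cfg <- sim_config(n_patients = 12, cells_per_patient = c(400L, 600L),
                    neg_fraction_positive = c(0.3, 0.5),
                    neg_fraction_negative = c(0.3, 0.5),
                    positive_cell_clustering = TRUE, seed = 86)
  coh <- simulate_cohort(cfg)
  gap_clustered <- vapply(coh$samples, function(s)
    bsps(s, 50, 6) - pct_od_positive(s, 6), numeric(1))
  cfg2 <- sim_config(n_patients = 12, cells_per_patient = c(400L, 600L),
                     neg_fraction_positive = c(0.3, 0.5),
                     neg_fraction_negative = c(0.3, 0.5),
                     positive_cell_clustering = FALSE, seed = 86)
  coh2 <- simulate_cohort(cfg2)
  gap_random <- vapply(coh2$samples, function(s)
    bsps(s, 50, 6) - pct_od_positive(s, 6), numeric(1))
  # with random negatives nearly every cell has a positive neighbour, so
  # bSPS saturates; clustered negatives keep whole regions negative
  expect_lt(mean(gap_clustered), mean(gap_random))
})

test_that("the planted feature gap contains the planted cut", {
  for (seed in 87:90) {
    coh <- simulate_cohort(sim_config(n_patients = 60,
                                      cells_per_patient = c(100L, 250L),
                                      seed = seed))
    expect_gt(coh$planted$cut, coh$planted$gap["low"])
    expect_lte(coh$planted$cut, coh$planted$gap["high"])
  }
})

test_that("cohort tables round-trip through the CSV interchange format", {
  coh <- simulate_cohort(sim_config(n_patients = 4,
                                    cells_per_patient = c(30L, 60L),
                                    seed = 91))
  dir <- tempfile("cohort")
  write_cohort_tables(coh$samples, dir)
  back <- read_cohort_tables(dir)
  expect_length(back, 4)
  expect_equal(back[["P002"]]$cells$od_membrane,
               coh$samples[[2]]$cells$od_membrane, tolerance = 1e-12)
  expect_equal(back[["P003"]]$epithelium_area_mm2,
               coh$samples[[3]]$epithelium_area_mm2)
})
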