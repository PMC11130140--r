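# Per-patient readouts: closed forms, limit identities, invariances.

test_that("OD quantiles and mean follow linear order-statistic interpolation", {
  s <- qcs_sample("P1", data.frame(cell_id = 1:3, x_um = 1:3, y_um = 0,
                                   od_membrane = c(10, 10, 10),
                                   od_cytoplasm = 0))
  for (q in c(5, 50, 95)) expect_equal(od_quantile(s, q), 10)
  s2 <- qcs_sample("P2", data.frame(cell_id = 1:2, x_um = 1:2, y_um = 0,
                                    od_membrane = c(0, 10),
                                    od_cytoplasm = 0))
  expect_equal(od_quantile(s2, 50), 5)
  set.seed(31)
  od <- runif(1000, 0, 80)
  s3 <- qcs_sample("P3", data.frame(cell_id = 1:1000, x_um = runif(1000),
                                    y_um = runif(1000), od_membrane = od,
                                    od_cytoplasm = 0))
  # sort-and-interpolate oracle for the 5th percentile (type-7 convention)
  so <- sort(od)
  h <- (1000 - 1) * 0.05 + 1
  expect_equal(od_quantile(s3, 5),
               so[floor(h)] + (h - floor(h)) *
                 (so[floor(h) + 1] - so[floor(h)]),
               tolerance = 1e-14)
  expect_equal(od_quantile(s3, "mean"), mean(od))
})

test_that("percentage of OD-positive cells counts inclusively", {
  s <- qcs_sample("P1", data.frame(cell_id = 1:3, x_um = 1:3, y_um = 0,
                                   od_membrane = c(5, 10, 20),
                                   od_cytoplasm = 0))
  expect_equal(pct_od_positive(s, 6), 100 * 2 / 3)
  expect_equal(pct_od_positive(s, 0), 100)
  s1 <- qcs_sample("P2", data.frame(cell_id = 1, x_um = 0, y_um = 0,
                                    od_membrane = 6, od_cytoplasm = 0))
  expect_equal(pct_od_positive(s1, 6), 100) # boundary is inclusive
})

test_that("positive density divides the positive count by epithelium area", {
  cells <- data.frame(cell_id = 1:60, x_um = runif(60), y_um = runif(60),
                      od_membrane = c(rep(10, 50), rep(1, 10)),
                      od_cytoplasm = 0)
  s <- qcs_sample("P1", cells, epithelium_area_mm2 = 2)
  expect_equal(positive_density(s, 6), 25)
  expect_equal(positive_density(s, 100), 0)
  s_bad <- qcs_sample("P2", cells)
  expect_error(positive_density(s_bad, 6), "area")
})

test_that("bSPS matches the three-collinear-cell worked example", {
  s <- qcs_sample("P1", data.frame(cell_id = 1:3, x_um = c(0, 30, 100),
                                   y_um = 0, od_membrane = c(20, 2, 2),
                                   od_cytoplasm = 0))
  # cell at 0 positive; cell at 30 has positive neighbour at d=30<=50;
  # cell at 100 has neither (d=70 and d=100)
  expect_equal(bsps(s, 50, 10), 100 * 2 / 3)
  expect_equal(bsps(s, 50, 1), 100)  # saturation: all positive
})

test_that("bSPS at r = 0 equals the percentage of positive cells exactly", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_sample(sample(20:150, 1))
    for (t in c(6, 20, 50))
      expect_identical(bsps(s, 0, t), pct_od_positive(s, t))
  }
})

test_that("cSPS per-cell values follow the normalised linear weighting", {
  # isolated cell keeps its own OD
  s1 <- qcs_sample("P1", data.frame(cell_id = 1, x_um = 0, y_um = 0,
                                    od_membrane = 42, od_cytoplasm = 0))
  expect_equal(csps_cell_values(s1, 25), 42)
  # two cells at d = r/2: value_1 = (a + 0.5 b) / 1.5
  s2 <- qcs_sample("P2", data.frame(cell_id = 1:2, x_um = c(0, 25),
                                    y_um = 0, od_membrane = c(10, 4),
                                    od_cytoplasm = 0))
  expect_equal(csps_cell_values(s2, 50), c((10 + 2) / 1.5, (4 + 5) / 1.5))
  # unnormalised mode returns the literal weighted sum
  expect_equal(csps_cell_values(s2, 50, normalize = FALSE),
               c(10 + 2, 4 + 5))
  # r -> 0 recovers raw per-cell ODs, hence quantiles match od_quantile
  set.seed(12)
  for (i in 1:25) {
    s <- random_sample(sample(20:150, 1))
    expect_identical(csps_cell_values(s, 0), s$cells$od_membrane)
    for (q in c(5, 50, 95))
      expect_identical(csps(s, 0, q), od_quantile(s, q))
    expect_identical(csps(s, 0, "mean"), od_quantile(s, "mean"))
  }
})

test_that("grid-indexed neighbourhoods equal the all-pairs oracle bit for bit", {
  set.seed(13)
  for (i in 1:6) {
    s <- random_sample(500)
    for (r in c(10, 25, 75)) {
      for (t in c(6, 30)) expect_identical(bsps(s, r, t),
                                           bsps_oracle(s$cells, r, t))
      expect_identical(csps_cell_values(s, r), csps_oracle(s$cells, r))
    }
  }
})

test_that("SPS readouts are monotone in radius, threshold and quantile", {
  set.seed(14)
  for (i in 1:10) {
    s <- random_sample(120)
    radii <- c(0, 10, 25, 50, 75)
    b <- vapply(radii, function(r) bsps(s, r, 20), numeric(1))
    expect_true(all(diff(b) >= 0))             # non-decreasing in r
    thr <- c(6, 10, 20, 40, 60)
    p <- vapply(thr, function(t) pct_od_positive(s, t), numeric(1))
    expect_true(all(diff(p) <= 0))             # non-increasing in threshold
    b2 <- vapply(thr, function(t) bsps(s, 25, t), numeric(1))
    expect_true(all(diff(b2) <= 0))
    qs <- vapply(seq(5, 95, 5), function(q) od_quantile(s, q), numeric(1))
    expect_true(all(diff(qs) >= 0))            # non-decreasing in q
    expect_true(all(b >= 0 & b <= 100))
    # convex-combination property of the normalised cSPS weighting
    v <- csps_cell_values(s, 50)
    expect_true(all(v >= min(s$cells$od_membrane) - 1e-12))
    expect_true(all(v <= max(s$cells$od_membrane) + 1e-12))
  }
})

test_that("spatial features are invariant under translation and rotation", {
  set.seed(15)
  for (i in 1:5) {
    s <- random_sample(150)
    th <- runif(1, 0, 2 * pi)
    cells2 <- s$cells
    x <- cells2$x_um; y <- cells2$y_um
    cells2$x_um <- cos(th) * x - sin(th) * y + 1000
    cells2$y_um <- sin(th) * x + cos(th) * y - 400
    s2 <- qcs_sample("T2", cells2, epithelium_area_mm2 = 1,
                     tumor_center_area_mm2 = 1)
    expect_equal(bsps(s2, 40, 20), bsps(s, 40, 20), tolerance = 1e-9)
    expect_equal(csps_cell_values(s2, 40), csps_cell_values(s, 40),
                 tolerance = 1e-9)
  }
})

test_that("stromal TIL density uses the tumour-centre area", {
  tils <- data.frame(x_um = runif(400), y_um = runif(400),
                     compartment = c(rep("stromal", 337),
                                     rep("intraepithelial", 63)))
  s <- qcs_sample("P1", random_cell_table(10), tils = tils,
                  epithelium_area_mm2 = 1, tumor_center_area_mm2 = 2)
  expect_equal(stil_density(s), 168.5)
  s0 <- qcs_sample("P2", random_cell_table(10), tumor_center_area_mm2 = 2)
  expect_equal(stil_density(s0), 0)
  s_bad <- qcs_sample("P3", random_cell_table(10))
  expect_error(stil_density(s_bad), "area")
})

test_that("empty cell tables give missing readouts", {
  empty <- qcs_sample("P0", random_cell_table(0), epithelium_area_mm2 = 1,
                      tumor_center_area_mm2 = 1)
  expect_true(is.na(od_quantile(empty, 50)))
  expect_true(is.na(pct_od_positive(empty, 6)))
  expect_true(is.na(bsps(empty, 50, 6)))
  expect_true(is.na(csps(empty, 50, "mean")))
})
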