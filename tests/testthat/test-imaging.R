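# Colour deconvolution, seeded watershed, compartments, validation metrics.

test_that("colour deconvolution inverts Beer-Lambert mixing in closed form", {
  basis <- stain_basis()
  # pure white: OD 0
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(as.numeric(deconvolve_dab(white)), 0)
  # pure DAB at absorbance 0.5: 50 scaled OD units under the x100 scale
  I <- 255 * 10^(-0.5 * basis["dab", ])
  img <- array(rep(I, each = 1), dim = c(1, 1, 3))
  expect_equal(as.numeric(deconvolve_dab(img)), 50, tolerance = 1e-6)
  # hematoxylin does not leak into the DAB channel
  Ih <- 255 * 10^(-0.8 * basis["hematoxylin", ])
  imgh <- array(rep(Ih, each = 1), dim = c(1, 1, 3))
  expect_equal(as.numeric(deconvolve_dab(imgh)), 0, tolerance = 1e-6)
  # monotone in DAB concentration under fixed hematoxylin
  ods <- vapply(seq(0.1, 1.2, 0.1), function(a) {
    I <- 255 * 10^(-(a * basis["dab", ] + 0.4 * basis["hematoxylin", ]))
    as.numeric(deconvolve_dab(array(I, dim = c(1, 1, 3))))
  }, numeric(1))
  expect_true(all(diff(ods) > 0))
  # saturated black clips at the configured maximum
  black <- array(0, dim = c(1, 1, 3))
  expect_lte(as.numeric(deconvolve_dab(black, max_od = 300)), 300)
  expect_error(deconvolve_dab(white, basis = matrix(1, 3, 3)), "singular")
})

test_that("two seeds split a ramp plateau at the posterior ridge", {
  # energy rises linearly to a crest at column 11 of 21
  energy <- matrix(rep(1 - abs(seq(-1, 1, length.out = 21)), each = 11),
                   nrow = 11)
  centers <- data.frame(x_px = c(3, 19), y_px = c(6, 6))
  seg <- segment_cells(energy, matrix(0, 11, 21), centers,
                       matrix(TRUE, 11, 21), band_px = 2)
  expect_identical(sort(unique(as.integer(seg$instances))), c(1L, 2L))
  boundary_cols <- apply(seg$instances, 1, function(row)
    max(which(row == 1)))
  expect_true(all(abs(boundary_cols - 10.5) <= 1))
})

test_that("compartments partition every instance with a 2-4 px membrane band", {
  roi <- make_roi_fixture(201, n_cells = 60L, extent = 200)
  seg <- segment_cells(roi$membrane_post, roi$nuclei_post, roi$centers,
                       roi$epithelium)
  lab <- seg$instances
  comp <- seg$compartments
  # compartments are defined exactly on the union of instances
  expect_identical(comp > 0, lab > 0)
  for (l in sample(seg$centers$label, 10)) {
    inst <- lab == l
    mem <- inst & comp == 1
    nuc <- inst & comp == 2
    cyt <- inst & comp == 3
    expect_identical(mem | nuc | cyt, inst)           # exhaustive
    expect_equal(sum(mem & nuc) + sum(mem & cyt) + sum(nuc & cyt), 0)
    # membrane depth: band present at depth 1-2, absent beyond depth 4
    e <- lab
    for (k in 1:2) e <- qcscore:::label_erode(e)
    shallow <- inst & e == 0
    expect_true(all(mem[shallow]))
    for (k in 3:4) e <- qcscore:::label_erode(e)
    expect_equal(sum(mem & e == l), 0)
  }
})

test_that("zero or misplaced seeds degrade gracefully", {
  post <- matrix(0.1, 20, 20)
  epi <- matrix(FALSE, 20, 20)
  epi[5:15, 5:15] <- TRUE
  empty <- segment_cells(post, post, data.frame(x_px = numeric(),
                                                y_px = numeric()), epi)
  expect_true(all(empty$instances == 0))
  expect_warning(
    seg <- segment_cells(post, post,
                         data.frame(x_px = c(10, 2), y_px = c(10, 2)), epi),
    "dropped")
  expect_equal(seg$n_dropped_seeds, 1)
  expect_identical(sort(unique(as.integer(seg$instances))), c(0L, 1L))
  # nuclei posterior identically 0: no nucleus anywhere
  expect_equal(sum(seg$compartments == 2), 0)
  expect_gt(sum(seg$compartments == 3), 0)
})

test_that("compartment means average the OD map over each compartment", {
  lab <- matrix(0L, 8, 8)
  lab[2:7, 2:7] <- 1L
  post <- matrix(0, 8, 8)
  seg <- segment_cells(post, post, data.frame(x_px = 4.5, y_px = 4.5),
                       lab > 0, band_px = 2)
  odmap <- matrix(7, 8, 8)
  m <- measure_compartment_od(odmap, seg, pixel_size_um = 1)
  expect_equal(m$od_membrane, 7)   # uniform map: every compartment mean = v
  expect_equal(m$od_cytoplasm, 7)
  odmap2 <- matrix(0, 8, 8)
  mem_px <- which(seg$compartments == 1)
  odmap2[mem_px[1:2]] <- c(6, 10)  # membrane pixels {6, 10, 0, ...}
  m2 <- measure_compartment_od(odmap2, seg, pixel_size_um = 1)
  expect_equal(m2$od_membrane, (6 + 10) / sum(seg$compartments == 1))
  expect_error(measure_compartment_od(matrix(0, 4, 4), seg), "dimensions")
})

test_that("validation metrics satisfy their identities and worked example", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(eval_dice(m1, m1), 1)
  expect_equal(eval_dice(m1, !m1), 0)
  expect_equal(eval_dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_equal(eval_dice(m1, matrix(FALSE, 2, 2)), 0)
  pts <- data.frame(x_um = c(0, 10, 20), y_um = 0)
  expect_equal(eval_f1_centers(pts, pts, 2)$f1, 1)
  # one of three pairs beyond the match radius: P = R = F1 = 2/3
  pred <- data.frame(x_um = c(0, 10, 50), y_um = 0)
  true <- data.frame(x_um = c(0.5, 10.5, 20), y_um = 0)
  res <- eval_f1_centers(pred, true, 3)
  expect_equal(res$precision, 2 / 3)
  expect_equal(res$recall, 2 / 3)
  expect_equal(res$f1, 2 / 3)
  sq <- matrix(FALSE, 12, 12); sq[3:9, 3:9] <- TRUE
  expect_equal(eval_assd(sq, sq), 0)
  sq2 <- matrix(FALSE, 12, 12); sq2[4:10, 3:9] <- TRUE  # shifted by 1 px
  expect_lte(eval_assd(sq, sq2, pixel_size_um = 0.5), 0.5)
  expect_error(eval_assd(sq, matrix(FALSE, 12, 12)), "non-empty")
  set.seed(99)
  v <- runif(50)
  expect_equal(eval_od_correlation(v, 2 * v + 1), 1)
})

test_that("rendered ROIs honour packing, ground-truth and OD round trips", {
  # one cell with membrane OD 0: no DAB absorbance on the membrane
  s1 <- qcs_sample("P1", data.frame(cell_id = 1, x_um = 20, y_um = 20,
                                    od_membrane = 0, od_cytoplasm = 0,
                                    od_nucleus = 0))
  roi1 <- render_roi(s1, noise_sd = 0, seed = 1)
  mem <- roi1$compartments == 1
  od1 <- deconvolve_dab(roi1$rgb)
  expect_lt(mean(od1[mem]), 0.5)
  # single-cell OD u recovered within 2% on the true membrane mask
  s2 <- qcs_sample("P2", data.frame(cell_id = 1, x_um = 20, y_um = 20,
                                    od_membrane = 40, od_cytoplasm = 10,
                                    od_nucleus = 2))
  roi2 <- render_roi(s2, seed = 2)
  od2 <- deconvolve_dab(roi2$rgb)
  expect_lt(abs(mean(od2[roi2$compartments == 1]) - 40) / 40, 0.02)
  # two touching cells have disjoint instance masks in the ground truth
  s3 <- qcs_sample("P3", data.frame(cell_id = 1:2, x_um = c(20, 29.5),
                                    y_um = 20, od_membrane = 20,
                                    od_cytoplasm = 5, od_nucleus = 1))
  roi3 <- render_roi(s3, seed = 3)
  expect_identical(sort(unique(as.integer(roi3$instances))), 0:2)
  expect_equal(sum(roi3$instances == 1 & roi3$instances == 2), 0)
  # overlap handling: drop counts or error, per configuration
  s4 <- qcs_sample("P4", data.frame(cell_id = 1:2, x_um = c(20, 22),
                                    y_um = 20, od_membrane = 20,
                                    od_cytoplasm = 5, od_nucleus = 1))
  expect_error(render_roi(s4, overlap = "error", seed = 4), "packing")
  roi4 <- render_roi(s4, overlap = "drop", seed = 4)
  expect_equal(roi4$n_dropped, 1)
  # posteriors are proper probability maps
  expect_true(all(roi3$membrane_post >= 0 & roi3$membrane_post <= 1))
  expect_true(all(roi3$nuclei_post >= 0 & roi3$nuclei_post <= 1))
})
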