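#' Render a synthetic IHC region of interest with ground truth
#'
#' Draws the tumour cells of a sample as near-circular cells (Voronoi-split
#' where they touch), builds per-cell compartment masks (an outer membrane
#' band, a nuclear disk, cytoplasm in between), and renders an RGB
#' brightfield image by Beer-Lambert mixing of a hematoxylin stain on nuclei
#' with a DAB stain whose per-pixel absorbance on the membrane band equals the
#' cell's true membrane OD. Membrane and nuclei posterior maps are smoothed
#' indicators of the true masks, and the cell centres double as watershed
#' seeds - together these are the inputs of [segment_cells()], with exact
#' ground truth for every rendered cell.
#'
#' Cells closer together than `min_sep_um` cannot be packed at the requested
#' radius; depending on `overlap` they are either dropped sequentially (with a
#' count in the result) or raise an error.
#'
#' @param sample A [qcs_sample()].
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param cell_radius_um Cell radius in micrometres (equal for all cells).
#' @param band_px Membrane band thickness in pixels (2-4).
#' @param overlap `"drop"` or `"error"` for cells violating the packing
#'   tolerance.
#' @param min_sep_um Packing tolerance (centre separation); default
#'   `1.8 * cell_radius_um`.
#' @param noise_sd Per-pixel absorbance noise (base-10) added to the DAB
#'   channel before quantisation; dithers the 8-bit rounding so compartment
#'   means stay unbiased.
#' @param od_scale Scaled OD units per unit absorbance (must match
#'   [deconvolve_dab()]).
#' @param basis Stain basis ([stain_basis()]).
#' @param roi_um Optional (width, height) of the rendered window; defaults to
#'   the bounding box of the cells plus one cell radius.
#' @param seed Optional seed for radii and noise.
#' @return List of class `qcs_roi`: `rgb` (H x W x 3, 0-255), `epithelium`
#'   (logical mask = union of cell instances), `instances` (integer label
#'   map), `compartments` (0 background, 1 membrane, 2 nucleus, 3 cytoplasm),
#'   `centers` (data frame with `cell_id`, `label`, pixel and micron
#'   coordinates), `membrane_post`/`nuclei_post` in [0, 1], `truth` (per-cell
#'   true compartment ODs), `pixel_size_um`, `n_dropped`.
#' @export
render_roi <- function(sample, pixel_size_um = 0.5, cell_radius_um = 5,
                       band_px = 3L, overlap = c("drop", "error"),
                       min_sep_um = 1.8 * cell_radius_um,
                       noise_sd = 0.004, od_scale = 100,
                       basis = stain_basis(), roi_um = NULL, seed = NULL) {
  overlap <- match.arg(overlap)
  stopifnot(pixel_size_um > 0, band_px >= 2, band_px <= 4)
  restore <- local_seed(seed)
  on.exit(restore())
  cells <- sample$cells
  if (nrow(cells) == 0) stop("cannot render an empty cell table")
  # sequential hard-core packing
  keep <- logical(nrow(cells))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    if (length(kx) == 0 ||
        all((kx - cells$x_um[i])^2 + (ky - cells$y_um[i])^2 >=
              min_sep_um^2)) {
      keep[i] <- TRUE
      kx <- c(kx, cells$x_um[i]); ky <- c(ky, cells$y_um[i])
    } else if (overlap == "error") {
      stop("cells overlap beyond the packing tolerance (cell_id ",
           cells$cell_id[i], ")")
    }
  }
  n_dropped <- sum(!keep)
  cells <- cells[keep, , drop = FALSE]
  n <- nrow(cells)
  if (is.null(roi_um))
    roi_um <- c(max(cells$x_um), max(cells$y_um)) + cell_radius_um
  W <- ceiling(roi_um[1] / pixel_size_um)
  H <- ceiling(roi_um[2] / pixel_size_um)
  # continuous 1-based pixel positions of the centres
  colc <- cells$x_um / pixel_size_um + 0.5
  rowc <- cells$y_um / pixel_size_um + 0.5
  # equal radii keep the true boundary between touching cells on the exact
  # midline between their centres (cell-size pleomorphism is not modelled)
  rad_px <- rep(cell_radius_um / pixel_size_um, n)
  lab <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  for (i in seq_len(n)) {
    r0 <- max(1L, floor(rowc[i] - rad_px[i]))
    r1 <- min(H, ceiling(rowc[i] + rad_px[i]))
    c0 <- max(1L, floor(colc[i] - rad_px[i]))
    c1 <- min(W, ceiling(colc[i] + rad_px[i]))
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - rowc[i])^2, (cc - colc[i])^2, "+"))
    upd <- d <= rad_px[i] & d < bestd[rr, cc]
    sub <- lab[rr, cc]; sub[upd] <- i; lab[rr, cc] <- sub
    subd <- bestd[rr, cc]; subd[upd] <- d[upd]; bestd[rr, cc] <- subd
  }
  membrane <- membrane_band(lab, band_px)
  nucleus <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    nr_px <- 0.45 * rad_px[i]
    r0 <- max(1L, floor(rowc[i] - nr_px)); r1 <- min(H, ceiling(rowc[i] + nr_px))
    c0 <- max(1L, floor(colc[i] - nr_px)); c1 <- min(W, ceiling(colc[i] + nr_px))
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - rowc[i])^2, (cc - colc[i])^2, "+"))
    sub <- nucleus[rr, cc]
    sub[d <= nr_px & lab[rr, cc] == i] <- TRUE
    nucleus[rr, cc] <- sub
  }
  nucleus <- nucleus & !membrane
  comp <- matrix(0L, H, W)
  comp[lab > 0] <- 3L
  comp[nucleus] <- 2L
  comp[membrane] <- 1L
  # per-pixel DAB absorbance from the true compartment ODs
  od_of <- function(col) { v <- numeric(H * W); v[lab > 0] <- col[lab[lab > 0]]; matrix(v, H, W) }
  od_nuc_col <- if (!is.null(cells$od_nucleus)) cells$od_nucleus else
    rep(0, n)
  a_dab <- matrix(0, H, W)
  a_dab[comp == 1L] <- od_of(cells$od_membrane)[comp == 1L] / od_scale
  a_dab[comp == 2L] <- od_of(od_nuc_col)[comp == 2L] / od_scale
  a_dab[comp == 3L] <- od_of(cells$od_cytoplasm)[comp == 3L] / od_scale
  a_dab <- pmax(a_dab + matrix(rnorm(H * W, 0, noise_sd), H, W), 0)
  a_hem <- matrix(0, H, W)
  a_hem[comp == 2L] <- 0.65
  a_hem[comp == 1L | comp == 3L] <- 0.03
  rgb <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    I <- 255 * 10^-(a_hem * basis["hematoxylin", ch] +
                      a_dab * basis["dab", ch])
    rgb[, , ch] <- pmin(pmax(round(I), 0), 255)
  }
  centers <- data.frame(cell_id = cells$cell_id, label = seq_len(n),
                        x_px = colc, y_px = rowc,
                        x_um = cells$x_um, y_um = cells$y_um)
  truth <- data.frame(cell_id = cells$cell_id, label = seq_len(n),
                      od_membrane = cells$od_membrane,
                      od_cytoplasm = cells$od_cytoplasm,
                      od_nucleus = od_nuc_col)
  structure(list(rgb = rgb, epithelium = lab > 0, instances = lab,
                 compartments = comp, centers = centers,
                 # membrane posterior: smoothed indicator, saturated on the
                 # band support so the watershed crest is a clean plateau
                 membrane_post = pmin(pmax(pmax(membrane * 1,
                                                blur3(membrane * 1)), 0), 1),
                 nuclei_post = pmin(pmax(blur3(nucleus * 1), 0), 1),
                 truth = truth, pixel_size_um = pixel_size_um,
                 n_dropped = n_dropped),
            class = "qcs_roi")
}
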