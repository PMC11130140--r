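#' Stain basis for colour deconvolution
#'
#' Unit absorbance vectors of the stains in RGB space. The default is the
#' Ruifrok-Johnston H-DAB basis (hematoxylin counterstain, DAB chromogen) with
#' a third residual vector orthogonal to both, so the 3x3 system is
#' invertible.
#'
#' @param hematoxylin,dab Length-3 absorbance direction vectors (need not be
#'   normalised).
#' @return 3x3 matrix with rows `hematoxylin`, `dab`, `residual`, each of
#'   unit length.
#' @export
stain_basis <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.268, 0.570, 0.776)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  if (sqrt(sum(r^2)) < 1e-8)
    stop("singular stain basis: hematoxylin and DAB vectors are collinear")
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

#' DAB optical density map from an RGB image
#'
#' Converts an RGB brightfield image to per-channel base-10 absorbance
#' `A_c = -log10(I_c / I0)` and projects it onto the DAB stain vector by
#' inverting the stain basis (colour deconvolution). The DAB coefficient is
#' scaled by `od_scale` to scaled OD units: the default scale of 100 means
#' one OD unit is 0.01 absorbance, so the perceptual staining range from very
#' faint (about 6) to very strong (about 120) maps onto absorbances 0.06-1.2.
#'
#' Saturated-black pixels are clipped at `max_od`; small negative
#' deconvolution coefficients (noise) are clipped at zero, so the map is
#' non-negative and finite everywhere.
#'
#' @param rgb Numeric array `H x W x 3` of intensities in `[0, maxval]`.
#' @param basis Stain basis from [stain_basis()] (rows: stains).
#' @param od_scale Scaled OD units per unit absorbance (default 100).
#' @param maxval White level (255 for 8-bit, 65535 for 16-bit input).
#' @param max_od Clip value in scaled OD units for saturated pixels.
#' @param pixel_size_um Physical pixel size, stored as an attribute.
#' @return `H x W` matrix of DAB OD in scaled OD units with attribute
#'   `pixel_size_um`.
#' @export
deconvolve_dab <- function(rgb, basis = stain_basis(), od_scale = 100,
                           maxval = 255, max_od = 300,
                           pixel_size_um = NA_real_) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be an H x W x 3 array")
  if (abs(det(basis)) < 1e-8) stop("singular stain basis")
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  flat <- matrix(rgb, ncol = 3)
  flat <- pmax(flat, maxval * 10^(-max_od / od_scale)) # saturated-black clip
  a <- -log10(flat / maxval)
  conc <- a %*% solve(basis)
  od <- conc[, 2] * od_scale
  od <- pmin(pmax(od, 0), max_od)
  out <- matrix(od, nrow = nr, ncol = nc)
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}
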