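# Small image-morphology helpers shared by the renderer and the segmenter.
# Images are plain numeric/integer matrices, row = y, col = x, 0-based physical
# coordinates via the pixel size.

shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# One 8-connected erosion of a label image: a pixel keeps its label only if
# all 8 neighbours (image border counts as background) carry the same label.
label_erode <- function(lab) {
  keep <- lab > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    keep <- keep & (shift_mat(lab, dr, dc, fill = 0L) == lab)
  }
  out <- lab
  out[!keep] <- 0L
  out
}

# Membrane band: instance pixels within `depth` 8-connected erosions of the
# instance boundary (boundaries between touching instances included). Depth is
# the band thickness in pixels.
membrane_band <- function(lab, depth = 3L) {
  e <- lab
  for (i in seq_len(depth)) e <- label_erode(e)
  lab > 0 & e == 0L
}

# Separable 3x3 binomial blur ([1 2 1]/4 in both directions), zero padding.
blur3 <- function(m) {
  h <- (shift_mat(m, 0, -1) + 2 * m + shift_mat(m, 0, 1)) / 4
  (shift_mat(h, -1, 0) + 2 * h + shift_mat(h, 1, 0)) / 4
}

# Boundary pixels of one mask: mask pixels with a 4-neighbour outside the mask
# (image border counts as outside).
mask_boundary <- function(mask) {
  inner <- mask &
    shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
    shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE)
  mask & !inner
}
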