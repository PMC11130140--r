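#' Seeded-watershed cell segmentation from posterior maps
#'
#' Classical instance segmentation of the post-network pipeline: cell
#' instances grow from the supplied cell centres by a seeded watershed with
#' the membrane posterior as energy (region growing stops against membrane
#' ridges; equal-energy plateaus are resolved in lexicographic pixel order),
#' restricted to the epithelium mask. Flooding follows the morphological
#' watershed semantics (the priority of a pixel is the maximum energy along
#' its growth path). Posterior plateaus - e.g. the interior of a shared
#' membrane band between touching cells - carry no boundary information of
#' their own, so contested plateau pixels are claimed by the contesting
#' region whose seed is nearest, which places the split on the midline
#' between the seeds; remaining exact ties fall back to lexicographic pixel
#' order. Seeds outside the epithelium are
#' dropped with a count; zero seeds give an empty segmentation. Within each
#' instance, nuclei are the pixels with nuclei posterior >= 0.5, the membrane
#' is a 2-4 pixel band along the instance boundary (watershed ridge), and the
#' cytoplasm is the remainder, so the three compartment masks are disjoint
#' and cover the instance exactly.
#'
#' @param membrane_post,nuclei_post Posterior maps in `[0, 1]` (matrices of
#'   identical size).
#' @param centers Data frame of seed points with pixel coordinates `x_px`,
#'   `y_px` (1-based) and optionally `cell_id`.
#' @param epithelium Logical mask of analysed epithelium.
#' @param band_px Membrane band thickness in pixels (2-4, default 3).
#' @return List of class `qcs_segmentation`: `instances` (integer label map),
#'   `compartments` (0 background, 1 membrane, 2 nucleus, 3 cytoplasm),
#'   `centers` (seed table with `label`), `band_px`, `n_dropped_seeds`.
#' @export
segment_cells <- function(membrane_post, nuclei_post, centers, epithelium,
                          band_px = 3L) {
  stopifnot(is.matrix(membrane_post), is.matrix(nuclei_post),
            all(dim(membrane_post) == dim(nuclei_post)),
            all(dim(membrane_post) == dim(epithelium)),
            band_px >= 2, band_px <= 4)
  if (any(membrane_post < 0 | membrane_post > 1) ||
      any(nuclei_post < 0 | nuclei_post > 1))
    stop("posterior maps must lie in [0, 1]")
  H <- nrow(membrane_post); W <- ncol(membrane_post)
  lab0 <- matrix(0L, H, W)
  lab0[!epithelium] <- -1L
  centers <- as.data.frame(centers)
  n_seeds <- nrow(centers)
  dropped <- 0L
  if (n_seeds > 0) {
    rr <- pmin(pmax(as.integer(round(centers$y_px)), 1L), H)
    cc <- pmin(pmax(as.integer(round(centers$x_px)), 1L), W)
    inside <- epithelium[cbind(rr, cc)]
    dropped <- sum(!inside)
    if (dropped > 0)
      warning(dropped, " seed(s) outside the epithelium mask were dropped")
    centers <- centers[inside, , drop = FALSE]
    centers$label <- seq_len(nrow(centers))
    lab0[cbind(rr[inside], cc[inside])] <- centers$label
  } else {
    centers$label <- integer(0)
  }
  lab <- if (nrow(centers) > 0) {
    cpp_watershed(membrane_post, centers$y_px, centers$x_px, lab0)
  } else {
    matrix(0L, H, W)
  }
  membrane <- membrane_band(lab, band_px)
  nucleus <- nuclei_post >= 0.5 & lab > 0 & !membrane
  comp <- matrix(0L, H, W)
  comp[lab > 0] <- 3L
  comp[nucleus] <- 2L
  comp[membrane] <- 1L
  structure(list(instances = lab, compartments = comp, centers = centers,
                 band_px = band_px, n_dropped_seeds = dropped),
            class = "qcs_segmentation")
}

#' Mean optical density per subcellular compartment
#'
#' Arithmetic mean of the OD map over every non-empty compartment of every
#' segmented cell; empty compartments give `NA`. Centroids are converted to
#' micrometres with the pixel size carried by the OD map (or given
#' explicitly).
#'
#' @param odmap OD matrix from [deconvolve_dab()] (same size as the
#'   segmentation).
#' @param seg A [segment_cells()] result.
#' @param pixel_size_um Pixel size; defaults to the OD map attribute.
#' @return Data frame with one row per cell: `cell_id`, `label`, centroid
#'   `x_um`, `y_um`, `od_membrane`, `od_cytoplasm`, `od_nucleus`, and
#'   per-compartment pixel counts.
#' @export
measure_compartment_od <- function(odmap, seg,
                                   pixel_size_um =
                                     attr(odmap, "pixel_size_um")) {
  stopifnot(inherits(seg, "qcs_segmentation"))
  if (!all(dim(odmap) == dim(seg$instances)))
    stop("OD map and segmentation dimensions differ")
  labs <- seg$centers$label
  if (length(labs) == 0)
    return(data.frame(cell_id = integer(), label = integer(),
                      x_um = numeric(), y_um = numeric(),
                      od_membrane = numeric(), od_cytoplasm = numeric(),
                      od_nucleus = numeric()))
  lab <- seg$instances
  comp <- seg$compartments
  idx <- which(lab > 0)
  li <- lab[idx]
  ci <- comp[idx]
  vi <- odmap[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  mean_by <- function(sel) {
    s <- rowsum(vi[sel], li[sel])
    n <- rowsum(rep(1, sum(sel)), li[sel])
    setNames((s / n)[, 1], rownames(s))
  }
  mem <- mean_by(ci == 1L)
  nuc <- mean_by(ci == 2L)
  cyt <- mean_by(ci == 3L)
  count_by <- function(sel) {
    n <- rowsum(rep(1L, sum(sel)), li[sel])
    setNames(n[, 1], rownames(n))
  }
  cx <- setNames((rowsum(cols, li) / rowsum(rep(1, length(li)), li))[, 1],
                 rownames(rowsum(cols, li)))
  cy <- setNames((rowsum(rows, li) / rowsum(rep(1, length(li)), li))[, 1],
                 rownames(rowsum(rows, li)))
  key <- as.character(labs)
  px <- if (is.na(pixel_size_um)) 1 else pixel_size_um
  data.frame(
    cell_id = if (!is.null(seg$centers$cell_id)) seg$centers$cell_id else
      labs,
    label = labs,
    x_um = unname((cx[key] - 0.5) * px),
    y_um = unname((cy[key] - 0.5) * px),
    od_membrane = unname(mem[key]),
    od_cytoplasm = unname(cyt[key]),
    od_nucleus = unname(nuc[key]),
    n_px_membrane = unname(count_by(ci == 1L)[key]),
    n_px_nucleus = unname(count_by(ci == 2L)[key]),
    n_px_cytoplasm = unname(count_by(ci == 3L)[key]))
}
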