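#' Per-patient QCS readouts
#'
#' The basic readouts aggregate the per-cell membrane optical density (OD)
#' distribution of one patient: OD quantiles and mean, the percentage of
#' OD-positive tumour cells at a threshold `t`
#' (`100 * #\{OD_i >= t\} / N`, inclusive comparison), and the density of
#' OD-positive cells per mm^2 of analysed epithelium. The spatial proximity
#' scores extend these with neighbourhood information to model the bystander
#' effect of antibody-drug conjugates: the binary SPS (bSPS) is the percentage
#' of tumour cells that are either OD-positive themselves or have at least one
#' OD-positive neighbour within radius `r`; the continuous SPS (cSPS) assigns
#' each cell a distance-weighted neighbourhood mean OD with linearly decreasing
#' weights `w_ij = 1 - d_ij / r` (self weight 1), normalised by the total
#' weight so that an isolated cell keeps its own OD and `r -> 0` recovers the
#' raw per-cell OD distribution.
#'
#' Neighbourhoods use Euclidean centroid distance with inclusive boundary
#' `d <= r` and exclude the cell itself. Quantiles use linear interpolation
#' between order statistics (type 7).
#'
#' @param sample A [qcs_sample()].
#' @param q Quantile level in percent (5..95) or `"mean"`.
#' @param od_threshold OD positivity threshold in scaled OD units.
#' @param r Neighbourhood radius in micrometres.
#' @param aggregation For [csps()]: `"mean"` or a quantile level in percent.
#' @return A scalar readout value ([od_quantile()], [pct_od_positive()],
#'   [positive_density()], [bsps()], [csps()], [stil_density()]) or a per-cell
#'   numeric vector ([csps_cell_values()]). Empty cell tables yield `NA`.
#' @seealso [expand_feature_grid()], [compute_readout_matrix()]
#' @export
od_quantile <- function(sample, q) {
  od <- sample$cells$od_membrane
  if (length(od) == 0) return(NA_real_)
  if (identical(q, "mean")) return(mean(od))
  stopifnot(is.numeric(q), q >= 0, q <= 100)
  unname(quantile(od, q / 100, type = 7))
}

#' @rdname od_quantile
#' @export
pct_od_positive <- function(sample, od_threshold) {
  od <- sample$cells$od_membrane
  if (length(od) == 0) return(NA_real_)
  100 * mean(od >= od_threshold)
}

#' @rdname od_quantile
#' @export
positive_density <- function(sample, od_threshold) {
  area <- sample$epithelium_area_mm2
  if (is.null(area) || is.na(area) || area <= 0)
    stop("positive_density requires epithelium_area_mm2 > 0")
  sum(sample$cells$od_membrane >= od_threshold) / area
}

# Neighbourhood statistics via uniform grid bucketing: for each cell, the
# maximum membrane OD among neighbours with d <= r, and the cSPS weighted sum
# and total weight. Neighbour contributions are accumulated in ascending cell
# index order so results are bit-identical to an all-pairs scan.
neighbor_stats <- function(x, y, od, r) {
  n <- length(x)
  max_neigh <- rep(-Inf, n)
  wsum <- numeric(n)
  wtot <- numeric(n)
  if (n == 0 || r <= 0)
    return(list(max_neigh = max_neigh, wsum = wsum, wtot = wtot))
  gx <- as.integer(floor((x - min(x)) / r))
  gy <- as.integer(floor((y - min(y)) / r))
  nbx <- max(gx) + 1L
  nby <- max(gy) + 1L
  bid <- gx + nbx * gy + 1L
  buckets <- split(seq_len(n), factor(bid, levels = seq_len(nbx * nby)))
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dy in -1:1) {
      gy2 <- gy[i] + dy
      if (gy2 < 0L || gy2 >= nby) next
      for (dx in -1:1) {
        gx2 <- gx[i] + dx
        if (gx2 < 0L || gx2 >= nbx) next
        cand <- c(cand, buckets[[gx2 + nbx * gy2 + 1L]])
      }
    }
    cand <- sort(cand)
    cand <- cand[cand != i]
    if (length(cand) == 0) next
    d <- sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2)
    keep <- d <= r
    if (!any(keep)) next
    cand <- cand[keep]
    d <- d[keep]
    max_neigh[i] <- max(od[cand])
    w <- 1 - d / r
    wsum[i] <- sum(w * od[cand])
    wtot[i] <- sum(w)
  }
  list(max_neigh = max_neigh, wsum = wsum, wtot = wtot)
}

#' @rdname od_quantile
#' @export
bsps <- function(sample, r, od_threshold) {
  cells <- sample$cells
  if (nrow(cells) == 0) return(NA_real_)
  ns <- neighbor_stats(cells$x_um, cells$y_um, cells$od_membrane, r)
  100 * mean(cells$od_membrane >= od_threshold |
               ns$max_neigh >= od_threshold)
}

#' @rdname od_quantile
#' @param normalize If `TRUE` (default) the weighted sum is divided by the
#'   total weight, making each per-cell value a convex combination of the
#'   neighbourhood's ODs with an exact `r -> 0` limit; `FALSE` returns the
#'   raw weighted sum (self-weight 1), whose magnitude grows with local
#'   cell density.
#' @export
csps_cell_values <- function(sample, r, normalize = TRUE) {
  cells <- sample$cells
  if (nrow(cells) == 0) return(numeric(0))
  ns <- neighbor_stats(cells$x_um, cells$y_um, cells$od_membrane, r)
  raw <- cells$od_membrane + ns$wsum
  if (normalize) raw / (1 + ns$wtot) else raw
}

#' @rdname od_quantile
#' @export
csps <- function(sample, r, aggregation = "mean", normalize = TRUE) {
  v <- csps_cell_values(sample, r, normalize = normalize)
  if (length(v) == 0) return(NA_real_)
  if (identical(aggregation, "mean")) return(mean(v))
  unname(quantile(v, as.numeric(aggregation) / 100, type = 7))
}

#' @rdname od_quantile
#' @export
stil_density <- function(sample) {
  area <- sample$tumor_center_area_mm2
  if (is.null(area) || is.na(area) || area <= 0)
    stop("stil_density requires tumor_center_area_mm2 > 0")
  sum(sample$tils$compartment == "stromal") / area
}
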