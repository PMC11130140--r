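#' Analytical-validation metrics for segmentation and OD concordance
#'
#' Standard agreement measures between a predicted and a reference
#' segmentation: Dice overlap of two masks (`2|A∩B| / (|A|+|B|)`; defined as
#' 1 when both masks are empty and 0 when exactly one is), F1 of centre
#' detection under greedy nearest-neighbour matching within a match radius,
#' average symmetric surface distance (ASSD) between two contours in
#' micrometres, and the Pearson correlation of paired OD measurements.
#'
#' @param pred,true Logical masks ([eval_dice()]), `data.frame`s with
#'   `x_um`/`y_um` columns or two-column matrices ([eval_f1_centers()]),
#'   logical masks whose boundaries are compared ([eval_assd()]), or paired
#'   numeric vectors ([eval_od_correlation()]).
#' @param match_radius_um Maximum centre-matching distance.
#' @param pixel_size_um Pixel size used to convert ASSD to micrometres.
#' @return [eval_dice()] a fraction in `[0, 1]`; [eval_f1_centers()] a list
#'   with `precision`, `recall`, `f1`, `n_matched`; [eval_assd()] a distance
#'   in micrometres; [eval_od_correlation()] Pearson's r.
#' @export
eval_dice <- function(pred, true) {
  a <- sum(pred); b <- sum(true)
  if (a == 0 && b == 0) return(1.0)
  if (a == 0 || b == 0) return(0.0)
  2 * sum(pred & true) / (a + b)
}

as_xy <- function(p) {
  if (is.data.frame(p)) cbind(p$x_um, p$y_um) else as.matrix(p)
}

#' @rdname eval_dice
#' @export
eval_f1_centers <- function(pred, true, match_radius_um) {
  p <- as_xy(pred); t <- as_xy(true)
  np <- nrow(p); nt <- nrow(t)
  if (np == 0 && nt == 0)
    return(list(precision = 1, recall = 1, f1 = 1, n_matched = 0L))
  if (np == 0 || nt == 0)
    return(list(precision = 0, recall = 0, f1 = 0, n_matched = 0L))
  d <- sqrt(outer(p[, 1], t[, 1], "-")^2 + outer(p[, 2], t[, 2], "-")^2)
  ord <- order(d)
  used_p <- logical(np); used_t <- logical(nt)
  n_matched <- 0L
  for (k in ord) {
    if (d[k] > match_radius_um) break
    i <- (k - 1L) %% np + 1L
    j <- (k - 1L) %/% np + 1L
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- used_t[j] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  precision <- n_matched / np
  recall <- n_matched / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = n_matched)
}

#' @rdname eval_dice
#' @export
eval_assd <- function(pred, true, pixel_size_um = 1) {
  pb <- which(mask_boundary(pred), arr.ind = TRUE)
  tb <- which(mask_boundary(true), arr.ind = TRUE)
  if (nrow(pb) == 0 || nrow(tb) == 0)
    stop("ASSD requires non-empty contours")
  d2 <- outer(pb[, 1], tb[, 1], "-")^2 + outer(pb[, 2], tb[, 2], "-")^2
  d_pt <- sqrt(apply(d2, 1, min))
  d_tp <- sqrt(apply(d2, 2, min))
  (mean(d_pt) + mean(d_tp)) / 2 * pixel_size_um
}

#' @rdname eval_dice
#' @export
eval_od_correlation <- function(pred, true) {
  stopifnot(length(pred) == length(true), length(pred) >= 3)
  cor(pred, true, use = "complete.obs")
}
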