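#' Remove non-informative readouts
#'
#' Drops zero-variance columns (a single unique value) and near-zero-variance
#' columns, defined as columns satisfying both of: the number of unique values
#' divided by the number of samples is < 0.1, and the ratio of the frequency
#' of the most common value to the frequency of the second most common value
#' is > 95:5. Column order is preserved.
#'
#' @param mat Numeric patients x readouts matrix.
#' @return The filtered matrix, with the dropped column names and triggering
#'   rule in attribute `"dropped"`.
#' @export
drop_non_informative <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  n <- nrow(mat)
  rule <- character(0)
  keep <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    v <- v[!is.na(v)]
    u <- length(unique(v))
    if (u <= 1) {
      keep[j] <- FALSE
      rule <- c(rule, setNames("zero_variance", colnames(mat)[j]))
      next
    }
    tab <- sort(table(v), decreasing = TRUE)
    nzv <- (u / n < 0.1) && (tab[1] / tab[2] > 95 / 5)
    keep[j] <- !nzv
    if (nzv) rule <- c(rule, setNames("near_zero_variance", colnames(mat)[j]))
  }
  out <- mat[, keep, drop = FALSE]
  attr(out, "dropped") <- rule
  out
}

#' Prune highly correlated readouts
#'
#' Iteratively removes one member of every readout pair with absolute Spearman
#' correlation at or above `rho`. At each step the pair with the largest
#' absolute correlation is processed first and the member with the larger mean
#' absolute correlation against all currently remaining readouts is discarded;
#' mean absolute correlations are re-evaluated after every removal. All ties
#' are broken by lexicographic readout name, which makes the surviving set
#' independent of the input column order.
#'
#' @param mat Numeric patients x readouts matrix with unique column names and
#'   no zero-variance columns (run [drop_non_informative()] first).
#' @param rho Correlation threshold (default 0.99).
#' @return The pruned matrix with dropped column names in attribute
#'   `"dropped"`. No surviving pair has absolute Spearman correlation
#'   >= `rho`.
#' @export
drop_correlated <- function(mat, rho = 0.99) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3)
  if (ncol(mat) < 2) {
    attr(mat, "dropped") <- character(0)
    return(mat)
  }
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("drop_correlated requires unique column names")
  vars <- apply(mat, 2, function(v) stats::var(v, na.rm = TRUE))
  if (any(vars == 0 | is.na(vars)))
    stop("zero-variance columns present; apply drop_non_informative() first")
  cm <- abs(cor(mat, method = "spearman", use = "pairwise.complete.obs"))
  diag(cm) <- 0
  alive <- colnames(mat)
  dropped <- character(0)
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    hits <- which(sub >= rho, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) == 0) break
    # pair with largest |rho|; ties by lexicographic pair name
    vals <- sub[hits]
    a <- rownames(sub)[hits[, 1]]
    b <- colnames(sub)[hits[, 2]]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    ord <- order(-vals, lo, hi)
    p1 <- lo[ord[1]]
    p2 <- hi[ord[1]]
    mac <- rowMeans(sub)  # mean |rho| against remaining set
    victim <- if (mac[p1] > mac[p2]) p1
              else if (mac[p2] > mac[p1]) p2
              else max(p1, p2)  # tie: discard lexicographically larger name
    dropped <- c(dropped, victim)
    alive <- setdiff(alive, victim)
  }
  out <- mat[, alive, drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
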