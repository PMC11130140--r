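#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator with right censoring, via [survival::survfit()].
#' The median is read from the curve as the first time at which the survival
#' probability drops to 0.5 or below; it is `NA` when the curve never reaches
#' 0.5.
#'
#' @param times Follow-up times (months); must be non-negative.
#' @param events Event indicators (1 = progression/death observed,
#'   0 = censored).
#' @return Object of class `qcs_km`: a list with step-function vectors `time`
#'   and `surv` (including the origin S(0) = 1), `n`, and `median`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tt <- c(0, fit$time)
  ss <- c(1, fit$surv)
  med <- if (any(ss <= 0.5)) tt[which(ss <= 0.5)[1]] else NA_real_
  structure(list(time = tt, surv = ss, n = length(times), median = med),
            class = "qcs_km")
}

#' @export
print.qcs_km <- function(x, ...) {
  cat(sprintf("<qcs_km> n = %d, median = %s\n", x$n,
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

# Restricted mean survival time: area under the KM curve up to tmax.
km_rmst <- function(km, tmax = max(km$time)) {
  keep <- km$time < tmax
  tt <- c(km$time[keep], tmax)
  ss <- km$surv[keep]
  sum(diff(tt) * ss)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) with ties handled by the
#' hypergeometric variance; the p-value is the chi-square upper tail. When the
#' variance is zero (e.g. identical groups after pooling ties) the statistic
#' is 0 and p = 1.
#'
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param group Two-level group labels (logical, 0/1, or factor-like).
#' @return List with `chisq`, `p`, `observed`, `expected` (group coded 1) and
#'   `variance`.
#' @export
logrank_test <- function(times, events, group) {
  if (length(times) != length(events) || length(times) != length(group))
    stop("times, events and group must have equal length")
  g <- as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2) stop("logrank_test requires exactly two groups")
  if (sum(events) < 1) stop("logrank_test requires at least one event")
  res <- cpp_logrank(as.numeric(times), as.integer(events), g)
  chisq <- unname(res["chisq"])
  list(chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = unname(res["observed1"]),
       expected = unname(res["expected1"]),
       variance = unname(res["variance"]))
}

#' Objective response rate
#'
#' Percentage of responders (complete or partial response) among all patients;
#' non-evaluable (NE) cases stay in the denominator as non-responders.
#'
#' @param best_response Character vector with levels CR, PR, SD, PD, NE.
#' @return ORR in percent, or `NA` on empty input.
#' @export
orr <- function(best_response) {
  if (length(best_response) == 0) return(NA_real_)
  bad <- setdiff(unique(best_response), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad) > 0)
    stop("invalid response categories: ", paste(bad, collapse = ", "))
  100 * mean(best_response %in% c("CR", "PR"))
}
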