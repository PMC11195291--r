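# Reliability and summary statistics: variance explained, Fisher z,
# Spearman and circular correlation for intersession reliability,
# behavioral performance, and eccentricity binning.

#' Variance explained by a prediction
#'
#' Squared Pearson correlation between data and prediction, the proportion
#' of variance in the time series explained by the model. Zero variance in
#' either input yields `NA`.
#'
#' @param data,prediction Equal-length numeric vectors or [timecourse()]s.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
variance_explained <- function(data, prediction) {
  r <- prf_objective(data, prediction)
  r^2
}

#' Fisher z transform of a correlation
#'
#' `Z = 0.5 * log((1 + r) / (1 - r)) = atanh(r)`. For `|r| >= 1` the
#' result is `+/-Inf` (flagged with a warning rather than silently
#' clipped).
#'
#' @param r Correlation coefficients.
#' @return Fisher z scores.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("|r| > 1 is not a correlation", call. = FALSE)
  if (any(abs(r) == 1, na.rm = TRUE))
    warning("|r| = 1: Fisher z is infinite")
  atanh(r)
}

#' Fisher-Lee circular correlation coefficient
#'
#' Pairwise definition
#' `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` normalized by the product of
#' the per-variable sums of squares; invariant to a common rotation of
#' either angle set. O(n^2) in the number of pairs.
#'
#' @param a,b Paired angles in radians.
#' @return Circular correlation in `[-1, 1]`.
#' @export
circular_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  da <- sin(outer(a, a, `-`))
  db <- sin(outer(b, b, `-`))
  up <- upper.tri(da)
  num <- sum(da[up] * db[up])
  den <- sqrt(sum(da[up]^2) * sum(db[up]^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Intersession reliability of a pRF parameter
#'
#' Correlates paired parameter estimates from two sessions: Spearman rank
#' correlation for linear parameters (eccentricity, size), the Fisher-Lee
#' circular correlation for polar angle. The correlation is also returned
#' as a Fisher z score.
#'
#' @param est_a,est_b Paired estimates (same units retained in both
#'   sessions). For `kind = "circular"`, angles in radians.
#' @param kind `"linear"` (Spearman) or `"circular"` (Fisher-Lee).
#' @return List of class `reliability_result`: `r`, `fisher_z`, `n`,
#'   `kind`. Fewer than 3 pairs gives `NA`s with a warning.
#' @export
reliability <- function(est_a, est_b, kind = c("linear", "circular")) {
  kind <- match.arg(kind)
  stopifnot(length(est_a) == length(est_b))
  ok <- is.finite(est_a) & is.finite(est_b)
  a <- est_a[ok]; b <- est_b[ok]
  n <- length(a)
  if (n < 3) {
    warning("fewer than 3 pairs: reliability undefined")
    r <- NA_real_
  } else if (kind == "linear") {
    r <- cor(a, b, method = "spearman")
  } else {
    r <- circular_cor(a, b)
  }
  z <- if (is.na(r)) NA_real_ else if (abs(r) >= 1) {
    warning("|r| = 1: Fisher z is infinite")
    sign(r) * Inf
  } else atanh(r)
  structure(list(r = r, fisher_z = z, n = n, kind = kind),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability:%s> r = %.4f (Z = %.4f), n = %d\n",
              x$kind, x$r, x$fisher_z, x$n))
  invisible(x)
}

#' Behavioral performance on the fixation task
#'
#' `(n_hit - n_false_alarms) / n_total * 100`, where hits are button
#' presses within 1 s of a fixation-color change and `n_total` is the
#' number of color changes.
#'
#' @param n_hit Number of detected color changes.
#' @param n_false_alarms Responses without a color change.
#' @param n_total Total color changes, > 0.
#' @return Performance in percent.
#' @export
behavioral_performance <- function(n_hit, n_false_alarms, n_total) {
  stopifnot(n_total > 0, n_hit >= 0, n_false_alarms >= 0, n_hit <= n_total)
  (n_hit - n_false_alarms) / n_total * 100
}

#' Bin values by eccentricity
#'
#' Per-bin mean and standard error of the mean; empty bins are reported as
#' `NA` rows, not dropped.
#'
#' @param values Numeric values (e.g. pRF sizes).
#' @param eccentricities Matching eccentricities in degrees.
#' @param bins Bin edges (default `ecc_bins()`).
#' @return Data frame with `bin`, `ecc_lo`, `ecc_hi`, `n`, `mean`, `sem`.
#' @export
bin_by_eccentricity <- function(values, eccentricities, bins = ecc_bins()) {
  stopifnot(length(values) == length(eccentricities))
  idx <- findInterval(eccentricities, bins, rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(length(bins) - 1),
                    ecc_lo = bins[-length(bins)], ecc_hi = bins[-1],
                    n = 0L, mean = NA_real_, sem = NA_real_)
  for (b in out$bin) {
    v <- values[idx == b & !is.na(values)]
    out$n[b] <- length(v)
    if (length(v)) {
      out$mean[b] <- mean(v)
      out$sem[b] <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    }
  }
  out
}
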