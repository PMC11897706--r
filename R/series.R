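#' Ordered observations with non-negative weights
#'
#' The single-track container used by the Gaussian and Poisson loss families.
#' Positions with weight zero contribute no loss but keep their place in the
#' index space, so changepoint indices are unaffected by masking.
#'
#' @param values numeric vector of observations, one per position.
#' @param weights non-negative numeric vector of the same length, default all 1.
#' @return An object of class `weighted_series` with fields `values` and
#'   `weights`.
#' @examples
#' weighted_series(c(1, 3, 10), weights = c(1, 1, 0.5))
#' @export
weighted_series <- function(values, weights = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop("'values' must have length >= 1")
  if (anyNA(values)) stop("'values' must not contain NA/NaN")
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("'weights' must match 'values' in length")
  if (anyNA(weights) || any(weights < 0)) stop("'weights' must be non-negative and non-missing")
  structure(list(values = values, weights = weights),
            class = "weighted_series")
}

#' Paired methylated/total counts with weights
#'
#' The dual-track container for the binomial loss: at each covered cytosine,
#' `meth` methylated reads out of `total` reads.  Both counts are kept; the
#' methylation fraction (beta value) is never pre-computed by rounding, so low
#' and high coverage positions carry their proper evidence.
#'
#' @param meth non-negative numeric vector of methylated read counts.
#' @param total non-negative numeric vector of total read counts,
#'   `meth <= total` elementwise.
#' @param weights non-negative numeric vector, default all 1.
#' @return An object of class `dual_count_series` with fields `meth`, `total`
#'   and `weights`.
#' @examples
#' dual_count_series(meth = c(3, 9), total = c(10, 10))
#' @export
dual_count_series <- function(meth, total, weights = NULL) {
  meth <- as.numeric(meth)
  total <- as.numeric(total)
  n <- length(meth)
  if (n < 1L) stop("'meth' must have length >= 1")
  if (length(total) != n) stop("'meth' and 'total' must have equal length")
  if (anyNA(meth) || anyNA(total)) stop("counts must not contain NA/NaN")
  if (any(meth < 0) || any(total < 0)) stop("counts must be non-negative")
  if (any(meth > total)) stop("'meth' must not exceed 'total'")
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("'weights' must match counts in length")
  if (anyNA(weights) || any(weights < 0)) stop("'weights' must be non-negative and non-missing")
  structure(list(meth = meth, total = total, weights = weights),
            class = "dual_count_series")
}

#' @export
length.weighted_series <- function(x) length(x$values)

#' @export
length.dual_count_series <- function(x) length(x$meth)

#' @export
print.weighted_series <- function(x, ...) {
  cat("<weighted_series> n =", length(x), "\n")
  cat("  values:", utils::head(signif(x$values, 4), 8),
      if (length(x) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
print.dual_count_series <- function(x, ...) {
  cat("<dual_count_series> n =", length(x), "\n")
  cat("  meth/total:",
      paste0(utils::head(x$meth, 6), "/", utils::head(x$total, 6)),
      if (length(x) > 6) "...\n" else "\n")
  invisible(x)
}

# subset a series keeping class (internal)
series_subset <- function(series, idx) {
  if (inherits(series, "dual_count_series")) {
    dual_count_series(series$meth[idx], series$total[idx], series$weights[idx])
  } else {
    weighted_series(series$values[idx], series$weights[idx])
  }
}
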