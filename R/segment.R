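#' Optimal constant fit for one index range
#'
#' Closed-form minimizer and minimum of the summed loss of a single segment.
#' The optimum on the mean scale is the weighted mean (Gaussian), the weighted
#' mean count, i.e. rate (Poisson), or the pooled fraction
#' \eqn{\sum w y_1 / \sum w y_2} (binomial).  Extreme sufficient statistics
#' (all-zero Poisson counts, binomial fraction exactly 0 or 1) clamp the
#' natural parameter to \eqn{\pm 30} so arithmetic stays finite.
#'
#' @param series a [weighted_series()] (gaussian/poisson) or
#'   [dual_count_series()] (binomial).
#' @param family one of `"gaussian"`, `"poisson"`, `"binomial"`.
#' @param from,to 1-based inclusive index range.
#' @return A list with `theta` (natural parameter at the optimum), `value`
#'   (the optimum on the mean scale) and `cost` (the minimized loss, additive
#'   constants in the data dropped).
#' @examples
#' segment_stats(weighted_series(c(1, 3)), "gaussian", 1, 2)  # mean 2, cost 1
#' @export
segment_stats <- function(series, family = c("gaussian", "poisson", "binomial"),
                          from = 1L, to = length(series)) {
  family <- check_family_series(series, family)
  n <- length(series)
  if (from < 1 || to > n || from > to) stop("invalid index range [", from, ", ", to, "]")
  idx <- from:to
  w <- series$weights[idx]
  if (family == "gaussian") {
    y <- series$values[idx]
    sw <- sum(w)
    if (sw == 0) return(list(theta = 0, value = 0, cost = 0))
    mu <- sum(w * y) / sw
    list(theta = mu, value = mu, cost = sum(w * y^2) / 2 - sw * mu^2 / 2)
  } else if (family == "poisson") {
    y <- series$values[idx]
    A <- sum(w)
    B <- sum(w * y)
    if (A == 0) return(list(theta = -THETA_CLAMP, value = 0, cost = 0))
    theta <- if (B > 0) log(B / A) else -THETA_CLAMP
    theta <- min(max(theta, -THETA_CLAMP), THETA_CLAMP)
    list(theta = theta, value = B / A, cost = A * exp(theta) - B * theta)
  } else {
    A <- sum(w * series$total[idx])
    B <- sum(w * series$meth[idx])
    if (A == 0) return(list(theta = 0, value = NA_real_, cost = 0))
    p <- B / A
    theta <- mean_to_theta(p, "binomial")
    list(theta = theta, value = p, cost = A * log1pexp(theta) - B * theta)
  }
}

new_segmentation <- function(seg_start, seg_end, theta, values, objective,
                             family, penalty, lambda, n, mean_pieces) {
  k <- length(seg_start)
  structure(list(
    breakpoints = if (k > 1) seg_end[-k] else integer(0),
    seg_start = as.integer(seg_start),
    seg_end = as.integer(seg_end),
    segment_params = theta,
    segment_values = values,
    objective = objective,
    family = family,
    penalty = penalty,
    lambda = lambda,
    n = as.integer(n),
    mean_pieces = mean_pieces
  ), class = "segmentation")
}

#' Exact L0-penalized segmentation
#'
#' Finds a global minimizer of
#' \deqn{\sum_i e(\beta_i, y_i) + \lambda \sum_i 1\{\beta_i \neq \beta_{i+1}\}}
#' by a functional-pruning dynamic program: a forward pass maintains the
#' running objective as a piecewise convex envelope of the current segment's
#' natural parameter, applying at each step the pointwise minimum with the
#' restart branch (envelope minimum plus \eqn{\lambda}); a backward pass
#' assigns the minimizer of the final envelope and copies it backwards,
#' emitting a changepoint wherever the stored provenance says the restart
#' branch was taken.  When continue and restart branches tie exactly, the
#' continue branch wins, so output is deterministic and parsimonious.
#'
#' @inheritParams segment_stats
#' @param lambda non-negative penalty per changepoint.
#' @return A `segmentation` object: `breakpoints` (positions \eqn{i} with a
#'   change between \eqn{i} and \eqn{i+1}), `seg_start`/`seg_end`,
#'   `segment_params` (natural-parameter optima), `segment_values`
#'   (mean / rate / fraction per segment, always the closed-form weighted
#'   statistic of the segment's own data), `objective`, and `mean_pieces`
#'   (average envelope size per position, a linear-scaling diagnostic).
#' @examples
#' s <- weighted_series(c(0, 0, 10, 10))
#' l0_segment(s, "gaussian", lambda = 1)
#' @seealso [l1_segment()], [select_lambda()], [reconstruct()]
#' @export
l0_segment <- function(series, family = c("gaussian", "poisson", "binomial"),
                       lambda) {
  family <- check_family_series(series, family)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  co <- family_coeffs(series, family)
  dom <- family_domain(series, family)
  fit <- l0_segment_cpp(co$da, co$db, co$dc, family_code(family), lambda,
                        dom[1], dom[2])
  k <- length(fit$seg_start)
  values <- vapply(seq_len(k), function(j) {
    segment_stats(series, family, fit$seg_start[j], fit$seg_end[j])$value
  }, numeric(1))
  new_segmentation(fit$seg_start, fit$seg_end, fit$theta, values,
                   fit$objective, family, "L0", lambda, length(series),
                   fit$mean_pieces)
}

#' Exact fused-lasso (L1) segmentation
#'
#' Solves the convex counterpart of [l0_segment()], penalizing
#' \eqn{\lambda \sum_i |\theta_i - \theta_{i+1}|} where \eqn{\theta} is the
#' loss family's natural parameter (mean, log-rate, or log-odds).  The forward
#' pass clips the derivative of the running envelope at \eqn{\mp\lambda}
#' (an inf-convolution with \eqn{\lambda|\cdot|}); the backward pass clamps
#' each position's parameter to the stored clipping interval.  Unlike L0, the
#' fitted segment values are shrunk towards their neighbours.
#'
#' @inheritParams l0_segment
#' @return A `segmentation` object; `segment_values` are the fitted
#'   (shrunken) values on the mean scale.
#' @examples
#' l1_segment(weighted_series(c(0, 10)), "gaussian", lambda = 2)  # fits 2, 8
#' @export
l1_segment <- function(series, family = c("gaussian", "poisson", "binomial"),
                       lambda) {
  family <- check_family_series(series, family)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  co <- family_coeffs(series, family)
  dom <- family_domain(series, family)
  fit <- l1_segment_cpp(co$da, co$db, co$dc, family_code(family), lambda,
                        dom[1], dom[2])
  theta <- fit$theta
  n <- length(theta)
  tol <- 1e-9 * pmax(1, abs(theta[-n]))
  change <- which(abs(diff(theta)) > tol)
  seg_start <- c(1L, change + 1L)
  seg_end <- c(change, n)
  seg_theta <- theta[seg_start]
  new_segmentation(seg_start, seg_end, seg_theta,
                   theta_to_mean(seg_theta, family),
                   fit$objective, family, "L1", lambda, n, fit$mean_pieces)
}

#' Expand a segmentation to a per-position fitted vector
#'
#' @param seg a `segmentation`.
#' @param n series length; defaults to the length the segmentation was fit on.
#' @return Numeric vector of length `n` holding each position's segment value
#'   on the mean scale.
#' @export
reconstruct <- function(seg, n = seg$n) {
  stopifnot(inherits(seg, "segmentation"))
  if (n != seg$n) stop("segmentation was fit on a series of length ", seg$n)
  rep(seg$segment_values, seg$seg_end - seg$seg_start + 1L)
}

#' @export
fitted.segmentation <- function(object, ...) reconstruct(object)

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s %s, lambda = %g\n", x$family, x$penalty, x$lambda))
  cat(sprintf("  n = %d, segments = %d (compression %.1fx), objective = %.6g\n",
              x$n, length(x$segment_values),
              x$n / length(x$segment_values), x$objective))
  k <- min(length(x$segment_values), 6)
  cat("  values:", signif(x$segment_values[seq_len(k)], 4),
      if (length(x$segment_values) > k) "...\n" else "\n")
  invisible(x)
}

#' Number of segments of a fit
#' @param seg a `segmentation`.
#' @return Integer segment count.
#' @export
n_segments <- function(seg) length(seg$segment_values)
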