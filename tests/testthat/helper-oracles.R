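# Independent oracles used across the suite.  These deliberately avoid the
# package's DP code paths: exhaustive enumeration for L0, projected gradient
# on the dual for the Gaussian fused lasso, dense grids for envelopes.

# exhaustive minimum of the L0 objective over all 2^(N-1) changepoint sets,
# with per-segment costs from the closed forms
brute_force_l0 <- function(series, family, lambda) {
  n <- length(series)
  cost <- matrix(NA_real_, n, n)
  for (s in 1:n) for (e in s:n)
    cost[s, e] <- segment_stats(series, family, s, e)$cost
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cps <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    ss <- c(1L, cps + 1L)
    ee <- c(cps, n)
    tot <- lambda * length(cps) + sum(cost[cbind(ss, ee)])
    if (tot < best) best <- tot
  }
  best
}

# exact-enough Gaussian fused lasso via projected gradient on the dual box;
# beta = y - W^{-1} D' u with u constrained to [-lambda, lambda]^(n-1)
tv_gaussian_oracle <- function(y, w, lambda, iters = 60000) {
  n <- length(y)
  D <- diff(diag(n))
  u <- rep(0, n - 1)
  winv <- 1 / w
  step <- 1 / (4 * max(winv))
  for (i in seq_len(iters)) {
    beta <- y - winv * drop(crossprod(D, u))
    u <- pmin(lambda, pmax(-lambda, u + step * drop(D %*% beta)))
  }
  y - winv * drop(crossprod(D, u))
}

# random series per family for property loops
random_series <- function(family, n, rng = NULL) {
  if (family == "gaussian") {
    weighted_series(rnorm(n, 0, 3), runif(n, 0.5, 2))
  } else if (family == "poisson") {
    weighted_series(rpois(n, sample(c(1, 5, 20), 1)), runif(n, 0.5, 2))
  } else {
    tot <- rpois(n, 10)
    tot[tot == 0] <- 1
    dual_count_series(rbinom(n, tot, runif(1, 0.05, 0.95)), tot)
  }
}

series_subset_for_test <- function(values, idx) weighted_series(values[idx])

# per-position segment labels of a fit
segment_labels <- function(fit) {
  rep(seq_along(fit$segment_values), fit$seg_end - fit$seg_start + 1L)
}

# closed-form mean-scale optimum per segment, recomputed from the raw data
closed_form_values <- function(series, family, fit) {
  vapply(seq_along(fit$seg_start), function(j) {
    idx <- fit$seg_start[j]:fit$seg_end[j]
    w <- series$weights[idx]
    if (family == "binomial") {
      sum(w * series$meth[idx]) / sum(w * series$total[idx])
    } else {
      sum(w * series$values[idx]) / sum(w)
    }
  }, numeric(1))
}
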