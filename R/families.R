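# Loss-family internals.
#
# Every per-datum loss is recorded as a coefficient triple (a, b, c) so that a
# partial-sum objective, as a function of the shared segment parameter theta,
# is a * g1(theta) + b * theta + c with
#   gaussian:  g1 = theta^2,          theta = mean,      e = w/2 * (y - theta)^2
#   poisson:   g1 = exp(theta),       theta = log rate,  e = w * (exp(theta) - y * theta)
#   binomial:  g1 = log(1+e^theta),   theta = log-odds,  e = w * (y2 * log(1+e^theta) - y1 * theta)
# Additive constants independent of theta (log y!, log choose(y2, y1)) are
# dropped, so objectives are comparable only within a family.

FAMILIES <- c("gaussian", "poisson", "binomial")

# natural-parameter clamp for families whose optima can diverge
# (poisson all-zero counts, binomial fraction 0 or 1)
THETA_CLAMP <- 30

family_code <- function(family) {
  match(match.arg(family, FAMILIES), FAMILIES) - 1L
}

check_family_series <- function(series, family) {
  family <- match.arg(family, FAMILIES)
  dual <- inherits(series, "dual_count_series")
  single <- inherits(series, "weighted_series")
  if (!dual && !single) stop("series must be a weighted_series or dual_count_series")
  if (family == "binomial" && !dual)
    stop("binomial loss requires a dual_count_series")
  if (family != "binomial" && !single)
    stop(family, " loss requires a weighted_series")
  if (family == "poisson" && any(series$values < 0))
    stop("poisson loss requires non-negative values")
  family
}

# per-datum coefficient triples, vectorized over the series
family_coeffs <- function(series, family) {
  w <- series$weights
  switch(family,
    gaussian = list(da = w / 2, db = -w * series$values, dc = w * series$values^2 / 2),
    poisson  = list(da = w, db = -w * series$values, dc = rep(0, length(w))),
    binomial = list(da = w * series$total, db = -w * series$meth, dc = rep(0, length(w)))
  )
}

# theta domain over which envelopes are maintained; any candidate segment
# optimum lies inside it
family_domain <- function(series, family) {
  if (family == "gaussian") {
    y <- series$values[series$weights > 0]
    if (!length(y)) y <- series$values
    r <- diff(range(y))
    pad <- r + 1
    c(min(y) - pad, max(y) + pad)
  } else {
    c(-THETA_CLAMP, THETA_CLAMP)
  }
}

theta_to_mean <- function(theta, family) {
  switch(family,
    gaussian = theta,
    poisson  = exp(theta),
    binomial = stats::plogis(theta)
  )
}

mean_to_theta <- function(mu, family) {
  switch(family,
    gaussian = mu,
    poisson  = log(pmax(mu, exp(-THETA_CLAMP))),
    binomial = pmin(pmax(stats::qlogis(mu), -THETA_CLAMP), THETA_CLAMP)
  )
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

# held-out negative log-likelihood (same dropped-constant convention as the
# fitting objective), given predictions on the mean scale
family_nll <- function(series, idx, pred, family) {
  w <- series$weights[idx]
  if (family == "gaussian") {
    sum(w / 2 * (series$values[idx] - pred)^2)
  } else if (family == "poisson") {
    mu <- pmax(pred, exp(-THETA_CLAMP))
    sum(w * (mu - series$values[idx] * log(mu)))
  } else {
    alpha <- mean_to_theta(pred, "binomial")
    sum(w * (series$total[idx] * log1pexp(alpha) - series$meth[idx] * alpha))
  }
}
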