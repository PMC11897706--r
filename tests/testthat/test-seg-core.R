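test_that("series constructors enforce their invariants", {
  expect_error(weighted_series(numeric(0)), "length")
  expect_error(weighted_series(c(1, NA)), "NA")
  expect_error(weighted_series(1:3, weights = c(1, -1, 1)), "non-negative")
  expect_error(dual_count_series(c(5, 1), c(4, 2)), "exceed")
  expect_error(dual_count_series(c(-1), c(2)), "non-negative")
  expect_silent(dual_count_series(c(0, 2), c(0, 2)))
  expect_error(l0_segment(weighted_series(c(1, -2)), "poisson", 1), "non-negative")
  expect_error(l0_segment(weighted_series(1:3), "binomial", 1), "dual_count_series")
  expect_error(l0_segment(dual_count_series(1, 2), "gaussian", 1), "weighted_series")
})

test_that("segment_stats returns the closed-form optimum per family", {
  # symmetric two-point gaussian: mean 2, cost 1 under e = w/2 (y - mu)^2
  st <- segment_stats(weighted_series(c(1, 3)), "gaussian", 1, 2)
  expect_equal(st$value, 2)
  expect_equal(st$cost, 1)
  # weighted fraction 12/20
  st <- segment_stats(dual_count_series(c(3, 9), c(10, 10)), "binomial", 1, 2)
  expect_equal(st$value, 0.6)
  # poisson rate 3, cost 6 - 6 log 3, matching a dense grid over theta
  st <- segment_stats(weighted_series(c(2, 4)), "poisson", 1, 2)
  expect_equal(st$value, 3)
  expect_equal(st$cost, 6 - 6 * log(3), tolerance = 1e-12)
  grid <- seq(-3, 3, length.out = 20001)
  expect_equal(st$cost, min(2 * exp(grid) - 6 * grid), tolerance = 1e-6)
  # extreme sufficient statistics clamp the natural parameter
  expect_equal(segment_stats(weighted_series(c(0, 0)), "poisson")$theta, -30)
  expect_equal(segment_stats(dual_count_series(c(5, 5), c(5, 5)), "binomial")$theta, 30)
  expect_error(segment_stats(weighted_series(1:3), "gaussian", 3, 2), "range")
})

test_that("l0_segment solves small hand-checkable instances exactly", {
  f <- l0_segment(weighted_series(c(0, 0, 10, 10)), "gaussian", 1)
  expect_equal(f$breakpoints, 2L)
  expect_equal(f$segment_values, c(0, 10))
  expect_equal(f$objective, 1)
  # penalty dominates: single segment at the global weighted statistic
  f <- l0_segment(weighted_series(c(0, 0, 10, 10)), "gaussian", 1e9)
  expect_equal(n_segments(f), 1L)
  expect_equal(f$segment_values, 5)
  f <- l0_segment(dual_count_series(c(3, 9), c(10, 10)), "binomial", 1e9)
  expect_equal(f$segment_values, 0.6)
  # poisson two-block instance
  f <- l0_segment(weighted_series(c(2, 2, 8, 8)), "poisson", 0.5)
  expect_equal(f$breakpoints, 2L)
  expect_equal(f$segment_values, c(2, 8))
  # zero penalty reproduces the data exactly (gaussian)
  y <- c(3.2, -1, 0.5, 7)
  expect_equal(reconstruct(l0_segment(weighted_series(y), "gaussian", 0)), y)
  expect_error(l0_segment(weighted_series(1:3), "gaussian", -1), "non-negative")
})

test_that("the DP objective equals exhaustive brute force on random instances", {
  set.seed(401)
  for (family in c("gaussian", "poisson", "binomial")) {
    for (trial in 1:12) {
      n <- sample(4:9, 1)
      s <- random_series(family, n)
      lambda <- runif(1, 0.05, 4)
      fit <- l0_segment(s, family, lambda)
      expect_equal(fit$objective, brute_force_l0(s, family, lambda),
                   tolerance = 1e-8)
      # reported objective is consistent with its own breakpoints
      recomputed <- lambda * length(fit$breakpoints) +
        sum(vapply(seq_along(fit$seg_start), function(j)
          segment_stats(s, family, fit$seg_start[j], fit$seg_end[j])$cost,
          numeric(1)))
      expect_equal(fit$objective, recomputed, tolerance = 1e-8)
    }
  }
})

test_that("fitted L0 segment values are the weighted mean / rate / fraction", {
  set.seed(402)
  for (family in c("gaussian", "poisson", "binomial")) {
    for (trial in 1:10) {
      s <- random_series(family, 40)
      fit <- l0_segment(s, family, runif(1, 0.1, 10))
      expect_equal(fit$segment_values, closed_form_values(s, family, fit),
                   tolerance = 1e-9)
      # natural-parameter optima agree on the mean scale as well
      mean_scale <- switch(family, gaussian = fit$segment_params,
                           poisson = exp(fit$segment_params),
                           binomial = plogis(fit$segment_params))
      expect_equal(mean_scale, fit$segment_values, tolerance = 1e-9)
    }
  }
})

test_that("segment count is non-increasing in lambda and hits both limits", {
  set.seed(403)
  for (family in c("gaussian", "poisson", "binomial")) {
    s <- random_series(family, 60)
    grid <- c(0, 10^seq(-3, 6, length.out = 16))
    counts <- vapply(grid, function(l) n_segments(l0_segment(s, family, l)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[length(counts)], 1)
  }
  # lambda = 0 gaussian: per-point fit, zero data loss
  y <- rnorm(20)
  f <- l0_segment(weighted_series(y), "gaussian", 0)
  expect_equal(f$objective, 0, tolerance = 1e-10)
  expect_equal(reconstruct(f), y)
})

test_that("gaussian L0 is equivariant under affine data transforms", {
  set.seed(404)
  y <- rnorm(50, 0, 2)
  w <- runif(50, 0.5, 2)
  lambda <- 0.8
  base <- l0_segment(weighted_series(y, w), "gaussian", lambda)
  for (ab in list(c(3, -2), c(0.25, 10))) {
    a <- ab[1]; b <- ab[2]
    tr <- l0_segment(weighted_series(a * y + b, w), "gaussian", a^2 * lambda)
    expect_equal(tr$breakpoints, base$breakpoints)
    expect_equal(tr$segment_values, a * base$segment_values + b,
                 tolerance = 1e-8)
  }
})

test_that("zero-weight positions carry no loss but keep their index", {
  y <- c(0, 0, 100, 10, 10)
  w <- c(1, 1, 0, 1, 1)
  f <- l0_segment(weighted_series(y, w), "gaussian", 1)
  expect_equal(f$breakpoints, 2L)      # the outlier at the masked position is free
  expect_equal(f$segment_values, c(0, 10))
})

test_that("l1_segment matches closed forms and the convex dual oracle", {
  # two-point fused lasso: mu = (y1 + lambda, y2 - lambda) while unfused
  f <- l1_segment(weighted_series(c(0, 10)), "gaussian", 2)
  expect_equal(reconstruct(f), c(2, 8))
  # lambda past the fusion threshold (y2 - y1)/2 forces the mean
  f <- l1_segment(weighted_series(c(0, 10)), "gaussian", 6)
  expect_equal(reconstruct(f), c(5, 5))
  # no penalty: exact interpolation
  y <- c(0.5, 10, 3)
  expect_equal(reconstruct(l1_segment(weighted_series(y), "gaussian", 0)), y)
  # random instances against projected gradient on the dual box
  set.seed(405)
  for (trial in 1:4) {
    n <- sample(10:50, 1)
    y <- rnorm(n, 0, 5)
    w <- if (trial %% 2) rep(1, n) else runif(n, 0.5, 2)
    lambda <- runif(1, 0.3, 4)
    fit <- reconstruct(l1_segment(weighted_series(y, w), "gaussian", lambda))
    expect_equal(fit, tv_gaussian_oracle(y, w, lambda), tolerance = 1e-6)
  }
})

test_that("reconstruct expands segments and round-trips the zero-penalty fit", {
  seg <- l0_segment(weighted_series(c(0, 0, 10, 10)), "gaussian", 1)
  expect_equal(reconstruct(seg), c(0, 0, 10, 10))
  expect_equal(fitted(seg), reconstruct(seg))
  one <- l0_segment(weighted_series(rep(7, 5)), "gaussian", 1)
  expect_equal(reconstruct(one), rep(7, 5))
  expect_error(reconstruct(seg, n = 7), "length")
})
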