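# The envelope operations are the DP's internals exposed; their contracts are
# checked against dense-grid pointwise oracles.

test_that("adding a datum shifts every piece by the datum's loss", {
  # empty gaussian envelope + datum y=5, w=1 -> single piece theta^2/2 - 5 theta + 12.5
  env <- envelope_new("gaussian", domain = c(-20, 20))
  env <- envelope_add_datum(env, y = 5, w = 1)
  expect_equal(env$pieces$a, 0.5)
  expect_equal(env$pieces$b, -5)
  expect_equal(env$pieces$c, 12.5)
  grid <- seq(-20, 20, length.out = 101)
  expect_equal(envelope_eval(env, grid), 0.5 * (grid - 5)^2, tolerance = 1e-12)

  # with several pieces all (a, b, c) shift identically
  env2 <- envelope_l0_step(env, lambda = 2)$envelope
  before <- env2$pieces
  env3 <- envelope_add_datum(env2, y = 1, w = 2)
  expect_equal(env3$pieces$a - before$a, rep(1, length(before$a)))
  expect_equal(env3$pieces$b - before$b, rep(-2, length(before$b)))
  expect_equal(env3$pieces$c - before$c, rep(1, length(before$c)))
})

test_that("envelope addition matches the pointwise sum on a dense grid", {
  set.seed(406)
  for (family in c("gaussian", "poisson", "binomial")) {
    dom <- if (family == "gaussian") c(-15, 15) else c(-30, 30)
    env <- envelope_new(family, domain = dom)
    # build a random multi-piece envelope by a few data + restart steps
    for (i in 1:4) {
      y <- if (family == "binomial") rbinom(1, 10, 0.6) else rpois(1, 5)
      tot <- if (family == "binomial") 10 else NULL
      env <- envelope_add_datum(env, y, w = runif(1, 0.5, 2), total = tot)
      env <- envelope_l0_step(env, lambda = runif(1, 0.5, 2))$envelope
    }
    grid <- seq(dom[1] + 1e-6, dom[2] - 1e-6, length.out = 1000)
    old_vals <- envelope_eval(env, grid)
    y <- if (family == "binomial") 4 else 7
    tot <- if (family == "binomial") 9 else NULL
    w <- 1.3
    datum <- switch(family,
      gaussian = w / 2 * (grid - y)^2 - w / 2 * y^2 + w * y^2 / 2,
      poisson = w * (exp(grid) - y * grid),
      binomial = w * (tot * log1p(exp(pmin(grid, 35))) - y * grid))
    if (family == "gaussian") datum <- w / 2 * grid^2 - w * y * grid + w * y^2 / 2
    new_vals <- envelope_eval(envelope_add_datum(env, y, w = w, total = tot), grid)
    # additivity is exact in the coefficients; evaluation roundoff scales
    # with the magnitude of the envelope (up to e^30 at the domain edge)
    rel_gap <- abs(new_vals - (old_vals + datum)) / pmax(1, abs(old_vals + datum))
    expect_lt(max(rel_gap), 1e-10)
  }
})

test_that("the L0 step is the pointwise min with the restart constant", {
  # half-quadratic (theta - 2)^2 / 2 with lambda = 2: crossings at theta = 0, 4
  env <- envelope_new("gaussian", domain = c(-20, 20))
  env <- envelope_add_datum(env, y = 2, w = 1)
  st <- envelope_l0_step(env, lambda = 2)
  expect_equal(st$min, 0)
  expect_equal(st$argmin, 2)
  expect_equal(sort(st$restart_regions), c(-20, 0, 4, 20), tolerance = 1e-9)
  grid <- seq(-20, 20, length.out = 1001)
  expect_lt(max(abs(envelope_eval(st$envelope, grid) -
                    pmin(0.5 * (grid - 2)^2, 2))), 1e-9)

  # lambda = 0 collapses the envelope to its own minimum constant
  flat <- envelope_l0_step(env, lambda = 0)$envelope
  expect_lt(max(abs(envelope_eval(flat, grid) - 0)), 1e-12)
})

test_that("the L0 step matches a dense-grid oracle for all families", {
  set.seed(407)
  for (family in c("gaussian", "poisson", "binomial")) {
    dom <- if (family == "gaussian") c(-15, 15) else c(-30, 30)
    env <- envelope_new(family, domain = dom)
    for (i in 1:5) {
      y <- if (family == "binomial") rbinom(1, 12, 0.4) else rpois(1, 6)
      tot <- if (family == "binomial") 12 else NULL
      env <- envelope_add_datum(env, y, w = runif(1, 0.5, 2), total = tot)
      lambda <- runif(1, 0.2, 3)
      grid <- seq(dom[1] + 1e-6, dom[2] - 1e-6, length.out = 1000)
      before <- envelope_eval(env, grid)
      st <- envelope_l0_step(env, lambda)
      after <- envelope_eval(st$envelope, grid)
      expect_lt(max(abs(after - pmin(before, st$min + lambda))), 1e-8)
      env <- st$envelope
    }
    # pieces tile the domain in order, with convex coefficients
    p <- env$pieces
    expect_equal(p$lo[1], dom[1])
    expect_equal(p$hi[length(p$hi)], dom[2])
    if (length(p$lo) > 1) expect_equal(p$lo[-1], p$hi[-length(p$hi)])
    expect_true(all(p$a >= 0))
  }
})

test_that("envelope minimum agrees with dense-grid minimization", {
  set.seed(408)
  env <- envelope_new("poisson")
  for (i in 1:6) {
    env <- envelope_add_datum(env, rpois(1, 8), w = 1)
    env <- envelope_l0_step(env, 1.5)$envelope
  }
  grid <- seq(-30, 30, length.out = 200001)
  vals <- envelope_eval(env, grid)
  m <- envelope_min(env)
  expect_equal(m$min, min(vals), tolerance = 1e-7)
  expect_equal(envelope_eval(env, m$argmin), m$min, tolerance = 1e-10)
})
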