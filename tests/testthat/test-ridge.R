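# helper: a quadratic rsm_fit with known coefficients, built by fitting
# noise-free synthetic data (exact interpolation)
fit_from_truth <- function(truth_coded, factors = toy_factors, n_center = 3) {
  names(truth_coded) <- extractopt:::quad_term_names(factors)
  spec <- synthetic_spec(factors, truth = truth_coded, truth_units = "coded",
                         noise_sd = 0, n_center = n_center)
  fit_quadratic(generate_synthetic(spec, seed = 1))
}

test_that("canonical analysis classifies a concave bowl and flags degeneracy", {
  bowl <- fit_from_truth(c(10, 0, 0, 0, -1, -1))   # yhat = 10 - a^2 - b^2
  ca <- canonical_analysis(bowl)
  expect_equal(ca$nature, "maximum")
  expect_equal(unname(ca$stationary_coded), c(0, 0), tolerance = 1e-8)
  expect_equal(ca$value, 10, tolerance = 1e-8)

  flat <- fit_from_truth(c(3, 1, -2, 0, 0, 0))     # purely linear model
  ca2 <- canonical_analysis(flat)
  expect_true(ca2$degenerate)
  expect_equal(ca2$nature, "ridge-degenerate")
})

test_that("stationary-point nature is certified by local sampling", {
  ca <- canonical_analysis(cga_fit)
  z0 <- unname(ca$stationary_coded)
  f <- function(z) predict(cga_fit, z, units = "coded")
  probes <- withr::with_seed(8, {
    d <- matrix(rnorm(500 * 4), 500, 4)
    d <- d / sqrt(rowSums(d^2)) * 0.05
    apply(d, 1, function(e) f(z0 + e) - f(z0))
  })
  if (ca$nature == "maximum") expect_true(all(probes <= 1e-10))
  if (ca$nature == "minimum") expect_true(all(probes >= -1e-10))
  if (ca$nature == "saddle") {
    expect_true(any(probes > 1e-10) && any(probes < -1e-10))
  }
})

test_that("ridge path lies on its spheres and is monotone, beating Monte-Carlo", {
  radii <- seq(0.25, 2, by = 0.25)
  rp <- ridge_max(cga_fit, radii)
  expect_true(all(rp$converged))
  coded <- as.matrix(rp[paste0(cga_factors()$name, "_coded")])
  expect_equal(sqrt(rowSums(coded^2)), radii, tolerance = 1e-7)
  expect_true(all(diff(rp$.pred) > 0))
  # the path starts at the center prediction in the radius -> 0 limit
  tiny <- ridge_max(cga_fit, c(1e-4))
  expect_equal(tiny$.pred, predict(cga_fit, c(0, 0, 0, 0), units = "coded"),
               tolerance = 1e-3)
  # each ridge point beats random same-radius sphere points
  for (i in c(2, 5, 8)) {
    r <- radii[i]
    rand <- withr::with_seed(100 + i, {
      m <- matrix(rnorm(10000 * 4), ncol = 4)
      m / sqrt(rowSums(m^2)) * r
    })
    colnames(rand) <- cga_factors()$name
    best_rand <- max(predict(cga_fit, as.data.frame(rand), units = "coded"))
    expect_gte(rp$.pred[i] + 1e-9, best_rand)
  }
})

test_that("for a concave model the ridge approaches the interior stationary point", {
  bowl <- fit_from_truth(c(10, 0.4, -0.2, 0, -1, -1))
  ca <- canonical_analysis(bowl)
  zs <- unname(ca$stationary_coded)
  rstar <- sqrt(sum(zs^2))
  rp <- ridge_max(bowl, c(rstar * 0.999))
  expect_equal(unname(unlist(rp[paste0(toy_factors$name, "_coded")])),
               zs * 0.999, tolerance = 1e-2)
  # beyond the stationary radius the constrained optimum stays on the sphere,
  # matching a generic numeric constrained optimizer
  r2 <- rstar * 2
  o <- optim(zs, function(th) {
    # parameterize the sphere by normalizing, penalty-free comparison point
    z <- th / sqrt(sum(th^2)) * r2
    -predict(bowl, z, units = "coded")
  })
  rp2 <- ridge_max(bowl, r2)
  expect_equal(rp2$.pred, -o$value, tolerance = 1e-5)
})

test_that("box-constrained maximization matches a dense grid on random quadratics", {
  fs3 <- dplyr::bind_rows(
    factor_spec("u", "x", 0, 1), factor_spec("v", "x", 0, 1),
    factor_spec("w", "x", 0, 1)
  )
  for (draw in 1:20) {
    truth <- withr::with_seed(500 + draw, {
      c(rnorm(1, 10, 2), rnorm(3, 0, 1), rnorm(3, 0, 0.4), rnorm(3, 0, 0.5))
    })
    fit <- fit_from_truth(truth, factors = fs3)
    bm <- box_constrained_max(fit)
    ax <- seq(-2, 2, length.out = 41)
    grid <- as.matrix(expand.grid(u = ax, v = ax, w = ax))
    gbest <- max(predict(fit, as.data.frame(grid), units = "coded"))
    expect_gte(bm$value + 1e-9, gbest)
    expect_lte(abs(bm$value - gbest), 0.05)  # grid resolution tolerance
  }
})

test_that("a concave bowl maximizes at the origin with the intercept value", {
  bowl <- fit_from_truth(c(7, 0, 0, 0, -1, -1))
  bm <- box_constrained_max(bowl)
  expect_equal(unname(bm$par_coded), c(0, 0), tolerance = 1e-6)
  expect_equal(bm$value, 7, tolerance = 1e-8)
  expect_length(bm$active, 0)
})

test_that("the fitted surface's box optimum dominates every design point", {
  bm <- box_constrained_max(cga_fit)
  expect_gte(bm$value, max(predict(cga_fit)))
  expect_true("power" %in% bm$active)
  expect_equal(unname(bm$par_coded["power"]), 2, tolerance = 1e-6)
})
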