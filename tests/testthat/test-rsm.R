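test_that("actual-unit coefficients reproduce the published model", {
  est <- coef(cga_fit, units = "actual")
  published <- c(
    "(Intercept)" = -344.708589,
    temperature = 2.212185, ethanol = 5.044251,
    ls_ratio = 3.887346, power = 1.337813,
    "temperature:ethanol" = 0.008599, "temperature:ls_ratio" = -0.017324,
    "temperature:power" = -0.011583, "ethanol:ls_ratio" = -0.012547,
    "ethanol:power" = -0.000117, "ls_ratio:power" = -0.006649,
    "I(temperature^2)" = -0.007313, "I(ethanol^2)" = -0.03598,
    "I(ls_ratio^2)" = -0.015413, "I(power^2)" = -0.002116
  )
  big <- c("(Intercept)", "temperature", "ethanol", "ls_ratio", "power")
  for (nm in big) {
    expect_lt(abs(est[[nm]] - published[[nm]]) / abs(published[[nm]]), 0.005)
  }
  # higher-order terms are tiny in magnitude; the printed responses carry
  # only two decimals, so compare absolutely at the rounding-limited scale
  for (nm in setdiff(names(published), big)) {
    expect_lt(abs(est[[nm]] - published[[nm]]), 5e-5)
  }
})

test_that("fitted values reproduce the published per-run predictions", {
  runs <- cga_runs()
  expect_true(all(abs(predict(cga_fit) - runs$rsm_pred_pub) <= 0.05))
  val <- cga_validation()
  expect_true(all(abs(predict(cga_fit, val) - val$rsm_pred_pub) <= 0.05))
  expect_equal(predict(cga_fit, c(50, 75, 30, 120)), 39.92, tolerance = 0.002)
  expect_equal(predict(cga_fit, c(60, 65, 30, 120)), 40.02, tolerance = 0.002)
})

test_that("prediction is identical through coded or actual coefficients", {
  set.seed(3)
  pts_coded <- matrix(runif(40, -2, 2), 10, 4)
  colnames(pts_coded) <- cga_factors()$name
  pts_actual <- to_actual(cga_factors(), as.data.frame(pts_coded))
  p1 <- predict(cga_fit, as.data.frame(pts_coded), units = "coded")
  p2 <- predict(cga_fit, pts_actual, units = "actual")
  # direct evaluation of the actual-space polynomial
  act <- coef(cga_fit, units = "actual")
  Z <- as.matrix(pts_actual)
  X <- extractopt:::quad_model_matrix(Z, cga_factors())
  p3 <- drop(X %*% act)
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_equal(p2, p3, tolerance = 1e-8)
})

test_that("coded fit back-transformed equals a direct actual-unit fit", {
  runs <- cga_runs()
  d <- as.data.frame(runs[c("temperature", "ethanol", "ls_ratio", "power")])
  d$y <- runs$yield
  direct <- lm(y ~ temperature + ethanol + ls_ratio + power +
                 temperature:ethanol + temperature:ls_ratio +
                 temperature:power + ethanol:ls_ratio + ethanol:power +
                 ls_ratio:power + I(temperature^2) + I(ethanol^2) +
                 I(ls_ratio^2) + I(power^2), data = d)
  est <- coef(cga_fit, units = "actual")
  expect_equal(unname(est["(Intercept)"]), unname(coef(direct)["(Intercept)"]),
               tolerance = 1e-6)
  for (nm in c("temperature", "I(power^2)", "ethanol:ls_ratio")) {
    expect_equal(unname(est[nm]), unname(coef(direct)[nm]), tolerance = 1e-6)
  }
})

test_that("noise-free quadratic data is recovered to machine tolerance", {
  truth <- c(5, 1.5, -2, 0.8, -0.6, 0.25)  # intercept, lin a, lin b, ab, a2, b2
  names(truth) <- extractopt:::quad_term_names(toy_factors)
  spec <- synthetic_spec(toy_factors, truth = truth, truth_units = "coded",
                         noise_sd = 0, n_center = 3)
  runs <- generate_synthetic(spec, seed = 1)
  fit <- fit_quadratic(runs)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-10)
  expect_equal(rsm_anova(fit)$summary$r.squared, 1, tolerance = 1e-10)
})

test_that("a rank-deficient design is rejected with the offending columns", {
  runs <- cga_runs()[1:20, ]  # drop the axial/center runs -> z^2 collinear
  attr(runs, "factors") <- cga_factors()
  expect_error(fit_quadratic(runs), "singular fit")
})

test_that("surface grid is consistent with pointwise prediction", {
  g <- evaluate_surface_grid(cga_fit, c("ethanol", "ls_ratio"), resolution = 2)
  expect_equal(nrow(g), 4)
  manual <- predict(cga_fit,
                    data.frame(temperature = 50, ethanol = g$ethanol,
                               ls_ratio = g$ls_ratio, power = 120))
  expect_equal(g$.pred, manual)
  # invariant to the units the fixed settings are given in
  g1 <- evaluate_surface_grid(cga_fit, c("ethanol", "ls_ratio"),
                              fixed = c(temperature = 60, power = 135),
                              resolution = 5)
  g2 <- evaluate_surface_grid(cga_fit, c("ethanol", "ls_ratio"),
                              fixed = c(temperature = 1, power = 1),
                              fixed_units = "coded", resolution = 5)
  expect_equal(g1, g2)
})

test_that("fine surface grid locates the high-yield region", {
  g <- evaluate_surface_grid(cga_fit, c("ethanol", "ls_ratio"),
                             resolution = 81)
  top <- g[which.max(g$.pred), ]
  expect_gte(top$ethanol, 65); expect_lte(top$ethanol, 75)
  expect_gte(top$ls_ratio, 30); expect_lte(top$ls_ratio, 50)
})
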