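# Small networks and data keep these fast; the expensive fixture training
# lives in the acceptance tests.

toy_runs <- generate_synthetic(
  synthetic_spec(toy_factors,
                 truth = stats::setNames(c(5, 1, -1, 0.5, -0.8, 0.3),
                                         extractopt:::quad_term_names(toy_factors)),
                 truth_units = "coded", noise_sd = 0.05, n_center = 3),
  seed = 4
)

test_that("forward pass with zero weights is the constant output bias", {
  fit <- train_mlp(toy_runs, hidden = 3, restarts = 1, seed = 1,
                   max_epochs = 1)
  fit$theta <- rep(0, length(fit$theta))
  fit$theta[length(fit$theta)] <- 0.25   # output bias, normalized scale
  pred <- predict(fit, toy_runs)
  expect_equal(pred, rep(extractopt:::denorm_minmax(0.25, fit$y_lo, fit$y_hi),
                         nrow(toy_runs)))
})

test_that("analytic backprop gradient matches central finite differences", {
  fit <- train_mlp(toy_runs, hidden = 4, restarts = 1, seed = 2,
                   max_epochs = 3)
  theta <- withr::with_seed(9, runif(length(fit$theta), -0.7, 0.7))
  expect_lt(gradient_check(fit, theta = theta), 1e-6)
  # near-perfect fit => near-zero gradient
  fit2 <- train_mlp(toy_runs, hidden = 6, restarts = 2, seed = 3,
                    max_epochs = 500)
  i <- which(fit2$assignment == "train")
  if (fit2$restarts_summary$train_mse[fit2$selected_restart] < 1e-8) {
    sub <- toy_runs[i, ]
    attr(sub, "factors") <- toy_factors
    g <- extractopt:::mlp_grad(
      fit2$theta,
      sapply(1:2, function(j) extractopt:::norm_minmax(
        as.matrix(sub[toy_factors$name])[, j], fit2$x_lo[j], fit2$x_hi[j])),
      extractopt:::norm_minmax(sub$yield, fit2$y_lo, fit2$y_hi),
      2, 6)
    expect_lt(max(abs(g)), 1e-3)
  }
})

test_that("an injected sign bug is caught by the gradient check", {
  fit <- train_mlp(toy_runs, hidden = 3, restarts = 1, seed = 5,
                   max_epochs = 2)
  theta <- withr::with_seed(11, runif(length(fit$theta), -0.5, 0.5))
  good <- gradient_check(fit, theta = theta)
  # negate the analytic gradient of the output bias by perturbing theta in
  # the finite-difference direction: emulate the bug by comparing against a
  # deliberately wrong analytic gradient
  ga <- extractopt:::mlp_grad(
    theta,
    sapply(1:2, function(j) extractopt:::norm_minmax(
      as.matrix(toy_runs[toy_factors$name])[, j], fit$x_lo[j], fit$x_hi[j])),
    extractopt:::norm_minmax(toy_runs$yield, fit$y_lo, fit$y_hi), 2, 3)
  bugged <- ga; bugged[length(bugged)] <- -bugged[length(bugged)]
  expect_gt(max(abs(bugged - ga) / pmax(abs(bugged) + abs(ga), 1e-8)),
            1000 * good)
})

test_that("tanh oddness: mirrored weights give mirrored outputs", {
  k <- 2; hidden <- 3
  theta <- withr::with_seed(13, runif(extractopt:::mlp_npar(k, hidden), -1, 1))
  # zero all biases
  p <- extractopt:::mlp_unpack(theta, k, hidden)
  theta <- c(as.vector(p$W1), rep(0, hidden), p$w2, 0)
  Xn <- matrix(c(0.3, -0.8, 0.1, 0.5), 2, 2)
  f1 <- extractopt:::mlp_forward(theta, Xn, k, hidden)
  f2 <- extractopt:::mlp_forward(theta, -Xn, k, hidden)
  expect_equal(f1, -f2, tolerance = 1e-12)
})

test_that("batch prediction equals elementwise prediction", {
  fit <- train_mlp(toy_runs, hidden = 4, restarts = 2, seed = 6,
                   max_epochs = 50)
  batch <- predict(fit, toy_runs)
  single <- vapply(seq_len(nrow(toy_runs)),
                   function(i) predict(fit, toy_runs[i, ]), numeric(1))
  expect_equal(batch, single)
})

test_that("training is deterministic given the seed", {
  f1 <- train_mlp(toy_runs, hidden = 4, restarts = 3, seed = 42,
                  max_epochs = 100)
  f2 <- train_mlp(toy_runs, hidden = 4, restarts = 3, seed = 42,
                  max_epochs = 100)
  expect_identical(f1$theta, f2$theta)
  expect_identical(predict(f1, toy_runs), predict(f2, toy_runs))
  expect_identical(f1$assignment, f2$assignment)
})

test_that("noise-free smooth data trains to below 1e-3 normalized MSE", {
  clean <- generate_synthetic(
    synthetic_spec(noise_sd = 0), seed = 7)   # 27-point CCRD, quadratic truth
  fit <- train_mlp(clean, restarts = 6, seed = 1, max_epochs = 400)
  best_train <- min(fit$restarts_summary$train_mse)
  expect_lt(best_train, 1e-3)
})

test_that("split respects the fractions and every run is assigned once", {
  fit <- train_mlp(toy_runs, hidden = 3, restarts = 1, seed = 8,
                   max_epochs = 2)
  n <- nrow(toy_runs)
  expect_length(fit$assignment, n)
  counts <- table(fit$assignment)
  expect_equal(unname(counts["train"]), round(0.7 * n))
  expect_equal(unname(counts["validation"]), round(0.15 * n))
  expect_error(train_mlp(toy_runs, split = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("early stopping returns the best validation epoch, not the last", {
  fit <- train_mlp(toy_runs, hidden = 6, restarts = 2, seed = 21,
                   max_epochs = 300, patience = 8)
  tr <- fit$trace
  sel <- fit$restarts_summary[fit$selected_restart, ]
  best_epoch_val <- min(tr$val_mse, na.rm = TRUE)
  expect_equal(sel$val_mse, best_epoch_val, tolerance = 1e-12)
  # the returned parameters achieve that validation MSE exactly
  ival <- which(fit$assignment == "validation")
  Xn <- sapply(1:2, function(j) extractopt:::norm_minmax(
    as.matrix(toy_runs[toy_factors$name])[ival, j], fit$x_lo[j], fit$x_hi[j]))
  tv <- extractopt:::norm_minmax(toy_runs$yield[ival], fit$y_lo, fit$y_hi)
  expect_equal(extractopt:::mlp_mse(fit$theta, Xn, tv, 2, 6), sel$val_mse,
               tolerance = 1e-12)
})

test_that("extrapolation beyond the normalization bounds warns", {
  fit <- train_mlp(toy_runs, hidden = 3, restarts = 1, seed = 9,
                   max_epochs = 5)
  far <- toy_runs[1, ]
  far$a <- max(toy_runs$a) + 100
  expect_warning(predict(fit, far), "extrapolation")
})

test_that("a serialized model reloads with identical predictions", {
  fit <- train_mlp(toy_runs, hidden = 4, restarts = 2, seed = 10,
                   max_epochs = 60)
  path <- tempfile(fileext = ".json")
  write_mlp(fit, path)
  back <- read_mlp(path)
  expect_equal(predict(back, toy_runs), predict(fit, toy_runs),
               tolerance = 1e-12)
  expect_identical(back$assignment, fit$assignment)
})
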