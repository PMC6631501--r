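# Single-hidden-layer perceptron surrogate: k inputs, H tanh hidden units,
# one linear output, trained by full-batch BFGS minimization of the mean
# squared error on min-max-normalized data, with analytic backpropagation
# gradients. Everything is deterministic given the seed.

mlp_npar <- function(k, hidden) hidden * k + hidden + hidden + 1L

mlp_unpack <- function(theta, k, hidden) {
  i1 <- hidden * k
  list(W1 = matrix(theta[seq_len(i1)], hidden, k),
       b1 = theta[i1 + seq_len(hidden)],
       w2 = theta[i1 + hidden + seq_len(hidden)],
       b2 = theta[i1 + 2L * hidden + 1L])
}

# forward pass on normalized inputs; Xn is n x k
mlp_forward <- function(theta, Xn, k, hidden) {
  p <- mlp_unpack(theta, k, hidden)
  A <- tanh(Xn %*% t(p$W1) + rep(1, nrow(Xn)) %o% p$b1)
  drop(A %*% p$w2 + p$b2)
}

mlp_mse <- function(theta, Xn, tn, k, hidden) {
  mean((mlp_forward(theta, Xn, k, hidden) - tn)^2)
}

# analytic gradient of the mean squared error wrt all parameters
mlp_grad <- function(theta, Xn, tn, k, hidden) {
  p <- mlp_unpack(theta, k, hidden)
  n <- nrow(Xn)
  Z <- Xn %*% t(p$W1) + rep(1, n) %o% p$b1
  A <- tanh(Z)
  yhat <- drop(A %*% p$w2 + p$b2)
  d <- 2 * (yhat - tn) / n
  gw2 <- drop(crossprod(A, d))
  gb2 <- sum(d)
  dA <- (d %o% p$w2) * (1 - A^2)
  gW1 <- crossprod(dA, Xn)
  gb1 <- colSums(dA)
  c(as.vector(gW1), gb1, gw2, gb2)
}

# Full-batch BFGS with Armijo backtracking. One epoch = one quasi-Newton
# step. When `patience` is finite, the validation MSE is monitored every
# epoch and the parameters of the best validation epoch are returned after
# `patience` consecutive non-improvements; otherwise training runs to the
# gradient tolerance or `max_epochs` and the final parameters are returned.
mlp_bfgs <- function(theta, Xtr, ttr, Xval = NULL, tval = NULL, k, hidden,
                     max_epochs = 1000, patience = Inf, grad_tol = 1e-10) {
  np <- length(theta)
  Binv <- diag(np)
  g <- mlp_grad(theta, Xtr, ttr, k, hidden)
  f <- mlp_mse(theta, Xtr, ttr, k, hidden)
  monitor <- !is.null(Xval) && nrow(Xval) > 0
  vm <- if (monitor) mlp_mse(theta, Xval, tval, k, hidden) else NA_real_
  best <- list(theta = theta, val = vm, epoch = 0L, train = f)
  fail <- 0L
  trace <- vector("list", max_epochs + 1L)
  trace[[1L]] <- c(epoch = 0, train_mse = f, val_mse = vm)
  epochs_run <- 0L
  converged <- FALSE

  for (ep in seq_len(max_epochs)) {
    d <- -drop(Binv %*% g)
    gd <- sum(g * d)
    if (gd > -1e-18) { Binv <- diag(np); d <- -g; gd <- sum(g * d) }
    a <- 1
    repeat {
      f2 <- mlp_mse(theta + a * d, Xtr, ttr, k, hidden)
      if (f2 <= f + 1e-4 * a * gd || a < 1e-12) break
      a <- a / 2
    }
    if (a < 1e-12) { converged <- TRUE; break }  # no descent step found
    s <- a * d
    theta2 <- theta + s
    g2 <- mlp_grad(theta2, Xtr, ttr, k, hidden)
    yk <- g2 - g
    sy <- sum(s * yk)
    if (sy > 1e-12) {  # curvature condition; otherwise skip the update
      rho <- 1 / sy
      V <- diag(np) - rho * (s %o% yk)
      Binv <- V %*% Binv %*% t(V) + rho * (s %o% s)
    }
    theta <- theta2; g <- g2; f <- f2
    epochs_run <- ep
    vm <- if (monitor) mlp_mse(theta, Xval, tval, k, hidden) else NA_real_
    trace[[ep + 1L]] <- c(epoch = ep, train_mse = f, val_mse = vm)
    if (monitor && is.finite(vm) && vm < best$val - 1e-12) {
      best <- list(theta = theta, val = vm, epoch = ep, train = f)
      fail <- 0L
    } else {
      fail <- fail + 1L
    }
    if (monitor && is.finite(patience) && fail >= patience) break
    if (sqrt(sum(g * g)) < grad_tol) { converged <- TRUE; break }
  }

  use_best <- monitor && is.finite(patience)
  out_theta <- if (use_best) best$theta else theta
  list(theta = out_theta,
       train_mse = mlp_mse(out_theta, Xtr, ttr, k, hidden),
       val_mse = if (monitor) mlp_mse(out_theta, Xval, tval, k, hidden) else NA_real_,
       best_epoch = if (use_best) best$epoch else epochs_run,
       epochs = epochs_run,
       converged = converged,
       trace = tibble::as_tibble(do.call(rbind, trace[!vapply(trace, is.null, TRUE)])))
}

norm_minmax <- function(v, lo, hi) 2 * (v - lo) / (hi - lo) - 1
denorm_minmax <- function(v, lo, hi) (v + 1) / 2 * (hi - lo) + lo

# Random init: small uniform hidden layer, linear least-squares readout.
# Starting at the optimal linear readout of near-linear hidden features
# means the search begins at (approximately) the best linear model and
# BFGS grows the nonlinearity from there, which empirically lands in much
# smoother interpolants than fully random starts.
mlp_init <- function(k, hidden, Xtr, ttr, init_scale) {
  W1 <- matrix(stats::runif(hidden * k, -init_scale, init_scale), hidden, k)
  b1 <- stats::runif(hidden, -init_scale, init_scale)
  A <- tanh(Xtr %*% t(W1) + rep(1, nrow(Xtr)) %o% b1)
  co <- tryCatch(qr.coef(qr(cbind(1, A)), ttr), error = function(e) rep(0, hidden + 1))
  co[!is.finite(co)] <- 0
  c(as.vector(W1), b1, co[-1], co[1])
}

#' Train a single-hidden-layer perceptron surrogate
#'
#' Trains `restarts` networks from different random initializations by
#' full-batch BFGS minimization of the mean squared error on normalized
#' data, and keeps the restart with the lowest validation MSE. Runs are
#' randomly partitioned into training, validation and test subsets; the
#' validation subset steers restart selection (and, when `patience` is
#' finite, early stopping), while the test subset is never touched during
#' training or selection.
#'
#' By default training runs to convergence and early stopping is off
#' (`patience = Inf`): with the small validation subsets typical of designed
#' experiments, epoch-level early stopping is dominated by noise and
#' systematically returns under-trained networks, so the validation data is
#' spent on restart selection instead. Set a finite `patience` to enable
#' classical early stopping (the parameters of the best validation epoch are
#' then returned).
#'
#' @param data Run table (actual factor columns + response), e.g.
#'   [cga_runs()].
#' @param factors Factor table; defaults to `attr(data, "factors")`.
#' @param response Response column name (default `"yield"`).
#' @param hidden Hidden-layer width (default 10).
#' @param restarts Number of random restarts (default 40).
#' @param split Train/validation/test fractions, summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Master seed; drives the split and every restart. Two calls
#'   with identical arguments give bit-identical models.
#' @param max_epochs Cap on BFGS iterations per restart (default 1000).
#' @param patience Early-stopping patience in epochs; `Inf` (default)
#'   disables early stopping.
#' @param init_scale Half-width of the uniform hidden-weight initialization
#'   (default 0.1); the output layer starts at its least-squares readout.
#'
#' @return An object of class `mlp_fit`: network weights, normalization
#'   bounds, split assignment, per-restart summary (`restarts_summary`),
#'   training trace of the selected restart (`trace`), and the seed.
#' @export
#' @examples
#' \donttest{
#' fit <- train_mlp(cga_runs(), restarts = 4, seed = 1)
#' glance(fit)
#' }
train_mlp <- function(data, factors = NULL, response = "yield", hidden = 10,
                      restarts = 40, split = c(0.70, 0.15, 0.15), seed = 1,
                      max_epochs = 1000, patience = Inf, init_scale = 0.1) {
  factors <- factors %||% attr(data, "factors")
  check_factors(factors)
  stopifnot(hidden >= 1, restarts >= 1)
  if (length(split) != 3 || any(split <= 0) || abs(sum(split) - 1) > 1e-8) {
    stop("'split' must be three positive fractions summing to 1", call. = FALSE)
  }
  n <- nrow(data)
  if (n < 10) stop("need at least 10 runs to train a surrogate", call. = FALSE)
  k <- nrow(factors)
  X <- as.matrix(data[factors$name])
  y <- data[[response]]

  x_lo <- apply(X, 2, min); x_hi <- apply(X, 2, max)
  if (any(x_hi - x_lo <= 0)) stop("constant factor column; cannot normalize",
                                  call. = FALSE)
  y_lo <- min(y); y_hi <- max(y)
  Xn <- sapply(seq_len(k), function(j) norm_minmax(X[, j], x_lo[j], x_hi[j]))
  tn <- norm_minmax(y, y_lo, y_hi)

  n_tr <- round(split[1] * n)
  n_val <- round(split[2] * n)
  assignment <- with_seed_local(seed, {
    ord <- sample.int(n)
    a <- rep("test", n)
    a[ord[seq_len(n_tr)]] <- "train"
    a[ord[n_tr + seq_len(n_val)]] <- "validation"
    a
  })
  itr <- which(assignment == "train")
  ival <- which(assignment == "validation")
  restart_seeds <- with_seed_local(seed, sample.int(.Machine$integer.max - 1,
                                                    restarts))

  Xtr <- Xn[itr, , drop = FALSE]; ttr <- tn[itr]
  Xv <- Xn[ival, , drop = FALSE]; tv <- tn[ival]

  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    theta0 <- with_seed_local(restart_seeds[r],
                              mlp_init(k, hidden, Xtr, ttr, init_scale))
    runs[[r]] <- mlp_bfgs(theta0, Xtr, ttr, Xv, tv, k, hidden,
                          max_epochs = max_epochs, patience = patience)
  }
  summary_tbl <- tibble::tibble(
    restart = seq_len(restarts),
    seed = restart_seeds,
    epochs = vapply(runs, `[[`, integer(1), "epochs"),
    converged = vapply(runs, `[[`, logical(1), "converged"),
    train_mse = vapply(runs, `[[`, numeric(1), "train_mse"),
    val_mse = vapply(runs, `[[`, numeric(1), "val_mse")
  )
  best_i <- which.min(summary_tbl$val_mse)
  best <- runs[[best_i]]

  structure(list(
    factors = factors, response = response,
    k = k, hidden = hidden,
    theta = best$theta,
    x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi,
    assignment = assignment,
    split = split, seed = seed, restarts = restarts,
    selected_restart = best_i,
    restarts_summary = summary_tbl,
    trace = best$trace,
    patience = patience, max_epochs = max_epochs, init_scale = init_scale,
    data = data
  ), class = "mlp_fit")
}

#' Predict from a trained perceptron surrogate
#'
#' Applies the stored min-max normalization, evaluates
#' `w2' tanh(W1 x + b1) + b2`, and maps back to original response units.
#' Settings outside the normalization bounds are allowed but trigger an
#' extrapolation warning.
#'
#' @param object An [train_mlp()] model.
#' @param newdata Data frame with one column per factor (actual units), a
#'   numeric vector of length `k`, or `NULL` for the training table.
#' @param ... Unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.mlp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  k <- object$k
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    stopifnot(length(newdata) == k)
    newdata <- stats::setNames(as.data.frame(as.list(newdata)),
                               object$factors$name)
  }
  X <- as.matrix(as.data.frame(newdata)[object$factors$name])
  outside <- sweep(X, 2, object$x_lo, "<") | sweep(X, 2, object$x_hi, ">")
  if (any(outside)) {
    warning("predicting outside the normalization bounds (extrapolation)",
            call. = FALSE)
  }
  Xn <- sapply(seq_len(k), function(j) norm_minmax(X[, j], object$x_lo[j],
                                                   object$x_hi[j]))
  if (is.null(dim(Xn))) Xn <- matrix(Xn, nrow = 1)
  denorm_minmax(mlp_forward(object$theta, Xn, k, object$hidden),
                object$y_lo, object$y_hi)
}

#' @rdname predict.mlp_fit
#' @param model An `mlp_fit`.
#' @export
mlp_predict <- function(model, newdata = NULL) predict(model, newdata)

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("Perceptron surrogate %d-%d-1 (tanh hidden, linear output)\n",
              x$k, x$hidden))
  cat(sprintf("selected restart %d of %d (validation MSE %.3g, train MSE %.3g)\n",
              x$selected_restart, x$restarts,
              x$restarts_summary$val_mse[x$selected_restart],
              x$restarts_summary$train_mse[x$selected_restart]))
  invisible(x)
}

#' @method tidy mlp_fit
#' @export
tidy.mlp_fit <- function(x, ...) {
  p <- mlp_unpack(x$theta, x$k, x$hidden)
  dplyr::bind_rows(
    tibble::tibble(layer = "hidden",
                   unit = rep(seq_len(x$hidden), x$k + 1),
                   input = rep(c(x$factors$name, "(bias)"), each = x$hidden),
                   weight = c(as.vector(p$W1), p$b1)),
    tibble::tibble(layer = "output", unit = 1L,
                   input = c(paste0("hidden", seq_len(x$hidden)), "(bias)"),
                   weight = c(p$w2, p$b2))
  )
}

#' @method glance mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  pred <- predict(x, x$data)
  y <- x$data[[x$response]]
  part <- split(seq_along(y), x$assignment)
  mse_of <- function(i) mean((pred[i] - y[i])^2)
  tibble::tibble(
    hidden = x$hidden, restarts = x$restarts, nobs = length(y),
    r.squared = 1 - sum((pred - y)^2) / sum((y - mean(y))^2),
    train_mse = mse_of(part$train),
    validation_mse = mse_of(part$validation),
    test_mse = mse_of(part$test)
  )
}

#' Check the backpropagation gradient against finite differences
#'
#' Compares the analytic gradient of the training MSE with central finite
#' differences over every parameter and returns the maximum relative error,
#' a guard on the hand-written backpropagation.
#'
#' @param model An `mlp_fit`, or `NULL` to check a random small network.
#' @param data Run table; defaults to the model's training table.
#' @param theta Parameter vector to check at (defaults to the model's).
#' @param h Finite-difference step (default 1e-6).
#' @return Maximum relative gradient error (scalar).
#' @export
gradient_check <- function(model = NULL, data = NULL, theta = NULL, h = 1e-6) {
  if (is.null(model)) stop("supply a trained or initialized model", call. = FALSE)
  data <- data %||% model$data
  k <- model$k; hidden <- model$hidden
  X <- as.matrix(as.data.frame(data)[model$factors$name])
  Xn <- sapply(seq_len(k), function(j) norm_minmax(X[, j], model$x_lo[j],
                                                   model$x_hi[j]))
  if (is.null(dim(Xn))) Xn <- matrix(Xn, nrow = 1)
  tn <- norm_minmax(data[[model$response]], model$y_lo, model$y_hi)
  theta <- theta %||% model$theta
  ga <- mlp_grad(theta, Xn, tn, k, hidden)
  gn <- vapply(seq_along(theta), function(j) {
    e <- rep(0, length(theta)); e[j] <- h
    (mlp_mse(theta + e, Xn, tn, k, hidden) -
       mlp_mse(theta - e, Xn, tn, k, hidden)) / (2 * h)
  }, numeric(1))
  max(abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-8))
}

#' Serialize a perceptron surrogate to a structured text file
#'
#' Writes topology, weights, normalization bounds, split assignment and seed
#' as JSON at full floating-point precision, so a reloaded model reproduces
#' predictions exactly.
#'
#' @param model An `mlp_fit`.
#' @param path Output file path.
#' @return `path`, invisibly. `read_mlp()` returns the restored `mlp_fit`
#'   (without the training data and trace).
#' @export
write_mlp <- function(model, path) {
  payload <- list(
    topology = c(model$k, model$hidden, 1L),
    factors = model$factors, response = model$response,
    theta = model$theta,
    x_lo = model$x_lo, x_hi = model$x_hi,
    y_lo = model$y_lo, y_hi = model$y_hi,
    assignment = model$assignment, split = model$split,
    seed = model$seed, restarts = model$restarts,
    selected_restart = model$selected_restart
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    factors = tibble::as_tibble(p$factors), response = p$response,
    k = p$topology[1], hidden = p$topology[2],
    theta = p$theta,
    x_lo = stats::setNames(p$x_lo, tibble::as_tibble(p$factors)$name),
    x_hi = stats::setNames(p$x_hi, tibble::as_tibble(p$factors)$name),
    y_lo = p$y_lo, y_hi = p$y_hi,
    assignment = p$assignment, split = p$split,
    seed = p$seed, restarts = p$restarts,
    selected_restart = p$selected_restart,
    restarts_summary = NULL, trace = NULL, data = NULL
  ), class = "mlp_fit")
}
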