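# Full second-order response-surface model:
#   y = b0 + sum_i bi z_i + sum_{i<j} bij z_i z_j + sum_i bii z_i^2
# fitted by ordinary least squares in coded units (z = (x - center)/step).
# Coded space is the canonical internal representation: the columns are well
# conditioned and, for a CCRD, the linear and interaction columns are
# mutually orthogonal. Actual-unit coefficients are obtained by exact
# polynomial substitution, never by refitting.

quad_term_names <- function(factors) {
  k <- nrow(factors)
  nm <- factors$name
  pr <- factor_pairs(k)
  c("(Intercept)", nm,
    paste0(nm[pr[1, ]], ":", nm[pr[2, ]]),
    paste0("I(", nm, "^2)"))
}

# Z: n x k matrix of coded settings -> n x (1 + 2k + k(k-1)/2) model matrix
quad_model_matrix <- function(Z, factors) {
  Z <- as.matrix(Z)
  k <- ncol(Z)
  pr <- factor_pairs(k)
  inter <- if (ncol(pr)) {
    sapply(seq_len(ncol(pr)), function(m) Z[, pr[1, m]] * Z[, pr[2, m]])
  } else {
    matrix(0, nrow(Z), 0)
  }
  if (is.null(dim(inter))) inter <- matrix(inter, nrow = 1)
  X <- cbind(1, Z, inter, Z^2)
  colnames(X) <- quad_term_names(factors)
  X
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least squares fit of the complete quadratic polynomial (linear,
#' two-way interaction and pure quadratic terms) to a designed-experiment
#' table. Fitting happens in coded units; actual-unit coefficients come from
#' exact substitution and are available via [tidy()][tidy.rsm_fit()] or
#' `coef(fit, units = "actual")`.
#'
#' @param data Run table: one row per run, actual-unit factor columns plus a
#'   response column. Typically [cga_runs()] or the output of
#'   [generate_synthetic()].
#' @param factors Factor table; defaults to `attr(data, "factors")`.
#' @param response Name of the response column (default `"yield"`).
#'
#' @return An object of class `rsm_fit`.
#' @export
#' @examples
#' fit <- fit_quadratic(cga_runs())
#' glance(fit)
fit_quadratic <- function(data, factors = NULL, response = "yield") {
  factors <- factors %||% attr(data, "factors")
  check_factors(factors)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  y <- data[[response]]
  if (any(!is.finite(y))) stop("all responses must be finite", call. = FALSE)
  k <- nrow(factors)
  Z <- as.matrix(to_coded(factors, data[factors$name], quiet = TRUE))
  X <- quad_model_matrix(Z, factors)
  p <- ncol(X)
  if (nrow(X) < p + 1) {
    stop("need at least ", p + 1, " runs to fit ", p,
         " coefficients with a residual degree of freedom", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular fit: collinear model columns ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  structure(list(
    factors = factors,
    response = response,
    coef_coded = beta,
    X = X, Z = Z, y = y, qr = qrX,
    fitted = fitted, residuals = res,
    df_residual = nrow(X) - p,
    data = data
  ), class = "rsm_fit")
}

# Exact coefficient conversion between coded and actual space by polynomial
# substitution z = (x - c)/s (or its inverse). `beta` is the named vector in
# the quad_term_names() layout.
convert_quad_coef <- function(beta, factors, from = c("coded", "actual")) {
  from <- match.arg(from)
  k <- nrow(factors)
  pr <- factor_pairs(k)
  np <- ncol(pr)
  idx_lin <- 1 + seq_len(k)
  idx_int <- 1 + k + seq_len(np)
  idx_qud <- 1 + k + np + seq_len(k)
  b0 <- beta[1]; bl <- beta[idx_lin]; bi <- beta[idx_int]; bq <- beta[idx_qud]
  cc <- factors$center; ss <- factors$step
  pairmat <- function(v) {  # symmetric matrix of interaction coefficients
    M <- matrix(0, k, k)
    for (m in seq_len(np)) {
      M[pr[1, m], pr[2, m]] <- v[m]
      M[pr[2, m], pr[1, m]] <- v[m]
    }
    M
  }
  Bint <- pairmat(bi)
  if (from == "coded") {
    # substitute z_i = (x_i - c_i)/s_i
    aq <- bq / ss^2
    ai <- bi / (ss[pr[1, ]] * ss[pr[2, ]])
    al <- bl / ss - 2 * bq * cc / ss^2 -
      drop(Bint %*% (cc / ss)) / ss
    a0 <- b0 - sum(bl * cc / ss) + sum(bq * (cc / ss)^2) +
      sum(bi * (cc[pr[1, ]] / ss[pr[1, ]]) * (cc[pr[2, ]] / ss[pr[2, ]]))
    out <- c(a0, al, ai, aq)
  } else {
    # substitute x_i = c_i + s_i z_i
    aq <- bq * ss^2
    ai <- bi * ss[pr[1, ]] * ss[pr[2, ]]
    al <- ss * (bl + 2 * bq * cc + drop(Bint %*% cc))
    a0 <- b0 + sum(bl * cc) + sum(bq * cc^2) +
      sum(bi * cc[pr[1, ]] * cc[pr[2, ]])
    out <- c(a0, al, ai, aq)
  }
  names(out) <- names(beta)
  out
}

#' @export
coef.rsm_fit <- function(object, units = c("coded", "actual"), ...) {
  units <- match.arg(units)
  if (units == "coded") return(object$coef_coded)
  convert_quad_coef(object$coef_coded, object$factors, from = "coded")
}

#' Predict yields from a fitted response-surface model
#'
#' @param object An `rsm_fit`.
#' @param newdata Data frame of settings (one column per factor), a numeric
#'   vector of length `k`, or `NULL` for the training runs.
#' @param units Are `newdata` settings in `"actual"` (default) or `"coded"`
#'   units?
#' @param ... Unused.
#' @return Numeric vector of predicted responses in original response units.
#' @export
predict.rsm_fit <- function(object, newdata = NULL,
                            units = c("actual", "coded"), ...) {
  units <- match.arg(units)
  if (is.null(newdata)) return(object$fitted)
  factors <- object$factors
  k <- nrow(factors)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    stopifnot(length(newdata) == k)
    newdata <- stats::setNames(as.data.frame(as.list(newdata)), factors$name)
  }
  newdata <- as.data.frame(newdata)
  Z <- if (units == "actual") {
    as.matrix(to_coded(factors, newdata[factors$name], quiet = TRUE))
  } else {
    as.matrix(newdata[factors$name])
  }
  drop(quad_model_matrix(Z, factors) %*% object$coef_coded)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Second-order response-surface fit (", nrow(x$factors), " factors, ",
      length(x$y), " runs)\n", sep = "")
  cat("Coded-space coefficients:\n")
  print(round(x$coef_coded, 5))
  invisible(x)
}

#' Tidy a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param units Report coefficients in `"coded"` (default) or `"actual"`
#'   units. Standard errors, t statistics and p values come from the
#'   coded-space least-squares fit and are only attached for coded units.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy rsm_fit
#' @export
tidy.rsm_fit <- function(x, units = c("coded", "actual"), ...) {
  units <- match.arg(units)
  est <- coef(x, units = units)
  out <- tibble::tibble(term = names(est), estimate = unname(est))
  if (units == "coded") {
    sigma2 <- sum(x$residuals^2) / x$df_residual
    XtXinv <- chol2inv(qr.R(x$qr))
    se <- sqrt(sigma2 * diag(XtXinv))
    out$std.error <- se
    out$statistic <- out$estimate / se
    out$p.value <- 2 * stats::pt(abs(out$statistic), x$df_residual,
                                 lower.tail = FALSE)
  }
  out
}

#' Model-level summary of a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `adj.r.squared`, `sigma` (residual
#'   standard deviation), `statistic` (overall model F), `p.value`, `press`
#'   (leave-one-out prediction error sum of squares), `cv` (coefficient of
#'   variation, percent), `mean_response`, `df.residual`, `nobs`.
#' @method glance rsm_fit
#' @export
glance.rsm_fit <- function(x, ...) {
  an <- rsm_anova(x)
  an$summary
}
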