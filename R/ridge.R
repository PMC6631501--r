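# Second-order surface analysis in coded units. The fitted polynomial is
# written as  yhat(z) = b0 + g'z + z' B z  with B symmetric (interaction
# coefficients halved off the diagonal), the standard canonical form for
# stationary-point and ridge analysis.

quad_form <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  k <- nrow(fit$factors)
  pr <- factor_pairs(k)
  beta <- fit$coef_coded
  np <- ncol(pr)
  g <- unname(beta[1 + seq_len(k)])
  B <- diag(unname(beta[1 + k + np + seq_len(k)]), k)
  for (m in seq_len(np)) {
    B[pr[1, m], pr[2, m]] <- B[pr[2, m], pr[1, m]] <-
      unname(beta[1 + k + m]) / 2
  }
  list(b0 = unname(beta[1]), g = g, B = B)
}

#' Canonical analysis of a fitted quadratic surface
#'
#' Finds the stationary point of the second-order model in coded units and
#' classifies it from the eigenvalues of the quadratic-form matrix: all
#' negative is a maximum, all positive a minimum, mixed signs a saddle.
#' A (numerically) singular quadratic form has no unique stationary point;
#' such models are reported as ridge-degenerate instead of producing one.
#'
#' @param fit An [fit_quadratic()] object.
#' @param tol Relative tolerance below which an eigenvalue counts as zero.
#' @return A list: `stationary_coded`, `stationary_actual` (tibble),
#'   `value` (prediction at the stationary point), `eigenvalues`, `nature`
#'   (`"maximum"`, `"minimum"`, `"saddle"` or `"ridge-degenerate"`),
#'   `degenerate` flag.
#' @export
canonical_analysis <- function(fit, tol = 1e-8) {
  qf <- quad_form(fit)
  k <- length(qf$g)
  ev <- eigen(qf$B, symmetric = TRUE, only.values = TRUE)$values
  # degenerate when the quadratic form is singular, or negligible relative
  # to the linear part (a purely first-order surface has no stationary point)
  ref <- max(abs(ev), abs(qf$g), 1)
  if (max(abs(ev)) < tol * ref || min(abs(ev)) < tol * max(abs(ev))) {
    return(list(stationary_coded = NULL, stationary_actual = NULL,
                value = NA_real_, eigenvalues = ev,
                nature = "ridge-degenerate", degenerate = TRUE))
  }
  zs <- drop(solve(2 * qf$B, -qf$g))
  nature <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  actual <- to_actual(fit$factors, actual_row(fit$factors, zs))
  list(stationary_coded = stats::setNames(zs, fit$factors$name),
       stationary_actual = actual,
       value = predict(fit, zs, units = "coded"),
       eigenvalues = ev, nature = nature, degenerate = FALSE)
}

#' Ridge-of-maximum-response analysis
#'
#' For each radius `r` the point maximizing the fitted quadratic on the
#' coded sphere of that radius is obtained from the Lagrangian system
#' `(mu I - B) z = g / 2`, with the multiplier `mu` above the largest
#' eigenvalue of `B` located by root finding on `||z(mu)|| = r` (the norm is
#' strictly decreasing in `mu` on that interval).
#'
#' @param fit An [fit_quadratic()] object.
#' @param radii Increasing positive radii in coded units.
#' @return A tibble with class `ridge_path`: `radius`, one coded and one
#'   actual column per factor, `.pred`, and `converged` (a failed
#'   root-finding at one radius flags that row and the path continues).
#' @export
#' @examples
#' rp <- ridge_max(fit_quadratic(cga_runs()), radii = seq(0.25, 2, 0.25))
ridge_max <- function(fit, radii = seq(0.1, 2, by = 0.1)) {
  stopifnot(all(radii > 0), !is.unsorted(radii))
  qf <- quad_form(fit)
  k <- length(qf$g)
  lam_max <- max(eigen(qf$B, symmetric = TRUE, only.values = TRUE)$values)
  half_g <- qf$g / 2
  norm_at <- function(mu) sqrt(sum(solve(mu * diag(k) - qf$B, half_g)^2))

  rows <- purrr::map(radii, function(r) {
    z <- rep(NA_real_, k); ok <- FALSE
    lo <- lam_max + 1e-10
    hi <- lam_max + max(1, sqrt(sum(half_g^2)) / r) * 10
    # expand until the bracket straddles ||z|| = r
    tries <- 0
    while (norm_at(hi) > r && tries < 60) { hi <- hi * 2; tries <- tries + 1 }
    n_lo <- tryCatch(norm_at(lo), error = function(e) NA_real_)
    if (is.finite(n_lo) && n_lo >= r && norm_at(hi) <= r) {
      mu <- tryCatch(
        stats::uniroot(function(m) norm_at(m) - r, c(lo, hi),
                       tol = 1e-12)$root,
        error = function(e) NA_real_)
      if (is.finite(mu)) {
        z <- drop(solve(mu * diag(k) - qf$B, half_g))
        ok <- TRUE
      }
    }
    tibble::tibble(radius = r,
                   !!!stats::setNames(as.list(z), paste0(fit$factors$name, "_coded")),
                   !!!to_actual(fit$factors, actual_row(fit$factors, z)),
                   .pred = if (ok) predict(fit, z, units = "coded") else NA_real_,
                   converged = ok)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "factors") <- fit$factors
  class(out) <- c("ridge_path", class(out))
  out
}

#' @method autoplot ridge_path
#' @export
autoplot.ridge_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$radius, .data$.pred)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "radius (coded units)", y = "predicted response") +
    ggplot2::theme_minimal()
}

#' Box-constrained maximization of the fitted surface
#'
#' Global maximum of the quadratic over a coded hypercube, by multi-start
#' projected quasi-Newton optimization: one start on every vertex-and-center
#' coarse lattice point plus seeded random interior starts. For a quadratic
#' over a box at this scale the multi-start search reliably returns the
#' global optimum.
#'
#' @param fit An [fit_quadratic()] object.
#' @param lower,upper Coded bounds, recycled over factors (default -2, 2).
#' @param n_random Extra random starts (default 64).
#' @param seed Seed for the random starts (default 1).
#' @return A list: `par_coded`, `par_actual` (tibble), `value` (predicted
#'   response at the optimum), `active` (names of factors sitting on a
#'   bound).
#' @export
#' @examples
#' box_constrained_max(fit_quadratic(cga_runs()))
box_constrained_max <- function(fit, lower = -2, upper = 2,
                                n_random = 64, seed = 1) {
  qf <- quad_form(fit)
  k <- length(qf$g)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  stopifnot(all(lower < upper))
  negf <- function(z) -(qf$b0 + sum(qf$g * z) + drop(t(z) %*% qf$B %*% z))
  negg <- function(z) -(qf$g + 2 * drop(qf$B %*% z))

  lattice <- as.matrix(expand.grid(purrr::map2(lower, upper,
                                               ~c(.x, (.x + .y) / 2, .y))))
  rand <- with_seed_local(seed, matrix(stats::runif(n_random * k), n_random, k))
  rand <- sweep(sweep(rand, 2, upper - lower, "*"), 2, lower, "+")
  starts <- rbind(lattice, rand)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], negf, negg, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 10))
    if (is.null(best) || o$value < best$value - 1e-12) best <- o
  }
  z <- best$par
  active <- fit$factors$name[z <= lower + 1e-6 | z >= upper - 1e-6]
  list(par_coded = stats::setNames(z, fit$factors$name),
       par_actual = to_actual(fit$factors, actual_row(fit$factors, z)),
       value = predict(fit, z, units = "coded"),
       active = active)
}
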