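# Synthetic CCRD experiments from a known quadratic truth: the designed runs
# are evaluated under a user-chosen coefficient set and homoscedastic
# Gaussian replicate noise is added, emulating the data-generating
# assumptions behind a duplicate-mean CCRD response table. The default truth
# is the packaged chlorogenic-acid surface and the default noise matches its
# replicated-center pure-error scale.

#' Specification for a synthetic CCRD experiment
#'
#' @param factors Factor table (default [cga_factors()]).
#' @param truth Named coefficient vector in the [fit_quadratic()] term
#'   layout, or an `rsm_fit` whose coefficients to reuse. Defaults to the
#'   quadratic surface fitted to the packaged chlorogenic-acid runs.
#' @param truth_units Units of a coefficient-vector `truth`: `"coded"` or
#'   `"actual"`.
#' @param noise_sd Replicate noise standard deviation in response units.
#'   The default 0.12 mg/g matches the pure-error scale of the packaged
#'   data's replicated center points; `noise_sd = 4.95` is a high-noise
#'   preset at that fit's residual standard deviation.
#' @param n_center Center replicates in the design (default 3).
#' @param n_replicates Technical replicates averaged per run (default 2,
#'   emulating duplicate determinations).
#' @param alpha Axial distance; default rotatable.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(factors = cga_factors(), truth = NULL,
                           truth_units = c("actual", "coded"),
                           noise_sd = 0.12, n_center = 3, n_replicates = 2,
                           alpha = NULL) {
  truth_units <- match.arg(truth_units)
  check_factors(factors)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be a non-negative number", call. = FALSE)
  }
  if (is.null(truth)) {
    truth <- coef(fit_quadratic(cga_runs()), units = "coded")
    truth_units <- "coded"
  } else if (inherits(truth, "rsm_fit")) {
    truth <- coef(truth, units = "coded")
    truth_units <- "coded"
  } else {
    expected <- quad_term_names(factors)
    if (length(truth) != length(expected)) {
      stop("'truth' must have the full second-order term structure (",
           length(expected), " coefficients)", call. = FALSE)
    }
    if (truth_units == "actual") {
      names(truth) <- expected
      truth <- convert_quad_coef(truth, factors, from = "actual")
      truth_units <- "coded"
    }
    names(truth) <- expected
  }
  structure(list(factors = factors, truth = truth, truth_units = truth_units,
                 noise_sd = noise_sd, n_center = n_center,
                 n_replicates = n_replicates, alpha = alpha),
            class = "synthetic_spec")
}

#' Generate a synthetic CCRD response table
#'
#' Evaluates the true quadratic at every design point and adds i.i.d.
#' Gaussian noise per technical replicate; the table stores the replicate
#' mean (and standard deviation when `n_replicates > 1`), mirroring how
#' duplicate determinations are reported. Deterministic given `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A run tibble compatible with [fit_quadratic()] and [train_mlp()]
#'   (columns: `run`, `block`, factor actual units, `yield`, `yield_sd`),
#'   with the factor table attached and the truth stored as attribute
#'   `"truth"`.
#' @export
#' @examples
#' spec <- synthetic_spec(noise_sd = 0)
#' runs <- generate_synthetic(spec, seed = 1)
generate_synthetic <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  design <- build_ccrd(spec$factors, alpha = spec$alpha,
                       n_center = spec$n_center)
  Z <- as.matrix(design[paste0(spec$factors$name, "_coded")])
  colnames(Z) <- spec$factors$name
  mu <- drop(quad_model_matrix(Z, spec$factors) %*% spec$truth)
  n <- length(mu)
  reps <- with_seed_local(seed, matrix(stats::rnorm(n * spec$n_replicates,
                                                    mean = mu,
                                                    sd = spec$noise_sd),
                                       nrow = n))
  out <- design[c("run", "block", spec$factors$name)]
  out$yield <- rowMeans(reps)
  out$yield_sd <- if (spec$n_replicates > 1) apply(reps, 1, stats::sd) else NA_real_
  attr(out, "factors") <- spec$factors
  attr(out, "truth") <- spec$truth
  out
}
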