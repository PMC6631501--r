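#' Build a central composite rotatable design
#'
#' Constructs the classical central composite design for `k` factors: a full
#' two-level factorial core (coded -1/+1), `2k` axial points at coded
#' `+/-alpha` on each axis, and `n_center` replicated center points. With the
#' rotatable axial distance `alpha = (2^k)^(1/4)` (the default) the design's
#' prediction variance depends only on the distance from the center.
#'
#' @param factors Factor table (one row per factor, see [factor_spec()]).
#' @param alpha Axial distance in coded units; defaults to the rotatable
#'   value `(2^k)^(1/4)`, which is 2 for four factors.
#' @param n_center Number of center replicates (default 3).
#' @param randomize Permute run order? Defaults to `FALSE`: model fitting is
#'   order-invariant, so the systematic order (factorial, axial, center) is
#'   kept unless a run sheet for the bench is wanted.
#' @param seed Integer seed used when `randomize = TRUE`.
#'
#' @return A tibble with one row per run: `run`, `block`
#'   (`"factorial"`, `"axial"` or `"center"`), one `<name>_coded` column per
#'   factor and one `<name>` column with the actual setting. The factor table
#'   travels along as attribute `"factors"`.
#' @export
#' @examples
#' build_ccrd(cga_factors())            # the 27-run design
#' build_ccrd(cga_factors()[1:2, ], n_center = 1)
build_ccrd <- function(factors, alpha = NULL, n_center = 3,
                       randomize = FALSE, seed = NULL) {
  check_factors(factors)
  k <- nrow(factors)
  if (k < 2 || k > 8) stop("build_ccrd supports 2 to 8 factors", call. = FALSE)
  if (!is.numeric(n_center) || n_center < 1 || n_center != round(n_center)) {
    stop("invalid design specification: 'n_center' must be a positive integer",
         call. = FALSE)
  }
  if (is.null(alpha)) alpha <- (2^k)^(1 / 4)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("invalid design specification: 'alpha' must be positive", call. = FALSE)
  }

  factorial <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -alpha
    axial[2 * j, j] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(factorial, axial, center)
  colnames(coded) <- factors$name
  block <- rep(c("factorial", "axial", "center"),
               c(nrow(factorial), nrow(axial), n_center))

  ord <- seq_len(nrow(coded))
  if (isTRUE(randomize)) {
    ord <- with_seed_local(seed, sample(ord))
  }
  coded <- coded[ord, , drop = FALSE]
  block <- block[ord]

  coded_df <- tibble::as_tibble(coded)
  names(coded_df) <- paste0(factors$name, "_coded")
  actual_df <- to_actual(factors, stats::setNames(tibble::as_tibble(coded),
                                                  factors$name))
  out <- dplyr::bind_cols(
    tibble::tibble(run = seq_len(nrow(coded)), block = block),
    coded_df, actual_df
  )
  attr(out, "factors") <- factors
  out
}

#' Extract the factor table attached to a design or model object
#'
#' @param x A design from [build_ccrd()], an experiment table from
#'   [load_fixture()], or a fitted model.
#' @return The factor tibble.
#' @export
design_factors <- function(x) {
  fs <- attr(x, "factors")
  if (is.null(fs) && inherits(x, c("rsm_fit", "mlp_fit"))) fs <- x$factors
  if (is.null(fs)) stop("no factor table attached to this object", call. = FALSE)
  fs
}
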