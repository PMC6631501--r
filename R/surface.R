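#' Evaluate the fitted surface on a rectangular two-factor grid
#'
#' Holds all but two factors fixed and evaluates the model prediction on a
#' regular grid, the numeric content of the familiar contour plot.
#'
#' @param fit An [fit_quadratic()] object (an [train_mlp()] surrogate works
#'   too, through its `predict` method).
#' @param vary Character vector of two factor names to vary.
#' @param fixed Named list/vector of settings for the remaining factors;
#'   defaults to the design center. Interpreted per `fixed_units`.
#' @param resolution Grid points per axis (default 50).
#' @param coded_range Coded interval spanned by each varied axis,
#'   default `c(-2, 2)`.
#' @param fixed_units Units of `fixed`: `"actual"` (default) or `"coded"`.
#'
#' @return A tibble with the two varied factors in actual units and the
#'   prediction in `.pred`; the fixed settings are attached as attribute
#'   `"fixed"`.
#' @export
#' @examples
#' fit <- fit_quadratic(cga_runs())
#' g <- evaluate_surface_grid(fit, c("ethanol", "ls_ratio"), resolution = 11)
#' g[which.max(g$.pred), ]
evaluate_surface_grid <- function(fit, vary, fixed = NULL, resolution = 50,
                                  coded_range = c(-2, 2),
                                  fixed_units = c("actual", "coded")) {
  fixed_units <- match.arg(fixed_units)
  factors <- design_factors(fit)
  stopifnot(length(vary) == 2, !anyDuplicated(vary))
  if (!all(vary %in% factors$name)) {
    stop("unknown factor(s): ",
         paste(setdiff(vary, factors$name), collapse = ", "), call. = FALSE)
  }
  others <- setdiff(factors$name, vary)

  fixed_coded <- stats::setNames(rep(0, length(others)), others)
  if (!is.null(fixed)) {
    fixed <- unlist(fixed)
    extra <- setdiff(names(fixed), others)
    if (length(extra)) stop("fixed settings given for varied or unknown factors: ",
                            paste(extra, collapse = ", "), call. = FALSE)
    for (nm in names(fixed)) {
      fs <- factors[factors$name == nm, ]
      fixed_coded[nm] <- if (fixed_units == "actual") {
        to_coded(fs, fixed[[nm]], quiet = TRUE)
      } else {
        fixed[[nm]]
      }
    }
  }

  ax <- seq(coded_range[1], coded_range[2], length.out = resolution)
  grid <- tidyr::expand_grid(a = ax, b = ax)
  coded <- tibble::tibble(!!vary[1] := grid$a, !!vary[2] := grid$b)
  for (nm in others) coded[[nm]] <- fixed_coded[[nm]]
  coded <- coded[factors$name]
  actual <- to_actual(factors, coded)
  out <- actual[vary]
  out$.pred <- predict(fit, actual, units = "actual")
  attr(out, "fixed") <- to_actual(factors[factors$name %in% others, ],
                                  tibble::as_tibble(as.list(fixed_coded))[others])
  out
}

#' Contour plot of a fitted surface over two factors
#'
#' @inheritParams evaluate_surface_grid
#' @param ... Passed to [evaluate_surface_grid()].
#' @return A ggplot object.
#' @export
plot_surface <- function(fit, vary, ...) {
  g <- evaluate_surface_grid(fit, vary, ...)
  factors <- design_factors(fit)
  lab <- function(nm) {
    fs <- factors[factors$name == nm, ]
    paste0(nm, " (", fs$unit, ")")
  }
  ggplot2::ggplot(g, ggplot2::aes(.data[[vary[1]]], .data[[vary[2]]],
                                  z = .data$.pred)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::labs(x = lab(vary[1]), y = lab(vary[2]),
                  fill = "predicted\nyield") +
    ggplot2::theme_minimal()
}
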