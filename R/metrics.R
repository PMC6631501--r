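# Model-comparison statistics between experimental and predicted yields:
#   R2   = 1 - sum((Ypre - Yexp)^2) / sum((Ym - Yexp)^2)
#   RMSE = sqrt(sum((Ypre - Yexp)^2) / n)
#   AAD% = 100 * mean(|Yexp - Ypre| / Ypre)
# The AAD denominator is the *predicted* value; the more common /Yexp
# convention is available behind `aad_denominator`.

#' Fit statistics between experimental and predicted responses
#'
#' @param experimental Observed responses (mg/g).
#' @param predicted Model predictions, same length.
#' @param aad_denominator Denominator convention for the absolute average
#'   deviation: `"predicted"` (default) or `"experimental"`.
#' @return One-row tibble: `n`, `r.squared`, `rmse`, `aad` (percent),
#'   `mean_response`.
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
compute_metrics <- function(experimental, predicted,
                            aad_denominator = c("predicted", "experimental")) {
  aad_denominator <- match.arg(aad_denominator)
  stopifnot(length(experimental) == length(predicted))
  n <- length(experimental)
  if (n < 2) stop("need at least two pairs", call. = FALSE)
  denom <- if (aad_denominator == "predicted") predicted else experimental
  if (any(denom == 0)) {
    stop("AAD undefined: zero ", aad_denominator, " value", call. = FALSE)
  }
  sse <- sum((predicted - experimental)^2)
  tibble::tibble(
    n = n,
    r.squared = 1 - sse / sum((mean(experimental) - experimental)^2),
    rmse = sqrt(sse / n),
    aad = 100 * mean(abs(experimental - predicted) / denom),
    mean_response = mean(experimental)
  )
}

#' Head-to-head comparison of surrogate models
#'
#' Computes [compute_metrics()] for each fitted model over the design runs
#' and, when supplied, over an external validation table and the pooled set,
#' and tabulates which model wins each metric on the design runs.
#'
#' @param data Design run table with measured responses.
#' @param ... Named fitted models (anything with a `predict` method taking
#'   the run table), e.g. `rsm = fit, ann = net`.
#' @param validation Optional external validation run table.
#' @param response Response column name (default `"yield"`).
#' @return An object of class `model_comparison`: `metrics` (tibble with
#'   `model`, `set`, and the metric columns), `scatter` (per-run experimental
#'   vs predicted values for export or plotting), `winner` (named character:
#'   best model per metric on the design set).
#' @export
#' @examples
#' runs <- cga_runs()
#' cmp <- compare_models(runs, rsm = fit_quadratic(runs),
#'                       validation = cga_validation())
#' cmp$metrics
compare_models <- function(data, ..., validation = NULL, response = "yield") {
  models <- list(...)
  if (!length(models) || is.null(names(models)) || any(names(models) == "")) {
    stop("supply named models, e.g. compare_models(data, rsm = fit)",
         call. = FALSE)
  }
  sets <- list(design = data)
  if (!is.null(validation)) {
    sets$validation <- validation
    pooled <- dplyr::bind_rows(data[intersect(names(data), names(validation))],
                               validation[intersect(names(data), names(validation))])
    attr(pooled, "factors") <- attr(data, "factors")
    sets$pooled <- pooled
  }

  metrics <- purrr::imap_dfr(sets, function(tab, set_name) {
    purrr::imap_dfr(models, function(m, model_name) {
      pred <- suppressWarnings(predict(m, tab))
      dplyr::bind_cols(tibble::tibble(model = model_name, set = set_name),
                       compute_metrics(tab[[response]], pred))
    })
  })

  scatter <- purrr::imap_dfr(sets[setdiff(names(sets), "pooled")],
                             function(tab, set_name) {
    out <- tibble::tibble(set = set_name,
                          run = tab$run %||% seq_len(nrow(tab)),
                          experimental = tab[[response]])
    for (nm in names(models)) {
      out[[paste0(nm, "_pred")]] <- suppressWarnings(predict(models[[nm]], tab))
    }
    out
  })

  design_m <- metrics[metrics$set == "design", ]
  winner <- c(
    r.squared = design_m$model[which.max(design_m$r.squared)],
    rmse = design_m$model[which.min(design_m$rmse)],
    aad = design_m$model[which.min(design_m$aad)]
  )
  structure(list(metrics = metrics, scatter = scatter, winner = winner),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Surrogate-model comparison\n")
  print(as.data.frame(x$metrics), digits = 4)
  cat("\nBest on design runs:",
      paste(names(x$winner), x$winner, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$metrics

#' Experimental-versus-predicted scatter plot
#'
#' @param object A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object, one panel per model, identity line shown.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scatter,
                              cols = dplyr::ends_with("_pred"),
                              names_to = "model", values_to = "predicted")
  long$model <- sub("_pred$", "", long$model)
  ggplot2::ggplot(long, ggplot2::aes(.data$experimental, .data$predicted,
                                     colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "experimental yield (mg/g)",
                  y = "predicted yield (mg/g)") +
    ggplot2::theme_minimal()
}
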