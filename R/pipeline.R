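# End-to-end orchestration: design -> quadratic fit -> ANOVA -> optimum ->
# perceptron surrogate -> comparison, with every artifact written as
# delimited text or JSON into an output directory. The configuration is a
# plain named list (or a YAML file of one); every stage default mirrors the
# packaged study settings.

default_config <- function() {
  list(
    input = NULL,                 # path to a run TSV; NULL = packaged runs
    validation = NULL,            # path to a validation TSV; NULL = packaged
    use_packaged_validation = TRUE,
    output_dir = "extractopt-output",
    response = "yield",
    design = list(alpha = 2, n_center = 3),
    ann = list(hidden = 10, restarts = 60, split = c(0.70, 0.15, 0.15),
               seed = 1),
    optimization = list(lower = -2, upper = 2),
    seed = 1
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in c("design", "ann", "optimization")) {
    if (!is.null(config[[section]])) {
      bad <- setdiff(names(config[[section]]), names(base[[section]]))
      if (length(bad)) {
        stop("unknown configuration key(s) in '", section, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  cfg <- utils::modifyList(base, config)
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    stop("input file not found: ", cfg$input, call. = FALSE)
  }
  if (!is.null(cfg$validation) && !file.exists(cfg$validation)) {
    stop("validation file not found: ", cfg$validation, call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Fits the quadratic response-surface model, produces the ANOVA table,
#' maximizes the surface over the coded design region, trains the perceptron
#' surrogate, compares the two models, and writes every result (plus a
#' provenance block with seeds and the configuration echo) into
#' `output_dir`. Re-running with the same inputs and seeds reproduces the
#' same files.
#'
#' @param config Named list of options, or path to a YAML file containing
#'   one. See the package vignette; unset keys fall back to defaults that
#'   mirror the packaged chlorogenic-acid study.
#' @return Invisibly, a list with the fitted objects (`rsm`, `anova`,
#'   `optimum`, `ann`, `comparison`) and the output paths.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(output_dir = tempfile(),
#'                          ann = list(restarts = 2)))
#' out$comparison$metrics
#' }
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  runs <- if (is.null(cfg$input)) {
    cga_runs()
  } else {
    tab <- readr::read_tsv(cfg$input, show_col_types = FALSE, progress = FALSE)
    attr(tab, "factors") <- cga_factors()
    tab
  }
  validation <- if (!is.null(cfg$validation)) {
    readr::read_tsv(cfg$validation, show_col_types = FALSE, progress = FALSE)
  } else if (isTRUE(cfg$use_packaged_validation)) {
    cga_validation()
  } else {
    NULL
  }

  fit <- fit_quadratic(runs, response = cfg$response)
  an <- rsm_anova(fit)
  opt <- box_constrained_max(fit, lower = cfg$optimization$lower,
                             upper = cfg$optimization$upper,
                             seed = cfg$seed)
  ann <- train_mlp(runs, response = cfg$response,
                   hidden = cfg$ann$hidden, restarts = cfg$ann$restarts,
                   split = cfg$ann$split, seed = cfg$ann$seed)
  cmp <- compare_models(runs, rsm = fit, ann = ann, validation = validation,
                        response = cfg$response)

  p <- function(f) file.path(cfg$output_dir, f)
  readr::write_tsv(tibble::tibble(term = names(coef(fit)),
                                  coded = unname(coef(fit)),
                                  actual = unname(coef(fit, units = "actual"))),
                   p("coefficients.tsv"))
  readr::write_tsv(an$table, p("anova.tsv"))
  readr::write_tsv(an$summary, p("anova_summary.tsv"))
  jsonlite::write_json(
    list(settings_actual = as.list(opt$par_actual),
         settings_coded = as.list(opt$par_coded),
         predicted = opt$value, active_bounds = opt$active),
    p("optimum.json"), digits = NA, auto_unbox = TRUE)
  write_mlp(ann, p("ann_model.json"))
  readr::write_tsv(cmp$metrics, p("comparison_metrics.tsv"))
  readr::write_tsv(cmp$scatter, p("comparison_scatter.tsv"))
  jsonlite::write_json(
    list(package = "extractopt",
         version = as.character(utils::packageVersion("extractopt")),
         seeds = list(pipeline = cfg$seed, ann = cfg$ann$seed),
         config = cfg),
    p("provenance.json"), auto_unbox = TRUE, null = "null")

  invisible(list(rsm = fit, anova = an, optimum = opt, ann = ann,
                 comparison = cmp, output_dir = cfg$output_dir))
}
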