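#' Define a process factor for a coded experimental design
#'
#' A factor is described by the actual value at coded level 0 (`center`) and
#' the actual increment corresponding to one coded unit (`step`), so that the
#' five levels of a central composite rotatable design sit at
#' `center + c * step` for coded `c` in -2, -1, 0, +1, +2.
#'
#' @param name Factor name (used as a column name in design tables).
#' @param unit Text label for the actual unit (e.g. `"degC"`, `"%"`).
#' @param center Actual value at coded zero.
#' @param step Actual increment per coded unit; must be positive.
#' @param symbol Short symbol such as `"X1"`; defaults to the name.
#'
#' @return A one-row tibble with columns `name`, `unit`, `symbol`, `center`,
#'   `step`. Bind several together (or use [cga_factors()]) to describe a
#'   multi-factor design.
#' @export
#' @examples
#' factor_spec("temperature", "degC", center = 50, step = 10, symbol = "X1")
factor_spec <- function(name, unit, center, step, symbol = name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(step) || step <= 0) {
    stop("invalid factor specification: 'step' must be a positive number",
         call. = FALSE)
  }
  if (!is.finite(center)) {
    stop("invalid factor specification: 'center' must be finite", call. = FALSE)
  }
  tibble::tibble(name = name, unit = unit, symbol = symbol,
                 center = as.numeric(center), step = as.numeric(step))
}

check_factors <- function(factors) {
  req <- c("name", "symbol", "center", "step")
  if (!is.data.frame(factors) || !all(req %in% names(factors))) {
    stop("'factors' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(factors$step)) || any(factors$step <= 0)) {
    stop("invalid factor specification: all steps must be positive",
         call. = FALSE)
  }
  if (anyDuplicated(factors$name)) {
    stop("factor names must be unique", call. = FALSE)
  }
  invisible(factors)
}

#' Convert between coded and actual factor units
#'
#' `to_coded()` maps actual settings to coded units via
#' `(actual - center) / step`; `to_actual()` is the exact inverse. Both are
#' vectorized: given the multi-row factor table they convert a data frame
#' column-by-column, and given a single factor row they convert a numeric
#' vector.
#'
#' Values beyond coded +/-2 are allowed (the model can be evaluated outside
#' the design region) but `to_coded()` emits a message so extrapolation does
#' not pass silently.
#'
#' @param factors Factor table from [factor_spec()] or [cga_factors()].
#' @param x Numeric vector (single-factor case) or data frame containing one
#'   column per factor name.
#' @param quiet Suppress the extrapolation message.
#'
#' @return Same shape as `x`, in the other unit system.
#' @export
#' @examples
#' fs <- cga_factors()
#' to_coded(fs, data.frame(temperature = 70, ethanol = 75,
#'                         ls_ratio = 30, power = 120))
to_coded <- function(factors, x, quiet = FALSE) {
  check_factors(factors)
  if (is.data.frame(x)) {
    missing_cols <- setdiff(factors$name, names(x))
    if (length(missing_cols)) {
      stop("missing factor columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    out <- x
    for (i in seq_len(nrow(factors))) {
      nm <- factors$name[i]
      out[[nm]] <- (x[[nm]] - factors$center[i]) / factors$step[i]
    }
    coded <- as.matrix(out[factors$name])
  } else {
    stopifnot(nrow(factors) == 1L)
    out <- (x - factors$center) / factors$step
    coded <- out
  }
  if (!quiet && any(abs(coded) > 2 + 1e-8, na.rm = TRUE)) {
    message("to_coded: some settings lie outside the coded design range [-2, 2]")
  }
  out
}

#' @rdname to_coded
#' @export
to_actual <- function(factors, x) {
  check_factors(factors)
  if (is.data.frame(x)) {
    missing_cols <- setdiff(factors$name, names(x))
    if (length(missing_cols)) {
      stop("missing factor columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    out <- x
    for (i in seq_len(nrow(factors))) {
      nm <- factors$name[i]
      out[[nm]] <- x[[nm]] * factors$step[i] + factors$center[i]
    }
    out
  } else {
    stopifnot(nrow(factors) == 1L)
    x * factors$step + factors$center
  }
}
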