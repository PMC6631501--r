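# ANOVA decomposition for the quadratic response-surface fit, in the style
# of dedicated DoE software: partial (Type-III) single-degree-of-freedom sums
# of squares per term, lack of fit split against pure error from replicated
# design points, PRESS from the hat matrix, and the usual summary diagnostics.

#' ANOVA table and diagnostics for a response-surface fit
#'
#' Per-term sums of squares are partial (Type III): the increase in residual
#' sum of squares when that single column is deleted from the full model,
#' each tested on 1 degree of freedom against the residual mean square.
#' Pure error is pooled from all groups of runs with identical settings
#' (for a CCRD, the replicated center points); lack of fit is the remainder
#' of the residual and is tested against pure error. When no replicates
#' exist the lack-of-fit and pure-error F and p are reported as `NA` rather
#' than fabricated. PRESS is computed with the leave-one-out hat-matrix
#' identity `sum((e_i / (1 - h_ii))^2)`.
#'
#' @param fit An [fit_quadratic()] object.
#' @return An object of class `rsm_anova`: a list with `table` (source, sum
#'   of squares, df, mean square, F, p) and `summary` (one-row tibble of
#'   model-level diagnostics). `tidy()` returns the table, `glance()` the
#'   summary.
#' @export
#' @examples
#' rsm_anova(fit_quadratic(cga_runs()))
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  X <- fit$X
  y <- fit$y
  n <- length(y)
  p <- ncol(X)
  df_res <- fit$df_residual
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1
  ms_res <- ss_res / df_res
  ms_mod <- ss_mod / df_mod
  f_mod <- ms_mod / ms_res
  p_mod <- stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE)

  # partial (extra-sum-of-squares) SS: refit with one column deleted
  term_idx <- 2:p
  ss_term <- vapply(term_idx, function(j) {
    rss_red <- sum(qr.resid(qr(X[, -j, drop = FALSE]), y)^2)
    rss_red - ss_res
  }, numeric(1))
  f_term <- ss_term / ms_res
  p_term <- stats::pf(f_term, 1, df_res, lower.tail = FALSE)

  # pure error: pooled within-group SS over replicated settings
  key <- apply(round(fit$Z, 10), 1, paste, collapse = "\r")
  groups <- split(y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- sum(vapply(groups, function(g) length(g) - 1L, integer(1)))
  if (df_pe > 0) {
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    ms_pe <- ss_pe / df_pe
    ms_lof <- ss_lof / df_lof
    f_lof <- ms_lof / ms_pe
    p_lof <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
  } else {
    ss_lof <- ss_res; df_lof <- df_res
    ms_lof <- ss_lof / df_lof
    ms_pe <- f_lof <- p_lof <- NA_real_
  }

  h <- rowSums(qr.Q(fit$qr)^2)
  press <- sum((fit$residuals / (1 - h))^2)

  table <- tibble::tibble(
    source = c("Model", colnames(X)[-1], "Residual", "Lack of Fit",
               "Pure Error", "Cor Total"),
    ss = c(ss_mod, ss_term, ss_res, ss_lof, ss_pe, ss_tot),
    df = c(df_mod, rep(1L, p - 1), df_res, df_lof, df_pe, n - 1L),
    ms = c(ms_mod, ss_term, ms_res, ms_lof,
           if (df_pe > 0) ss_pe / df_pe else NA_real_, NA_real_),
    statistic = c(f_mod, f_term, NA_real_, f_lof, NA_real_, NA_real_),
    p.value = c(p_mod, p_term, NA_real_, p_lof, NA_real_, NA_real_)
  )
  summary <- tibble::tibble(
    r.squared = 1 - ss_res / ss_tot,
    adj.r.squared = 1 - (ss_res / df_res) / (ss_tot / (n - 1)),
    sigma = sqrt(ms_res),
    statistic = f_mod,
    p.value = p_mod,
    press = press,
    cv = 100 * sqrt(ms_res) / mean(y),
    mean_response = mean(y),
    df.residual = df_res,
    nobs = n
  )
  structure(list(table = table, summary = summary), class = "rsm_anova")
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("Response-surface ANOVA (partial sums of squares)\n")
  print(as.data.frame(x$table), digits = 5)
  cat(sprintf("\nR2 %.4f  adj R2 %.4f  sd %.3f  CV%% %.2f  PRESS %.2f\n",
              x$summary$r.squared, x$summary$adj.r.squared,
              x$summary$sigma, x$summary$cv, x$summary$press))
  invisible(x)
}

#' @method tidy rsm_anova
#' @export
tidy.rsm_anova <- function(x, ...) x$table

#' @method glance rsm_anova
#' @export
glance.rsm_anova <- function(x, ...) x$summary
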