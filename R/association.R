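# Hemorrhage-edema association: OLS regression of infarct-zone T2 on T2*.

#' Regress infarct-zone T2 on T2* across subjects
#'
#' Ordinary least squares with intercept over per-subject (T2*, T2) pairs.
#' By default only the hemorrhagic arms (+HEM, I+HEM) enter the fit, matching
#' the convention of plotting the non-hemorrhagic subjects but excluding them
#' from the analysis.
#'
#' @param pairs data.frame with numeric columns `t2star` (X) and `t2` (Y),
#'   and optionally `arm`.
#' @param include_arms arms kept when `pairs$arm` exists (default
#'   `c("+HEM", "I+HEM")`); set `NULL` to keep everything.
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`, `residual_sd`, `included_arms`.
#' @export
fit_t2_vs_t2star <- function(pairs, include_arms = c("+HEM", "I+HEM")) {
  stopifnot(is.data.frame(pairs), all(c("t2star", "t2") %in% names(pairs)))
  if (!is.null(include_arms) && "arm" %in% names(pairs)) {
    pairs <- pairs[pairs$arm %in% include_arms, , drop = FALSE]
  }
  pairs <- pairs[is.finite(pairs$t2star) & is.finite(pairs$t2), , drop = FALSE]
  n <- nrow(pairs)
  if (n < 3) {
    cmrtc_stop(sprintf("need >= 3 pairs for a reportable fit, have %d", n),
      "cmrtc_insufficient_data")
  }
  if (stats::var(pairs$t2star) == 0) {
    cmrtc_stop("zero variance in T2*: slope undefined", "cmrtc_undefined_slope")
  }
  fit <- stats::lm(t2 ~ t2star, data = pairs)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pairs$t2 - mean(pairs$t2))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2, n = n,
      residual_sd = if (n > 2) sqrt(ss_res / (n - 2)) else NA_real_,
      included_arms = include_arms
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> Y = %.3f X + %.2f, R^2 = %.3f, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}
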