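#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for diameter-linearity fits
#'
#' @param x A `diameter_fit` from [diameter_linearity_fit()].
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient of the linear fit (`term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`). `glance()`: a
#'   one-row model summary including both R^2 values and which model the
#'   data prefer.
#' @method tidy diameter_fit
#' @export
tidy.diameter_fit <- function(x, ...) {
  s <- summary(x$fit_linear)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.diameter_fit
#' @method glance diameter_fit
#' @export
glance.diameter_fit <- function(x, ...) {
  tibble(
    response = x$response,
    membrane = x$membrane,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    r.squared.quadratic = x$r_squared_quadratic,
    preferred = if (x$r_squared >= x$r_squared_quadratic) "linear" else "quadratic",
    nobs = stats::nobs(x$fit_linear)
  )
}

#' Tidiers for insertion ANOVA results
#'
#' @param x An `insertion_anova` from [three_factor_anova()].
#' @param ... Unused.
#' @return `tidy()`: one row per model term (`term`, `sumsq`, `df`,
#'   `statistic`, `p.value`). `glance()`: response, membrane, residual df
#'   and number of trials.
#' @method tidy insertion_anova
#' @export
tidy.insertion_anova <- function(x, ...) {
  a <- as.data.frame(x$anova)
  keep <- rownames(a) != "Residuals"
  tibble(
    term = rownames(a)[keep],
    sumsq = a[keep, "Sum Sq"],
    df = a[keep, "Df"],
    statistic = a[keep, "F value"],
    p.value = a[keep, "Pr(>F)"]
  )
}

#' @rdname tidy.insertion_anova
#' @method glance insertion_anova
#' @export
glance.insertion_anova <- function(x, ...) {
  a <- as.data.frame(x$anova)
  tibble(
    response = x$response,
    membrane = x$membrane,
    df.residual = a["Residuals", "Df"],
    sigma = sqrt(a["Residuals", "Sum Sq"] / a["Residuals", "Df"]),
    nobs = x$n
  )
}
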