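#' Pearson product-moment correlation
#'
#' Correlation with its t-based two-sided p value
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df). Requires at least
#' 3 paired values and nonzero variance in both series.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble: `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired values.")
  if (var(x) == 0 || var(y) == 0) {
    abort("Correlation undefined: a series has zero variance.")
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value, n = length(x))
}

#' Simple linear regression of the Bolton ratio on SATR
#'
#' Ordinary least squares of `abr ~ satr` on ratio *fractions* (0.787, not
#' 78.7): the regression operates on the scale on which a relation like
#' `y = 0.503 + 0.328 x` is dimensionally meaningful. Percent inputs
#' (values above 2) are converted internally.
#'
#' `fit_satr_abr()` takes either a width cohort (ratios are computed first)
#' or a data frame already holding `satr_pct`/`abr_pct` (or
#' `satr_frac`/`abr_frac`) columns. `ols_fit()` is the vector interface.
#'
#' @param data A cohort tibble or a per-subject ratio table.
#' @return An object of class `satr_fit` with [tidy()], [glance()],
#'   [predict_abr()] and [autoplot()] methods.
#' @examples
#' cohort <- simulate_cohort(60, scenario = "mixed", seed = 3)$cohort
#' fit <- fit_satr_abr(cohort)
#' glance(fit)
#' @export
fit_satr_abr <- function(data) {
  data <- as_tibble(data)
  if (all(c("fdi", "width_mm") %in% names(data))) {
    data <- tooth_ratios(data)
  }
  if (all(c("satr_pct", "abr_pct") %in% names(data))) {
    x <- data$satr_pct; y <- data$abr_pct
  } else if (all(c("satr_frac", "abr_frac") %in% names(data))) {
    x <- data$satr_frac; y <- data$abr_frac
  } else {
    abort("`data` must be a cohort or carry satr/abr ratio columns.")
  }
  ols_fit(x, y)
}

#' @param x SATR values (fractions or percents).
#' @param y Anterior Bolton ratio values (fractions or percents).
#' @rdname fit_satr_abr
#' @export
ols_fit <- function(x, y) {
  x <- as_fraction(x); y <- as_fraction(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired values.")
  if (var(x) == 0) abort("Regression undefined: predictor is constant.")
  if (var(y) == 0) abort("Regression undefined: response is constant.")
  d <- tibble(satr = x, abr = y)
  model <- lm(abr ~ satr, data = d)
  cor_row <- pearson_r(x, y)
  structure(
    list(model = model,
         intercept = unname(coef(model)[1]),
         slope = unname(coef(model)[2]),
         r = cor_row$r, p = cor_row$p, n = length(x)),
    class = "satr_fit"
  )
}

# ratios above 2 are percents; convert to fractions
as_fraction <- function(v) {
  v <- as.numeric(v)
  ifelse(!is.na(v) & abs(v) > 2, v / 100, v)
}

#' Predict the anterior Bolton ratio from SATR
#'
#' Applies `intercept + slope * satr` on the fraction scale.
#'
#' @param object A `satr_fit`, or a numeric vector `c(intercept, slope)`
#'   (fraction scale, e.g. `c(0.503, 0.328)`).
#' @param satr_value SATR values, fractions or percents.
#' @param scale Output scale: `"percent"` (default) or `"fraction"`.
#' @return Numeric vector of predicted anterior Bolton ratios.
#' @examples
#' predict_abr(c(0.503, 0.328), 0.8569)
#' @export
predict_abr <- function(object, satr_value, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  cf <- if (inherits(object, "satr_fit")) {
    c(object$intercept, object$slope)
  } else if (is.numeric(object) && length(object) == 2) {
    as.numeric(object)
  } else {
    abort("`object` must be a satr_fit or c(intercept, slope).")
  }
  pred <- cf[1] + cf[2] * as_fraction(satr_value)
  if (scale == "percent") 100 * pred else pred
}

#' @export
print.satr_fit <- function(x, ...) {
  cat("SATR-Bolton linear association (OLS on ratio fractions)\n")
  cat(sprintf("  abr = %.4f + %.4f * satr   (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$r, x$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.satr_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("(Intercept)", "satr"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::glance
glance.satr_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(r = x$r, r.squared = s$r.squared, sigma = s$sigma,
         p.value = x$p, n = x$n)
}
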