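#' Normative mean ± k·SD standard
#'
#' A reference interval for a tooth-size ratio: values inside
#' `[mean - k*sd, mean + k*sd]` are normal, below deficient, above excess.
#' Two built-in standards ship with the package:
#'
#' * [satr_standard()] — SATR 85.69% ± 3.57% (normal 82.12–89.26%), from
#'   132 post-treatment models with perfect occlusion;
#' * [bolton_standard()] — anterior Bolton ratio 78.8% ± 1.72% (normal
#'   77.08–80.52%), the Chinese normative value.
#'
#' @param mean Mean of the reference population, percent.
#' @param sd Sample SD, percent (n − 1 denominator convention).
#' @param k SD multiplier defining the normal band (default 1: the published
#'   thresholds equal mean ± 1·SD exactly).
#' @param n Sample size behind the standard (`NA` if unknown).
#' @return An object of class `norm_standard`: a list with `mean`, `sd`,
#'   `k`, `lower`, `upper`, `n`.
#' @export
norm_standard <- function(mean, sd, k = 1, n = NA_integer_) {
  if (!is.numeric(mean) || !is.numeric(sd) || sd < 0 || k < 0) {
    abort("`mean` and `sd` must be numeric with sd >= 0 and k >= 0.")
  }
  structure(
    list(mean = mean, sd = sd, k = k,
         lower = mean - k * sd, upper = mean + k * sd, n = n),
    class = "norm_standard"
  )
}

#' @rdname norm_standard
#' @export
satr_standard <- function(k = 1) norm_standard(85.69, 3.57, k = k, n = 132L)

#' @rdname norm_standard
#' @export
bolton_standard <- function(k = 1) norm_standard(78.8, 1.72, k = k)

#' @export
print.norm_standard <- function(x, ...) {
  cat(sprintf(
    "Normative standard: %.2f%% +/- %g x %.2f%%  (normal %.2f-%.2f%%%s)\n",
    x$mean, x$k, x$sd, x$lower, x$upper,
    if (is.na(x$n)) "" else sprintf(", n = %d", x$n)
  ))
  invisible(x)
}

#' Establish a normative standard from observed ratio values
#'
#' Computes the mean and sample SD (n − 1) of a set of ratio values and the
#' mean ± k·SD normal band.
#'
#' @param values_pct Numeric ratio values in percent (at least 2).
#' @param k SD multiplier (default 1).
#' @return A [norm_standard()] object with `n = length(values_pct)`.
#' @examples
#' establish_standard(c(84, 86))
#' @export
establish_standard <- function(values_pct, k = 1) {
  values_pct <- as.numeric(values_pct)
  if (length(values_pct) < 2) {
    abort("Need at least 2 values to establish a standard.")
  }
  norm_standard(mean(values_pct), sd(values_pct), k = k,
                n = length(values_pct))
}

#' Classify ratio values against a normative standard
#'
#' Values strictly below the lower bound are `deficient`, strictly above the
#' upper bound `excess`, otherwise `normal` (bounds inclusive to normal,
#' the same convention as [assign_bolton_group()]).
#'
#' @param values_pct Numeric ratio values in percent.
#' @param standard A [norm_standard()] object.
#' @param strict_paper If `TRUE`, compare against thresholds rounded to
#'   2 decimals (the printed table values) instead of full precision.
#' @return An ordered factor with levels `deficient < normal < excess`.
#' @examples
#' classify_ratio(c(80, 85.5, 90), satr_standard())
#' @export
classify_ratio <- function(values_pct, standard, strict_paper = FALSE) {
  stopifnot(inherits(standard, "norm_standard"))
  values_pct <- as.numeric(values_pct)
  if (any(values_pct <= 0, na.rm = TRUE)) abort("Ratios must be positive.")
  lo <- if (strict_paper) round(standard$lower, 2) else standard$lower
  hi <- if (strict_paper) round(standard$upper, 2) else standard$upper
  # tie tolerance: thresholds derived from printed decimals (mean - k*sd)
  # are not exactly representable in binary; values equal to a bound at
  # decimal precision stay in the inclusive normal band
  eps <- 1e-9
  lab <- ifelse(values_pct < lo - eps, "deficient",
                ifelse(values_pct > hi + eps, "excess", "normal"))
  factor(lab, levels = c("deficient", "normal", "excess"), ordered = TRUE)
}
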