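#' Bolton-ratio stratification bounds
#'
#' The anterior Bolton ratio cut-offs separating low, normal and high
#' groups. Defaults are the Chinese normative interval 78.8% ± 1.72%,
#' i.e. 77.08% and 80.52%; both boundary values belong to the normal group
#' (the interval is written closed, strict inequalities mark the outer
#' groups).
#'
#' @param low Upper limit of the low group, percent.
#' @param high Lower limit of the high group, percent.
#' @return A list of class `bolton_bounds`.
#' @export
bolton_bounds <- function(low = 77.08, high = 80.52) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    abort("`low` must be numeric and strictly below `high`.")
  }
  structure(list(low = low, high = high), class = "bolton_bounds")
}

#' Assign anterior Bolton ratio values to low/normal/high groups
#'
#' @param abr_pct Numeric vector of anterior Bolton ratios in percent.
#' @param bounds A [bolton_bounds()] object.
#' @return An ordered factor with levels `low < normal < high`. Boundary
#'   values are assigned to `normal`.
#' @examples
#' assign_bolton_group(c(76, 78.8, 81))
#' @export
assign_bolton_group <- function(abr_pct, bounds = bolton_bounds()) {
  stopifnot(inherits(bounds, "bolton_bounds"))
  if (any(abr_pct <= 0, na.rm = TRUE)) abort("Ratios must be positive.")
  eps <- 1e-9  # decimal-boundary ties resolve to normal
  lab <- ifelse(abr_pct < bounds$low - eps, "low",
                ifelse(abr_pct > bounds$high + eps, "high", "normal"))
  factor(lab, levels = c("low", "normal", "high"), ordered = TRUE)
}

# Levene's test centred at the group mean: pooled one-way ANOVA on the
# absolute deviations |x - mean(group)|. Returns NA when every deviation is
# zero (no variance information, treated as homogeneous upstream).
levene_p <- function(a, b) {
  dev <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (all(dev == 0)) return(NA_real_)
  if (var(dev[g == "a"]) == 0 && var(dev[g == "b"]) == 0) return(NA_real_)
  oneway.test(dev ~ g, var.equal = TRUE)$p.value
}

#' Two-sample t test for tooth widths
#'
#' Independent-samples t test with an explicit variance-handling policy:
#' `"pooled"` (Student), `"welch"`, or `"auto"` — pooled when Levene's test
#' (centred at the mean) does not reject homogeneity at 0.05, Welch
#' otherwise. The statistic is computed as `mean(a) - mean(b)` scaled, so
#' its sign follows the argument order.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param variant `"auto"`, `"pooled"` or `"welch"`.
#' @return A one-row tibble: `t`, `df`, `p`, `variant` (the variant actually
#'   used), `levene_p` (`NA` unless `variant = "auto"`).
#' @examples
#' width_t_test(c(1, 2, 3), c(2, 3, 4), variant = "pooled")
#' @export
width_t_test <- function(a, b, variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each sample needs at least 2 values.")
  }

  lp <- NA_real_
  if (var(a) == 0 && var(b) == 0) {
    # degenerate: no within-group variability
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1,
                    variant = "pooled", levene_p = lp))
    }
    abort("Zero variance in both samples with unequal means: t undefined.")
  }

  used <- variant
  if (variant == "auto") {
    lp <- levene_p(a, b)
    used <- if (is.na(lp) || lp > 0.05) "pooled" else "welch"
  }
  ht <- t.test(a, b, var.equal = (used == "pooled"))
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, variant = used, levene_p = lp)
}

#' Pairwise per-tooth-type group comparisons
#'
#' For every (arch, tooth type), compares bilateral mean crown widths
#' between the low/normal/high Bolton groups with independent-samples
#' t tests: normal vs low, normal vs high, and low vs high (18 tests in
#' all). No multiple-testing correction is applied by default; set
#' `p_adjust` to a [stats::p.adjust()] method to correct across the 18
#' tests.
#'
#' @param cohort A Bolton-complete cohort tibble. Group labels are taken
#'   from a `group` column with values low/normal/high; if absent, subjects
#'   are labelled internally from their anterior Bolton ratio via
#'   [assign_bolton_group()].
#' @param variant t-test variance policy, see [width_t_test()].
#' @param bounds Bounds used when labelling internally.
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return A tibble with 18 rows: `arch`, `tooth_type`, `comparison`, `t`,
#'   `df`, `p`, `variant`.
#' @export
pairwise_tooth_tests <- function(cohort,
                                 variant = c("auto", "pooled", "welch"),
                                 bounds = bolton_bounds(),
                                 p_adjust = "none") {
  variant <- match.arg(variant)
  cohort <- check_cohort(cohort)
  if (!"group" %in% names(cohort)) {
    abr <- anterior_bolton_ratio(cohort)
    lab <- tibble(subject_id = abr$subject_id,
                  group = as.character(assign_bolton_group(abr$value_pct,
                                                           bounds)))
    cohort <- inner_join(cohort, lab, by = "subject_id")
  }
  if (!all(cohort$group %in% c("low", "normal", "high"))) {
    abort("Group labels must be 'low', 'normal' or 'high'.")
  }
  sizes <- cohort |> distinct(.data$subject_id, .data$group) |>
    count(.data$group)
  small <- setdiff(c("low", "normal", "high"),
                   sizes$group[sizes$n >= 2])
  if (length(small) > 0) {
    abort(sprintf("Group(s) with fewer than 2 subjects: %s.",
                  paste(small, collapse = ", ")))
  }

  bm <- bilateral_means(select(cohort, -"group")) |>
    inner_join(distinct(cohort, .data$subject_id, .data$group),
               by = "subject_id")

  comparisons <- list(normal_vs_low = c("normal", "low"),
                      normal_vs_high = c("normal", "high"),
                      low_vs_high = c("low", "high"))

  cells <- split(bm, paste(bm$arch, bm$tooth_type, sep = "|"))
  out <- purrr::list_rbind(purrr::map(cells, function(d) {
    purrr::list_rbind(purrr::imap(comparisons, function(gg, cmp) {
      res <- width_t_test(d$width_mm[d$group == gg[1]],
                          d$width_mm[d$group == gg[2]],
                          variant = variant)
      res$arch <- d$arch[1]; res$tooth_type <- d$tooth_type[1]
      res$comparison <- cmp
      res
    }))
  })) |>
    select("arch", "tooth_type", "comparison", "t", "df", "p", "variant")

  if (!identical(p_adjust, "none")) {
    out$p <- stats::p.adjust(out$p, method = p_adjust)
  }
  out
}

#' Select the key tooth type per arch
#'
#' A tooth type qualifies as a key tooth for its arch when all three of its
#' pairwise group comparisons are significant at `alpha`. Exactly one type
#' may qualify per arch; more than one is an ambiguity error, none yields
#' `NA` for that arch.
#'
#' @param tests The 18-row tibble from [pairwise_tooth_tests()].
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `key_teeth` with columns `arch` and
#'   `tooth_type` (`NA` when no type qualifies), and attribute `alpha`.
#' @export
select_key_teeth <- function(tests, alpha = 0.05) {
  needed <- tidyr::expand_grid(
    arch = c("upper", "lower"),
    tooth_type = c("central", "lateral", "canine"),
    comparison = c("normal_vs_low", "normal_vs_high", "low_vs_high")
  )
  if (nrow(anti_join(needed, tests,
                     by = c("arch", "tooth_type", "comparison"))) > 0) {
    abort("`tests` must cover all 18 (arch, tooth_type, comparison) cells.")
  }

  qual <- tests |>
    semi_join(needed, by = c("arch", "tooth_type", "comparison")) |>
    summarise(all_sig = all(.data$p < alpha),
              .by = c("arch", "tooth_type")) |>
    filter(.data$all_sig)

  multi <- qual |> count(.data$arch) |> filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf(
      "Ambiguous key-tooth selection: more than one tooth type qualifies in the %s arch.",
      paste(multi$arch, collapse = " and ")
    ))
  }

  out <- tibble(arch = c("upper", "lower")) |>
    left_join(select(qual, "arch", "tooth_type"), by = "arch")
  structure(out, class = c("key_teeth", class(out)), alpha = alpha)
}
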