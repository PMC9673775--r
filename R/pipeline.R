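#' Analysis pipeline configuration
#'
#' Bundles every constant the pipeline uses. Defaults are the published
#' decision rules: Bolton stratification bounds 77.08/80.52%, SATR standard
#' 85.69% ± 3.57% with k = 1, alpha 0.05, Levene-gated t tests, and
#' `"normal"` as the positive condition of the diagnostic test.
#'
#' @param bolton_low,bolton_high Bolton stratification bounds, percent.
#' @param satr_mean,satr_sd SATR normative standard, percent.
#' @param k SD multiplier of the normal band.
#' @param alpha Significance level for the derivation tests.
#' @param t_variant `"auto"`, `"pooled"` or `"welch"`.
#' @param positive Positive condition of the diagnostic test.
#' @param strict_paper Compare against thresholds rounded to 2 decimals.
#' @param seed Optional integer seed recorded for provenance.
#' @return A list of class `toothratio_config`.
#' @export
pipeline_config <- function(bolton_low = 77.08, bolton_high = 80.52,
                            satr_mean = 85.69, satr_sd = 3.57, k = 1,
                            alpha = 0.05,
                            t_variant = c("auto", "pooled", "welch"),
                            positive = c("normal", "abnormal"),
                            strict_paper = FALSE, seed = NULL) {
  t_variant <- match.arg(t_variant)
  positive <- match.arg(positive)
  structure(
    list(bolton_low = bolton_low, bolton_high = bolton_high,
         satr_mean = satr_mean, satr_sd = satr_sd, k = k, alpha = alpha,
         t_variant = t_variant, positive = positive,
         strict_paper = strict_paper, seed = seed),
    class = "toothratio_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip `read_config(write_config(cfg, path))` is idempotent.
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `toothratio_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "toothratio_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Run the anterior-tooth-ratio analysis pipeline
#'
#' Sequences the analysis stages on one cohort:
#'
#' * `ratio` — per-subject ABR and/or SATR;
#' * `derive` — Bolton-group stratification, the 18 pairwise tooth tests
#'   and the key-tooth selection (needs Bolton-complete records);
#' * `associate` — SATR-ABR correlation and regression (Bolton-complete);
#' * `norm` — a SATR standard established from this cohort (reported
#'   alongside, never silently replacing, the configured standard);
#' * `classify` — SATR diagnosis against the configured standard
#'   (SATR-complete suffices);
#' * `evaluate` — SATR vs gold-standard cross-tables, diagnostic metrics
#'   and the marginal chi-square. The gold diagnosis is the Bolton
#'   classification when the cohort is Bolton-complete, else the `gold`
#'   labels supplied by the caller.
#'
#' @param cohort A cohort tibble.
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("ratio","derive","associate","norm","classify","evaluate")`.
#' @param gold Optional externally supplied gold diagnosis labels
#'   (deficient/normal/excess), aligned with the cohort's subjects in
#'   `subject_id` order; used by `evaluate` when ABR cannot be computed.
#' @return A list of class `toothratio_report` holding one element per
#'   executed stage (tibbles, cross-tables and fitted objects) plus the
#'   `config` used.
#' @examples
#' sim <- simulate_cohort(80, scenario = "mixed", seed = 11)
#' rep <- run_pipeline(sim$cohort, stages = c("ratio", "classify", "evaluate"))
#' rep$evaluate$metrics
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         stages = c("ratio", "derive", "associate", "norm",
                                    "classify", "evaluate"),
                         gold = NULL) {
  stopifnot(inherits(config, "toothratio_config"))
  known <- c("ratio", "derive", "associate", "norm", "classify", "evaluate")
  if (length(stages) == 0) abort("`stages` must name at least one stage.")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")))
  }
  cohort <- check_cohort(cohort)

  bounds <- bolton_bounds(config$bolton_low, config$bolton_high)
  satr_std <- norm_standard(config$satr_mean, config$satr_sd, k = config$k)
  bolton_ok <- all(is_ratio_complete(cohort, "bolton")$complete)
  satr_ok <- all(is_ratio_complete(cohort, "satr")$complete)

  need <- function(stage, ok, what) {
    if (!ok) abort(sprintf("Stage '%s' requires %s.", stage, what))
  }

  report <- list(config = config)

  if ("ratio" %in% stages) {
    report$ratio <- bind_rows(
      if (bolton_ok) anterior_bolton_ratio(cohort),
      if (satr_ok) satr(cohort)
    )
    if (nrow(report$ratio) == 0) {
      abort("Stage 'ratio' requires SATR- or Bolton-complete records.")
    }
  }

  if ("derive" %in% stages) {
    need("derive", bolton_ok, "Bolton-complete records")
    tests <- pairwise_tooth_tests(cohort, variant = config$t_variant,
                                  bounds = bounds)
    report$derive <- list(
      groups = anterior_bolton_ratio(cohort) |>
        mutate(group = assign_bolton_group(.data$value_pct, bounds)) |>
        select("subject_id", abr_pct = "value_pct", "group"),
      tests = tests,
      selection = select_key_teeth(tests, alpha = config$alpha)
    )
  }

  if ("associate" %in% stages) {
    need("associate", bolton_ok && satr_ok, "Bolton-complete records")
    fit <- fit_satr_abr(cohort)
    report$associate <- list(fit = fit, coefficients = tidy(fit),
                             summary = glance(fit))
  }

  if ("norm" %in% stages) {
    need("norm", satr_ok, "SATR-complete records")
    report$norm <- establish_standard(satr(cohort)$value_pct, k = config$k)
  }

  if ("classify" %in% stages) {
    need("classify", satr_ok, "SATR-complete records")
    report$classify <- satr(cohort) |>
      mutate(diagnosis = classify_ratio(.data$value_pct, satr_std,
                                        strict_paper = config$strict_paper)) |>
      select("subject_id", satr_pct = "value_pct", "diagnosis")
  }

  if ("evaluate" %in% stages) {
    need("evaluate", satr_ok, "SATR-complete records")
    cls <- report$classify %||% (satr(cohort) |>
      mutate(diagnosis = classify_ratio(.data$value_pct, satr_std,
                                        strict_paper = config$strict_paper)) |>
      select("subject_id", satr_pct = "value_pct", "diagnosis"))
    gold_labels <- if (bolton_ok) {
      abr <- anterior_bolton_ratio(cohort)
      tibble(subject_id = abr$subject_id,
             gold = as.character(assign_bolton_group(abr$value_pct, bounds)))
    } else if (!is.null(gold)) {
      tibble(subject_id = sort(unique(cohort$subject_id)),
             gold = as.character(gold))
    } else {
      abort("Stage 'evaluate' requires Bolton-complete records or supplied `gold` labels.")
    }
    # the Bolton grouping uses low/normal/high; the diagnosis scale is
    # deficient/normal/excess — identical partitions, renamed
    gold_labels$gold <- c(low = "deficient", normal = "normal",
                          high = "excess",
                          deficient = "deficient", excess = "excess"
    )[gold_labels$gold]
    paired <- inner_join(cls, gold_labels, by = "subject_id")
    t3 <- cross_tabulate(paired$diagnosis, paired$gold)
    t2 <- collapse_to_binary(t3)
    report$evaluate <- list(
      table3 = t3, table2 = t2,
      metrics = diagnostic_metrics(t2, positive = config$positive),
      chi_square = marginal_chi_square(t3)
    )
  }

  structure(report, class = "toothratio_report")
}

#' @export
print.toothratio_report <- function(x, ...) {
  cat("Anterior tooth-ratio analysis report\n")
  cat("  stages:", paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  if (!is.null(x$derive)) {
    sel <- x$derive$selection
    cat(sprintf("  key teeth: upper = %s, lower = %s\n",
                sel$tooth_type[sel$arch == "upper"],
                sel$tooth_type[sel$arch == "lower"]))
  }
  if (!is.null(x$associate)) print(x$associate$fit)
  if (!is.null(x$norm)) print(x$norm)
  if (!is.null(x$evaluate)) {
    print(x$evaluate$metrics)
    print(x$evaluate$chi_square)
  }
  invisible(x)
}
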