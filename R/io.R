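#' Read a cohort of anterior tooth widths from CSV
#'
#' Reads per-subject mesiodistal crown widths (mm) of the permanent anterior
#' teeth. Two layouts are supported:
#'
#' * **wide** — header `subject_id,13,12,11,21,22,23,33,32,31,41,42,43[,group]`,
#'   one row per subject; a subset of tooth columns is allowed (e.g. only the
#'   four lateral incisors for SATR work).
#' * **long** — header `subject_id,tooth_fdi,width_mm[,group]`, one row per
#'   tooth.
#'
#' Unknown tooth codes, non-numeric or non-positive widths, and duplicate
#' (subject, tooth) entries are hard errors naming the offending values —
#' nothing is silently dropped.
#'
#' @param path Path to a UTF-8, comma-delimited CSV file (decimal point).
#' @param layout `"auto"` (inspect the header), `"wide"` or `"long"`.
#' @return A cohort tibble in long form: `subject_id` (character), `fdi`
#'   (character), `width_mm` (double), plus `group` when present in the file.
#' @seealso [write_widths()], [as_cohort()], [validate_widths()]
#' @examples
#' # a small synthetic cohort ships with the package
#' path <- system.file("extdata", "synthetic_cohort_wide.csv",
#'                     package = "toothratio")
#' cohort <- read_widths(path)
#' tooth_ratios(cohort)
#' @export
read_widths <- function(path, layout = c("auto", "wide", "long")) {
  layout <- match.arg(layout)
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort(sprintf("Cannot read '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(raw) == 0) abort(sprintf("Empty cohort file: '%s'.", path))
  if (layout == "auto") {
    layout <- if ("tooth_fdi" %in% names(raw)) "long" else "wide"
  }
  as_cohort(raw, layout = layout)
}

#' Coerce a data frame of tooth widths to the canonical cohort form
#'
#' Accepts in-memory data in the wide or long layout of [read_widths()] and
#' returns the canonical long cohort tibble, applying the same validation
#' (anterior FDI codes only, numeric positive widths, no duplicate
#' (subject, tooth) pairs, unique handling of an optional `group` column).
#'
#' @param data A data frame in wide or long layout.
#' @param layout `"auto"`, `"wide"` or `"long"`.
#' @return A cohort tibble: `subject_id`, `fdi`, `width_mm`[, `group`].
#' @export
as_cohort <- function(data, layout = c("auto", "wide", "long")) {
  layout <- match.arg(layout)
  data <- as_tibble(data)
  if (!"subject_id" %in% names(data)) {
    abort("Cohort data must have a 'subject_id' column.")
  }
  if (layout == "auto") {
    layout <- if (any(c("tooth_fdi", "fdi") %in% names(data))) "long" else "wide"
  }

  if (layout == "long" && "fdi" %in% names(data) && !"tooth_fdi" %in% names(data)) {
    data <- rename(data, tooth_fdi = "fdi")
  }
  if (layout == "wide") {
    tooth_cols <- setdiff(names(data), c("subject_id", "group"))
    assert_anterior(tooth_cols, context = "wide-layout tooth column")
    if (length(tooth_cols) == 0) abort("Wide cohort has no tooth columns.")
    long <- data |>
      tidyr::pivot_longer(all_of(tooth_cols), names_to = "fdi",
                          values_to = "width_mm") |>
      filter(!is.na(.data$width_mm) & .data$width_mm != "")
  } else {
    needed <- c("subject_id", "tooth_fdi", "width_mm")
    missing_cols <- setdiff(needed, names(data))
    if (length(missing_cols) > 0) {
      abort(sprintf("Long cohort is missing column(s): %s.",
                    paste(missing_cols, collapse = ", ")))
    }
    long <- data |> rename(fdi = "tooth_fdi")
  }

  long <- long |> mutate(subject_id = as.character(.data$subject_id),
                         fdi = as.character(.data$fdi))
  assert_anterior(long$fdi)

  width_num <- suppressWarnings(as.numeric(long$width_mm))
  bad <- is.na(width_num) | width_num <= 0
  if (any(bad)) {
    ex <- long[bad, , drop = FALSE]
    abort(sprintf(
      "Non-numeric or non-positive width(s) for: %s.",
      paste(sprintf("subject %s tooth %s ('%s')",
                    head(ex$subject_id, 5), head(ex$fdi, 5),
                    head(as.character(ex$width_mm), 5)), collapse = "; ")
    ))
  }
  long$width_mm <- width_num

  dup <- long |> count(.data$subject_id, .data$fdi) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate (subject, tooth) entries: %s.",
      paste(sprintf("subject %s tooth %s", dup$subject_id, dup$fdi),
            collapse = "; ")
    ))
  }

  keep <- c("subject_id", "fdi", "width_mm",
            if ("group" %in% names(long)) "group")
  if ("group" %in% keep) {
    g <- long |> distinct(.data$subject_id, .data$group)
    if (anyDuplicated(g$subject_id) > 0) {
      abort("A subject carries more than one group label.")
    }
  }
  out <- long |> select(all_of(keep)) |> arrange(.data$subject_id, .data$fdi)
  class(out) <- c("tooth_cohort", class(out))
  out
}

#' Write a cohort of tooth widths to CSV
#'
#' Inverse of [read_widths()]: numeric content round-trips at full stored
#' precision in both layouts.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_widths <- function(cohort, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  cohort <- check_cohort(cohort)
  out <- if (layout == "wide") {
    cohort |>
      tidyr::pivot_wider(names_from = "fdi", values_from = "width_mm") |>
      relocate("subject_id")
  } else {
    cohort |> rename(tooth_fdi = "fdi")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a cohort against a ratio's completeness and plausibility rules
#'
#' A record is *Bolton-complete* when all 12 anterior codes are present and
#' *SATR-complete* when the four lateral incisors (12, 22, 32, 42) are
#' present. Widths outside the plausibility window (default 3–15 mm, wide
#' enough for real anterior crowns but catching cm-vs-mm unit errors) are
#' flagged.
#'
#' @param cohort A cohort tibble.
#' @param requirement `"bolton"` or `"satr"`.
#' @param window Length-2 numeric plausibility window in mm.
#' @return A tibble of issues (`subject_id`, `fdi`, `issue`, `width_mm`);
#'   zero rows if and only if every subject satisfies the requirement.
#' @export
validate_widths <- function(cohort, requirement = c("bolton", "satr"),
                            window = c(3, 15)) {
  requirement <- match.arg(requirement)
  cohort <- check_cohort(cohort)
  need <- if (requirement == "bolton") bolton_teeth() else satr_teeth()

  missing_rep <- cohort |>
    distinct(.data$subject_id) |>
    tidyr::expand_grid(fdi = need) |>
    anti_join(cohort, by = c("subject_id", "fdi")) |>
    mutate(issue = "missing", width_mm = NA_real_)

  window_rep <- as_tibble(strip_cohort(cohort)) |>
    filter(.data$width_mm < window[1] | .data$width_mm > window[2]) |>
    mutate(issue = if_else(.data$width_mm < window[1],
                           "below_window", "above_window")) |>
    select("subject_id", "fdi", "issue", "width_mm")

  bind_rows(missing_rep, window_rep) |>
    arrange(.data$subject_id, .data$fdi)
}

#' Which subjects are complete for a given ratio?
#'
#' @inheritParams validate_widths
#' @return A tibble `subject_id`, `complete` (logical).
#' @export
is_ratio_complete <- function(cohort, requirement = c("bolton", "satr")) {
  requirement <- match.arg(requirement)
  cohort <- check_cohort(cohort)
  need <- if (requirement == "bolton") bolton_teeth() else satr_teeth()
  cohort |>
    filter(.data$fdi %in% need) |>
    summarise(complete = n_distinct(.data$fdi) == length(need),
              .by = "subject_id")
}

strip_cohort <- function(x) {
  class(x) <- setdiff(class(x), "tooth_cohort")
  x
}

# internal: accept data already in canonical long form without re-pivoting;
# anything else is routed through as_cohort()
check_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort("A cohort must be a data frame.")
  if (inherits(cohort, "tooth_cohort") &&
      all(c("subject_id", "fdi", "width_mm") %in% names(cohort))) {
    return(cohort)
  }
  if (!all(c("subject_id", "fdi", "width_mm") %in% names(cohort))) {
    return(as_cohort(cohort))
  }
  as_cohort(cohort, layout = "long")
}

#' Bilateral mean crown widths
#'
#' Averages the left and right widths of each (arch, tooth type) within each
#' subject — the per-tooth-type summary used when stratifying cohorts by
#' Bolton ratio. Both sides must be present; a missing side is an error
#' naming the absent FDI code.
#'
#' @param cohort A cohort tibble.
#' @return A tibble `subject_id`, `arch`, `tooth_type`, `width_mm` (the
#'   bilateral mean), one row per subject and tooth type present.
#' @export
bilateral_means <- function(cohort) {
  cohort <- check_cohort(cohort)
  joined <- cohort |> inner_join(anterior_teeth(), by = "fdi")
  # any tooth type represented by only one side is an error naming the twin
  singles <- joined |>
    add_count(.data$subject_id, .data$arch, .data$tooth_type, name = "n_sides") |>
    filter(.data$n_sides == 1)
  if (nrow(singles) > 0) {
    ref <- anterior_teeth()
    twin <- purrr::pmap_chr(
      singles[c("arch", "tooth_type", "side")],
      function(arch, tooth_type, side) {
        ref$fdi[ref$arch == arch & ref$tooth_type == tooth_type &
                  ref$side != side]
      }
    )
    abort(sprintf(
      "Cannot take bilateral means; missing contralateral tooth: %s.",
      paste(sprintf("subject %s code %s", singles$subject_id, twin),
            collapse = "; ")
    ))
  }
  joined |>
    summarise(width_mm = mean(.data$width_mm),
              .by = c("subject_id", "arch", "tooth_type"))
}

#' Per-group, per-tooth-type cohort summary
#'
#' Mean and sample SD (n − 1 denominator) of the bilateral mean widths for
#' each group × (arch, tooth type) cell. With no `group` column the whole
#' cohort is summarised as one group.
#'
#' @param cohort A cohort tibble, optionally with a `group` column.
#' @return A tibble `group`, `arch`, `tooth_type`, `n`, `mean_mm`, `sd_mm`.
#'   `sd_mm` is `NA` for cells with a single subject (SD undefined).
#' @export
cohort_summary <- function(cohort) {
  cohort <- check_cohort(cohort)
  groups <- if ("group" %in% names(cohort)) {
    if (anyNA(cohort$group)) abort("Every subject must carry a group label.")
    cohort |> distinct(.data$subject_id, .data$group)
  } else {
    cohort |> distinct(.data$subject_id) |> mutate(group = "all")
  }
  bilateral_means(select(cohort, -any_of("group"))) |>
    inner_join(groups, by = "subject_id") |>
    summarise(
      n = n(),
      mean_mm = mean(.data$width_mm),
      sd_mm = if (n() >= 2) sd(.data$width_mm) else NA_real_,
      .by = c("group", "arch", "tooth_type")
    ) |>
    arrange(.data$group, desc(.data$arch), .data$tooth_type)
}
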