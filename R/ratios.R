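#' Generic lower/upper tooth-width ratio
#'
#' Computes `100 * sum(lower widths) / sum(upper widths)` per subject for
#' arbitrary arch-consistent tooth sets. [anterior_bolton_ratio()] and
#' [satr()] are this operation with fixed tooth sets.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param lower_teeth FDI codes of the mandibular teeth to sum.
#' @param upper_teeth FDI codes of the maxillary teeth to sum.
#' @param kind Label stored in the result (`"ABR"`, `"SATR"` or a custom tag).
#' @return A tibble with one row per subject: `subject_id`, `kind`,
#'   `value_pct`, `lower_sum_mm`, `upper_sum_mm`.
#' @export
generic_ratio <- function(cohort, lower_teeth, upper_teeth, kind = "custom") {
  cohort <- check_cohort(cohort)
  lower_teeth <- assert_anterior(lower_teeth)
  upper_teeth <- assert_anterior(upper_teeth)
  if (length(lower_teeth) == 0 || length(upper_teeth) == 0) {
    abort("Both tooth sets must be non-empty.")
  }
  ref <- anterior_teeth()
  arch_of <- setNames(ref$arch, ref$fdi)
  if (any(arch_of[lower_teeth] != "lower")) {
    abort(sprintf("lower_teeth contains maxillary code(s): %s.",
                  paste(lower_teeth[arch_of[lower_teeth] != "lower"],
                        collapse = ", ")))
  }
  if (any(arch_of[upper_teeth] != "upper")) {
    abort(sprintf("upper_teeth contains mandibular code(s): %s.",
                  paste(upper_teeth[arch_of[upper_teeth] != "upper"],
                        collapse = ", ")))
  }

  need <- c(lower_teeth, upper_teeth)
  found <- cohort |> filter(.data$fdi %in% need)
  cnt <- table(found$subject_id)
  all_sub <- unique(cohort$subject_id)
  incomplete <- union(setdiff(all_sub, names(cnt)),
                      names(cnt)[cnt < length(need)])
  if (length(incomplete) > 0) {
    # slow path only on error: name each missing code per subject
    miss <- tibble(subject_id = incomplete) |>
      tidyr::expand_grid(fdi = need) |>
      anti_join(found, by = c("subject_id", "fdi"))
    msg <- miss |>
      summarise(codes = paste(sort(.data$fdi), collapse = ","),
                .by = "subject_id")
    abort(sprintf(
      "Incomplete record(s) for %s ratio: %s.",
      kind,
      paste(sprintf("subject %s missing %s", msg$subject_id, msg$codes),
            collapse = "; ")
    ))
  }

  found |>
    inner_join(anterior_teeth(), by = "fdi") |>
    summarise(
      lower_sum_mm = sum(.data$width_mm[.data$arch == "lower"]),
      upper_sum_mm = sum(.data$width_mm[.data$arch == "upper"]),
      .by = "subject_id"
    ) |>
    mutate(kind = kind,
           value_pct = 100 * .data$lower_sum_mm / .data$upper_sum_mm) |>
    select("subject_id", "kind", "value_pct", "lower_sum_mm", "upper_sum_mm")
}

#' Anterior Bolton ratio
#'
#' Bolton's anterior index: the summed mesiodistal widths of the six
#' mandibular anterior teeth over the six maxillary anterior teeth, times
#' 100. Requires Bolton-complete records (all 12 anterior codes).
#'
#' @inheritParams generic_ratio
#' @return A tibble as in [generic_ratio()] with `kind = "ABR"`.
#' @examples
#' cohort <- simulate_cohort(3, seed = 1)$cohort
#' anterior_bolton_ratio(cohort)
#' @export
anterior_bolton_ratio <- function(cohort) {
  ref <- anterior_teeth()
  generic_ratio(cohort,
                lower_teeth = ref$fdi[ref$arch == "lower"],
                upper_teeth = ref$fdi[ref$arch == "upper"],
                kind = "ABR")
}

#' Simplified anterior tooth ratio (SATR)
#'
#' The lateral-incisor screening ratio: summed widths of the two mandibular
#' lateral incisors (32, 42) over the two maxillary lateral incisors
#' (12, 22), times 100. Requires SATR-complete records.
#'
#' @inheritParams generic_ratio
#' @return A tibble as in [generic_ratio()] with `kind = "SATR"`.
#' @examples
#' cohort <- simulate_cohort(3, seed = 1)$cohort
#' satr(cohort)
#' @export
satr <- function(cohort) {
  generic_ratio(cohort, lower_teeth = c("32", "42"),
                upper_teeth = c("12", "22"), kind = "SATR")
}

#' Per-subject ABR and SATR side by side
#'
#' Convenience wrapper returning both ratios in wide form, the shape used by
#' the association and diagnostic stages.
#'
#' @inheritParams generic_ratio
#' @return A tibble `subject_id`, `abr_pct`, `satr_pct` (plus `group` when
#'   the cohort carries one).
#' @export
tooth_ratios <- function(cohort) {
  cohort <- check_cohort(cohort)
  out <- anterior_bolton_ratio(cohort) |>
    select("subject_id", abr_pct = "value_pct") |>
    inner_join(satr(cohort) |>
                 select("subject_id", satr_pct = "value_pct"),
               by = "subject_id")
  if ("group" %in% names(cohort)) {
    out <- out |>
      inner_join(distinct(cohort, .data$subject_id, .data$group),
                 by = "subject_id")
  }
  out
}
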