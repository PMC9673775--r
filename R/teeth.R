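#' Reference table of the twelve permanent anterior teeth
#'
#' Returns the FDI two-digit codes of the permanent anterior teeth together
#' with the arch, tooth type and side each code encodes. FDI notation packs
#' quadrant (first digit: 1 upper right, 2 upper left, 3 lower left,
#' 4 lower right) and position from the midline (second digit: 1 central
#' incisor, 2 lateral incisor, 3 canine) into one code, so the code alone
#' determines arch, tooth type and side.
#'
#' @return A tibble with 12 rows and columns `fdi` (character code),
#'   `arch` (`"upper"`/`"lower"`), `tooth_type`
#'   (`"central"`/`"lateral"`/`"canine"`) and `side` (`"left"`/`"right"`).
#' @examples
#' anterior_teeth()
#' @export
anterior_teeth <- function() {
  quadrant <- c(`1` = "upper_right", `2` = "upper_left",
                `3` = "lower_left", `4` = "lower_right")
  tidyr::expand_grid(q = names(quadrant), pos = c("1", "2", "3")) |>
    mutate(
      fdi = paste0(.data$q, .data$pos),
      arch = ifelse(.data$q %in% c("1", "2"), "upper", "lower"),
      tooth_type = c("central", "lateral", "canine")[as.integer(.data$pos)],
      side = ifelse(.data$q %in% c("1", "4"), "right", "left")
    ) |>
    select("fdi", "arch", "tooth_type", "side")
}

#' Resolve FDI codes to tooth descriptions
#'
#' @param fdi Character or numeric vector of two-digit FDI codes.
#' @return A tibble with one row per input code, columns as in
#'   [anterior_teeth()], in input order.
#' @examples
#' tooth_ref(c(12, 32))
#' @export
tooth_ref <- function(fdi) {
  fdi <- as.character(fdi)
  assert_anterior(fdi)
  ref <- anterior_teeth()
  ref[match(fdi, ref$fdi), ]
}

# hard error listing every non-anterior code encountered
assert_anterior <- function(fdi, context = "tooth code") {
  bad <- setdiff(unique(as.character(fdi)), anterior_teeth()$fdi)
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid %s(s): %s. Valid codes are the 12 permanent anterior FDI codes: %s.",
      context, paste(bad, collapse = ", "),
      paste(anterior_teeth()$fdi, collapse = ", ")
    ))
  }
  invisible(as.character(fdi))
}

# tooth sets used by the two named ratios
bolton_teeth <- function() anterior_teeth()$fdi
satr_teeth <- function() c("12", "22", "32", "42")
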