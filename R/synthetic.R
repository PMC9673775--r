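#' Parameters of the synthetic tooth-width generator
#'
#' Per-tooth-type crown-width means and SDs (mm) default to the normal-ABR
#' derivation group: upper central 8.650 ± 0.490, upper lateral
#' 7.216 ± 0.511, upper canine 8.007 ± 0.522, lower central 5.654 ± 0.418,
#' lower lateral 6.172 ± 0.350, lower canine 6.961 ± 0.531.
#'
#' Each tooth type's variance is decomposed into three independent parts so
#' that the simulated per-tooth SD equals the input SD exactly:
#'
#' * a *shared size factor* per subject (real tooth sizes covary within a
#'   mouth) carrying `size_factor_sd_share` of the variance;
#' * a per-(subject, arch, tooth type) effect shared by the two sides,
#'   carrying the remainder after the asymmetry part;
#' * independent left-right noise with SD `asymmetry_sd_mm`.
#'
#' Scenario shifts model lateral-incisor size anomalies, the mechanism
#' behind anterior-ratio deviation. Scenario names describe the *upper*
#' lateral incisors: `lateral_deficient` (undersized upper laterals, the
#' common clinical anomaly) subtracts `lateral_shift_mm` from the upper
#' laterals and adds `lower_shift_frac * lateral_shift_mm` to the lower
#' laterals, raising SATR and ABR together; `lateral_excess` mirrors it,
#' lowering both.
#'
#' @param means,sds Named numeric vectors over
#'   `c("upper_central","upper_lateral","upper_canine","lower_central",
#'   "lower_lateral","lower_canine")`.
#' @param size_factor_sd_share Fraction of each tooth type's variance
#'   attributed to the shared per-subject size factor, in \[0, 1\].
#' @param asymmetry_sd_mm SD of independent left-right noise (mm). Must
#'   satisfy `asymmetry_sd_mm^2 <= (1 - size_factor_sd_share) * sd^2` for
#'   every tooth type.
#' @param lateral_shift_mm Deterministic lateral-incisor shift per scenario
#'   (mm). The 0.4 mm default plants three-group mean ABRs of roughly
#'   76.4 / 78.7 / 81.1%, beyond the 77.08/80.52 stratification bounds.
#' @param lower_shift_frac Fraction of the shift applied (with opposite
#'   sign) to the lower laterals; 0.6 mirrors the observed ratio of upper
#'   to lower lateral group differences.
#' @param width_window Plausibility window; generated widths are clipped to
#'   it (clips are counted in the result).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(means = c(upper_central = 8.650,
                                    upper_lateral = 7.216,
                                    upper_canine = 8.007,
                                    lower_central = 5.654,
                                    lower_lateral = 6.172,
                                    lower_canine = 6.961),
                          sds = c(upper_central = 0.490,
                                  upper_lateral = 0.511,
                                  upper_canine = 0.522,
                                  lower_central = 0.418,
                                  lower_lateral = 0.350,
                                  lower_canine = 0.531),
                          size_factor_sd_share = 0.5,
                          asymmetry_sd_mm = 0.15,
                          lateral_shift_mm = 0.4,
                          lower_shift_frac = 0.6,
                          width_window = c(3, 15)) {
  types <- c("upper_central", "upper_lateral", "upper_canine",
             "lower_central", "lower_lateral", "lower_canine")
  if (!all(types %in% names(means)) || !all(types %in% names(sds))) {
    abort("`means` and `sds` must be named over the six arch_type combinations.")
  }
  if (any(means[types] <= 0)) abort("Mean widths must be positive.")
  if (any(sds[types] < 0) || size_factor_sd_share < 0 ||
      size_factor_sd_share > 1 || asymmetry_sd_mm < 0) {
    abort("SDs must be >= 0 and size_factor_sd_share in [0, 1].")
  }
  resid_var <- (1 - size_factor_sd_share) * sds[types]^2 - asymmetry_sd_mm^2
  if (any(resid_var < -1e-12)) {
    abort(paste(
      "asymmetry_sd_mm^2 exceeds the non-shared variance for:",
      paste(types[resid_var < -1e-12], collapse = ", ")
    ))
  }
  structure(
    list(means = means[types], sds = sds[types],
         size_factor_sd_share = size_factor_sd_share,
         asymmetry_sd_mm = asymmetry_sd_mm,
         lateral_shift_mm = lateral_shift_mm,
         lower_shift_frac = lower_shift_frac,
         width_window = width_window),
    class = "cohort_params"
  )
}

scenario_levels <- c("balanced", "lateral_deficient", "lateral_excess")

# per-scenario additive shift (mm) for (arch, tooth_type); fully vectorized
scenario_shift <- function(scenario, arch, tooth_type, params) {
  n <- max(length(scenario), length(arch), length(tooth_type))
  scenario <- rep_len(scenario, n)
  arch <- rep_len(arch, n)
  tooth_type <- rep_len(tooth_type, n)
  sgn <- (scenario == "lateral_deficient") - (scenario == "lateral_excess")
  out <- ifelse(arch == "upper",
                -sgn * params$lateral_shift_mm,
                sgn * params$lower_shift_frac * params$lateral_shift_mm)
  out[tooth_type != "lateral"] <- 0
  out
}

#' Simulate a cohort of anterior tooth widths
#'
#' Draws `n` subjects from the generative model described in
#' [cohort_params()]. Fully reproducible from `seed`; the same seed yields
#' a bit-identical cohort.
#'
#' @param n Number of subjects.
#' @param scenario `"balanced"`, `"lateral_deficient"`, `"lateral_excess"`,
#'   or `"mixed"` (each subject's scenario drawn with `mixed_weights`).
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param mixed_weights Named probabilities for the `"mixed"` scenario.
#' @param id_prefix Prefix for generated subject ids.
#' @return A list of class `satr_sim`:
#'   * `cohort` — long cohort tibble (`subject_id`, `fdi`, `width_mm`);
#'   * `truth` — per-subject ground truth (`subject_id`, `scenario`,
#'     `upper_lateral_shift_mm`, `lower_lateral_shift_mm`, `true_abr_pct`,
#'     `true_satr_pct`), with the true ratios computed from the generated
#'     widths themselves;
#'   * `n_clipped` — number of widths clipped to the plausibility window.
#' @examples
#' sim <- simulate_cohort(5, scenario = "mixed", seed = 42)
#' sim$truth
#' @export
simulate_cohort <- function(n,
                            scenario = c("balanced", "lateral_deficient",
                                         "lateral_excess", "mixed"),
                            params = cohort_params(),
                            seed = NULL,
                            mixed_weights = c(balanced = 0.5,
                                              lateral_deficient = 0.25,
                                              lateral_excess = 0.25),
                            id_prefix = "S") {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "cohort_params"))
  if (n < 1) abort("`n` must be at least 1.")
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_cohort(
      n, scenario, params, seed = NULL, mixed_weights = mixed_weights,
      id_prefix = id_prefix
    )))
  }

  scen <- if (scenario == "mixed") {
    sample(names(mixed_weights), n, replace = TRUE, prob = mixed_weights)
  } else {
    rep(scenario, n)
  }
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))

  share <- params$size_factor_sd_share
  teeth <- anterior_teeth()
  type_key <- paste(teeth$arch, teeth$tooth_type, sep = "_")
  mu <- params$means[type_key]
  lambda <- params$sds[type_key] * sqrt(share)
  tau6 <- sqrt(pmax(0, (1 - share) * params$sds^2 - params$asymmetry_sd_mm^2))
  tooth_of_type <- match(type_key, names(params$means))

  z <- rnorm(n)
  u6 <- matrix(rnorm(n * 6), n, 6) * rep(tau6, each = n)  # subject x type
  eps <- matrix(rnorm(n * 12, sd = params$asymmetry_sd_mm), n, 12)
  shift <- outer(scen, seq_len(12), function(sc, j) {
    scenario_shift(sc, teeth$arch[j], teeth$tooth_type[j], params)
  })

  w_raw <- matrix(mu, n, 12, byrow = TRUE) +
    outer(z, lambda) + u6[, tooth_of_type] + shift + eps
  w <- pmin(pmax(w_raw, params$width_window[1]), params$width_window[2])
  n_clipped <- sum(w != w_raw)
  if (n_clipped > 0) {
    warn(sprintf("%d generated width(s) clipped to the plausibility window.",
                 n_clipped))
  }

  cohort <- tibble(
    subject_id = rep(ids, each = 12),
    fdi = rep(teeth$fdi, n),
    width_mm = as.vector(t(w))
  ) |>
    arrange(.data$subject_id, .data$fdi)
  class(cohort) <- c("tooth_cohort", class(cohort))

  truth <- tibble(subject_id = ids, scenario = scen) |>
    mutate(
      upper_lateral_shift_mm = scenario_shift(.data$scenario, "upper",
                                              "lateral", params),
      lower_lateral_shift_mm = scenario_shift(.data$scenario, "lower",
                                              "lateral", params)
    ) |>
    inner_join(tooth_ratios(cohort) |>
                 rename(true_abr_pct = "abr_pct", true_satr_pct = "satr_pct"),
               by = "subject_id")

  structure(list(cohort = cohort, truth = truth, n_clipped = n_clipped),
            class = "satr_sim")
}

#' @export
print.satr_sim <- function(x, ...) {
  cat(sprintf("Synthetic anterior-width cohort: %d subjects (%d clipped widths)\n",
              nrow(x$truth), x$n_clipped))
  print(count(x$truth, .data$scenario))
  invisible(x)
}

#' Simulate a three-group derivation study
#'
#' Builds a labelled cohort mirroring the derivation design: a normal group
#' (balanced scenario), a low-ABR group (oversized upper laterals,
#' `lateral_excess`) and a high-ABR group (undersized upper laterals,
#' `lateral_deficient`). Warns — rather than errors — when the planted
#' shifts are too small for the expected group mean ABRs to clear the
#' stratification bounds.
#'
#' @param n_per_group Sizes of the low, normal and high groups (each >= 2),
#'   in that order.
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @param bounds The [bolton_bounds()] the groups should straddle.
#' @return A list of class `satr_sim` whose `cohort` carries a `group`
#'   column (`low`/`normal`/`high`) and whose `truth` records the planted
#'   shifts per subject.
#' @export
simulate_three_group_study <- function(n_per_group = c(low = 80, normal = 80,
                                                       high = 80),
                                       params = cohort_params(),
                                       seed = NULL,
                                       bounds = bolton_bounds()) {
  if (length(n_per_group) != 3 || any(n_per_group < 2)) {
    abort("`n_per_group` must give three group sizes of at least 2.")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_three_group_study(
      n_per_group, params, seed = NULL, bounds = bounds
    )))
  }

  spec <- tibble(
    group = c("low", "normal", "high"),
    scenario = c("lateral_excess", "balanced", "lateral_deficient"),
    n = as.integer(n_per_group)
  )

  # analytic mean ABR per group from the planted shifts
  expected_abr <- function(scn) {
    up <- 2 * sum(params$means[c("upper_central", "upper_lateral",
                                 "upper_canine")]) +
      2 * scenario_shift(scn, "upper", "lateral", params)
    lo <- 2 * sum(params$means[c("lower_central", "lower_lateral",
                                 "lower_canine")]) +
      2 * scenario_shift(scn, "lower", "lateral", params)
    100 * lo / up
  }
  if (expected_abr("lateral_excess") >= bounds$low ||
      expected_abr("lateral_deficient") <= bounds$high) {
    warn("Planted lateral shifts are too small to separate the group mean ABRs beyond the bounds.")
  }

  sims <- purrr::pmap(spec, function(group, scenario, n) {
    sim <- simulate_cohort(n, scenario = scenario, params = params,
                           id_prefix = paste0(group, "-"))
    sim$cohort$group <- group
    sim$truth$group <- group
    sim
  })

  structure(
    list(cohort = purrr::list_rbind(purrr::map(sims, "cohort")),
         truth = purrr::list_rbind(purrr::map(sims, "truth")),
         n_clipped = sum(purrr::map_int(sims, "n_clipped"))),
    class = "satr_sim"
  )
}
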