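test_that("the generator is deterministic given a seed", {
  a <- simulate_cohort(25, scenario = "mixed", seed = 5)
  b <- simulate_cohort(25, scenario = "mixed", seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(25, scenario = "mixed", seed = 6)
  expect_false(identical(a$cohort$width_mm, c_$cohort$width_mm))
})

test_that("a large balanced cohort recovers the generator's moments", {
  sim <- simulate_cohort(2000, seed = 99)
  p <- cohort_params()

  cs <- cohort_summary(sim$cohort)
  key <- paste(cs$arch, cs$tooth_type, sep = "_")
  expect_true(all(abs(cs$mean_mm - p$means[key]) < 0.05))

  per_tooth <- sim$cohort |>
    dplyr::inner_join(anterior_teeth(), by = "fdi") |>
    dplyr::summarise(m = mean(width_mm), s = sd(width_mm),
                     .by = c(arch, tooth_type))
  key2 <- paste(per_tooth$arch, per_tooth$tooth_type, sep = "_")
  expect_true(all(abs(per_tooth$m - p$means[key2]) < 0.05))
  expect_true(all(abs(per_tooth$s - p$sds[key2]) < 0.05))
})

test_that("the noise-free degenerate cohort equals the mean-width ratios", {
  p0 <- cohort_params(
    sds = setNames(rep(0, 6), names(cohort_params()$sds)),
    asymmetry_sd_mm = 0, size_factor_sd_share = 1
  )
  sim <- simulate_cohort(3, params = p0, seed = 1)
  rr <- tooth_ratios(sim$cohort)
  expect_equal(rr$abr_pct, rep(100 * 37.574 / 47.746, 3), tolerance = 1e-12)
  expect_equal(rr$satr_pct, rep(100 * 6.172 / 7.216, 3), tolerance = 1e-12)
})

test_that("stored ground-truth ratios equal the ratio-module outputs", {
  sim <- simulate_cohort(40, scenario = "mixed", seed = 8)
  rr <- tooth_ratios(sim$cohort)
  expect_equal(sim$truth$true_abr_pct, rr$abr_pct, tolerance = 1e-12)
  expect_equal(sim$truth$true_satr_pct, rr$satr_pct, tolerance = 1e-12)
})

test_that("scenario shifts move SATR and ABR together, as planted", {
  lo <- simulate_cohort(200, scenario = "lateral_excess", seed = 21)$truth
  hi <- simulate_cohort(200, scenario = "lateral_deficient", seed = 22)$truth
  mid <- simulate_cohort(200, scenario = "balanced", seed = 23)$truth
  expect_lt(mean(lo$true_abr_pct), mean(mid$true_abr_pct))
  expect_gt(mean(hi$true_abr_pct), mean(mid$true_abr_pct))
  expect_lt(mean(lo$true_satr_pct), mean(mid$true_satr_pct))
  expect_gt(mean(hi$true_satr_pct), mean(mid$true_satr_pct))
})

test_that("three-group studies straddle the stratification bounds", {
  tg <- simulate_three_group_study(c(60, 60, 60), seed = 13)
  means <- tg$truth |>
    dplyr::summarise(abr = mean(true_abr_pct), .by = group)
  abr <- setNames(means$abr, means$group)
  expect_lt(abr["low"], 77.08)
  expect_gt(abr["high"], 80.52)
  expect_true(abr["low"] < abr["normal"] && abr["normal"] < abr["high"])

  expect_warning(
    simulate_three_group_study(
      c(3, 3, 3), seed = 1,
      params = cohort_params(lateral_shift_mm = 0.01)),
    "too small"
  )
  expect_error(simulate_three_group_study(c(1, 5, 5)), "at least 2")
})

test_that("key-tooth selection power grows with the planted lateral shift", {
  rate_for <- function(shift, reps = 12) {
    hits <- 0
    for (i in seq_len(reps)) {
      params <- cohort_params(lateral_shift_mm = shift)
      tg <- simulate_three_group_study(c(40, 40, 40), params = params,
                                       seed = 7000 + i)
      sel <- tryCatch(select_key_teeth(pairwise_tooth_tests(tg$cohort)),
                      error = function(e) NULL)
      if (!is.null(sel) &&
          identical(sel$tooth_type, c("lateral", "lateral"))) {
        hits <- hits + 1
      }
    }
    hits / reps
  }
  expect_lte(suppressWarnings(rate_for(0.05)), rate_for(0.4))
})

test_that("implausible parameter combinations are rejected or clipped", {
  expect_error(
    cohort_params(means = setNames(rep(-1, 6), names(cohort_params()$means))),
    "positive")
  expect_error(cohort_params(size_factor_sd_share = 1.5), "\\[0, 1\\]")
  expect_error(cohort_params(asymmetry_sd_mm = 0.6), "exceeds")

  # a mean near the window edge forces clipping, which warns and counts
  squeeze <- cohort_params(
    means = c(upper_central = 8.650, upper_lateral = 7.216,
              upper_canine = 8.007, lower_central = 5.654,
              lower_lateral = 3.1, lower_canine = 6.961),
    sds = setNames(rep(0, 6), names(cohort_params()$sds)),
    asymmetry_sd_mm = 0, size_factor_sd_share = 1
  )
  expect_warning(
    sim <- simulate_cohort(4, scenario = "lateral_excess", params = squeeze,
                           seed = 2),
    "clipped"
  )
  expect_equal(sim$n_clipped, 8)  # both lower laterals of all 4 subjects
  expect_true(all(sim$cohort$width_mm >= 3))
})
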