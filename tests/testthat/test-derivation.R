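test_that("Bolton-group assignment partitions with boundaries in normal", {
  expect_equal(as.character(assign_bolton_group(76.00)), "low")
  expect_equal(as.character(assign_bolton_group(78.80)), "normal")
  expect_equal(as.character(assign_bolton_group(81.00)), "high")
  expect_equal(as.character(assign_bolton_group(77.08)), "normal")
  expect_equal(as.character(assign_bolton_group(80.52)), "normal")

  vals <- withr::with_seed(7, sort(stats::runif(200, 60, 100)))
  g <- assign_bolton_group(vals)
  expect_false(anyNA(g))          # every value gets exactly one label
  expect_false(is.unsorted(g))    # labels are monotone in the ratio
})

test_that("pooled t statistic matches the hand-computed case", {
  res <- width_t_test(c(1, 2, 3), c(2, 3, 4), variant = "pooled")
  expect_equal(res$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
})

test_that("degenerate samples follow the stated rules", {
  same <- width_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(width_t_test(c(2, 2), c(3, 3)), "undefined")
  expect_error(width_t_test(1, c(2, 3)), "at least 2")

  ident <- width_t_test(c(1, 2, 3), c(1, 2, 3), variant = "pooled")
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("t test agrees with the closed-form oracle and is antisymmetric", {
  for (i in 1:40) {
    withr::with_seed(100 + i, {
      a <- rnorm(sample(3:12, 1), mean = 7, sd = runif(1, 0.2, 1))
      b <- rnorm(sample(3:12, 1), mean = 7.2, sd = runif(1, 0.2, 1))
    })
    for (pooled in c(TRUE, FALSE)) {
      variant <- if (pooled) "pooled" else "welch"
      got <- width_t_test(a, b, variant = variant)
      want <- oracle_t(a, b, pooled = pooled)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$df, want$df, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
      swap <- width_t_test(b, a, variant = variant)
      expect_equal(swap$t, -got$t, tolerance = 1e-12)
      expect_equal(swap$p, got$p, tolerance = 1e-12)
    }
  }
})

test_that("auto variant is gated by Levene's test on mean-centred deviations", {
  withr::with_seed(1, {
    a <- rnorm(40, sd = 1)
    b_same <- rnorm(40, sd = 1)
    b_diff <- rnorm(40, sd = 6)
  })
  expect_equal(width_t_test(a, b_same)$variant, "pooled")
  expect_equal(width_t_test(a, b_diff)$variant, "welch")
})

test_that("pairwise tests label unlabeled cohorts and enforce group sizes", {
  tg <- simulate_three_group_study(c(20, 20, 20), seed = 61)
  tt <- pairwise_tooth_tests(tg$cohort)
  expect_equal(nrow(tt), 18)
  expect_equal(sort(unique(tt$comparison)),
               sort(c("normal_vs_low", "normal_vs_high", "low_vs_high")))

  # internal labelling from the ratio itself also yields 18 tests
  unlabeled <- dplyr::select(tg$cohort, -group)
  tt2 <- pairwise_tooth_tests(unlabeled)
  expect_equal(nrow(tt2), 18)

  tiny <- dplyr::mutate(tg$cohort,
    group = ifelse(subject_id == "low-0001", "low",
                   ifelse(grepl("^high", subject_id), "high", "normal")))
  expect_error(pairwise_tooth_tests(tiny), "low")
})

test_that("a cohort of identical subjects yields all-zero t statistics", {
  same <- dplyr::bind_rows(lapply(1:9, function(i) {
    mean_width_cohort(sprintf("S%02d", i))
  }))
  same$group <- rep(c("low", "normal", "high"), each = 12 * 3)
  tt <- pairwise_tooth_tests(same)
  expect_true(all(tt$t == 0))
  expect_true(all(tt$p == 1))
})

test_that("key-tooth selection reproduces the published significance pattern", {
  sel <- select_key_teeth(table1_p_pattern())
  expect_equal(sel$tooth_type[sel$arch == "upper"], "lateral")
  expect_equal(sel$tooth_type[sel$arch == "lower"], "lateral")
})

test_that("selection handles no qualifier and flags ambiguity", {
  none <- dplyr::mutate(table1_p_pattern(), p = 0.5)
  sel <- select_key_teeth(none)
  expect_true(all(is.na(sel$tooth_type)))

  ambiguous <- dplyr::mutate(table1_p_pattern(),
    p = ifelse(arch == "upper" & tooth_type %in% c("central", "lateral"),
               0.001, p))
  expect_error(select_key_teeth(ambiguous), "[Aa]mbiguous")

  expect_error(select_key_teeth(table1_p_pattern()[-1, ]), "18")
})
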