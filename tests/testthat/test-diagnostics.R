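test_that("cross_tabulate reconstructs the validation study's 3x3 table", {
  pairs <- label_pairs_from_counts(table4_counts)
  t3 <- cross_tabulate(pairs$pred, pairs$gold)
  expect_equal(unclass(unname(t3)),
               matrix(table4_counts, 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(t3)), c(34, 74, 34))
  expect_equal(unname(colSums(t3)), c(42, 76, 24))
  expect_equal(sum(t3), 142)
})

test_that("cross_tabulate validates its inputs", {
  expect_error(cross_tabulate(c("normal", "excess"), "normal"),
               "equal length")
  expect_error(cross_tabulate(character(0), character(0)), "at least one")
  expect_error(cross_tabulate("tiny", "normal"), "deficient, normal, excess")
  # perfectly matched subjects land on the diagonal
  t3 <- cross_tabulate(c("deficient", "normal", "excess"),
                       c("deficient", "normal", "excess"))
  expect_equal(unname(diag(t3)), c(1, 1, 1))
  expect_equal(sum(t3) - sum(diag(t3)), 0)
})

test_that("collapsing to two classes reproduces the published 2x2 table", {
  t3 <- cross_table(table4_counts)
  t2 <- collapse_to_binary(t3)
  expect_equal(unclass(unname(t2)), unname(table5_counts), ignore_attr = TRUE)
  expect_equal(sum(t2), sum(t3))  # grand total preserved

  diag3 <- cross_table(c(5, 0, 0, 0, 6, 0, 0, 0, 7))
  t2d <- collapse_to_binary(diag3)
  expect_equal(unname(t2d["normal", "abnormal"]), 0L)
  expect_equal(unname(t2d["abnormal", "normal"]), 0L)

  only_normal <- cross_table(c(0, 0, 0, 0, 9, 0, 0, 0, 0))
  t2n <- collapse_to_binary(only_normal)
  expect_equal(unname(rowSums(t2n)), c(9, 0))
  expect_equal(unname(colSums(t2n)), c(9, 0))
})

test_that("diagnostic metrics reproduce the published values", {
  t2 <- collapse_to_binary(cross_table(table4_counts))
  m <- diagnostic_metrics(t2)
  expect_equal(round(m$sensitivity_pct, 2), 77.63)
  expect_equal(round(m$specificity_pct, 2), 77.27)
  expect_equal(round(m$ppv_pct, 2), 79.73)
  expect_equal(round(m$npv_pct, 2), 75.00)

  # swapping the positive condition exchanges the metric roles
  sw <- diagnostic_metrics(t2, positive = "abnormal")
  expect_equal(sw$sensitivity_pct, m$specificity_pct)
  expect_equal(sw$specificity_pct, m$sensitivity_pct)
  expect_equal(sw$ppv_pct, m$npv_pct)
  expect_equal(sw$npv_pct, m$ppv_pct)
})

test_that("perfect agreement and empty denominators are handled", {
  perfect <- collapse_to_binary(cross_table(c(10, 0, 0, 0, 20, 0, 0, 0, 5)))
  m <- diagnostic_metrics(perfect)
  expect_equal(unlist(m[c("sensitivity_pct", "specificity_pct",
                          "ppv_pct", "npv_pct")], use.names = FALSE),
               rep(100, 4))

  all_normal <- collapse_to_binary(cross_table(c(0, 0, 0, 0, 9, 0, 0, 0, 0)))
  m2 <- diagnostic_metrics(all_normal)
  expect_true(is.na(m2$specificity_pct))  # no gold-abnormal subjects
  expect_true(is.na(m2$npv_pct))          # no test-abnormal subjects
  expect_equal(m2$sensitivity_pct, 100)
  expect_equal(m2$ppv_pct, 100)
})

test_that("the marginal chi-square reproduces the published consistency test", {
  res <- marginal_chi_square(cross_table(table4_counts))
  expect_equal(round(res$statistic, 2), 2.59)
  expect_equal(res$df, 2L)
  expect_equal(round(res$p, 2), 0.27)
})

test_that("marginal chi-square edge cases and oracle agreement", {
  sym <- cross_table(c(5, 2, 1, 2, 9, 2, 1, 2, 6))
  res <- marginal_chi_square(sym)  # equal margins by symmetry
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  expect_error(
    marginal_chi_square(cross_table(c(0, 0, 0, 0, 9, 1, 0, 3, 2))),
    "zero total"
  )

  for (i in 1:40) {
    counts <- withr::with_seed(400 + i, stats::rpois(9, 8) + 1)
    t3 <- cross_table(counts)
    got <- marginal_chi_square(t3)
    margins <- rbind(rowSums(t3), colSums(t3))
    expect_equal(got$statistic, oracle_chisq(margins), tolerance = 1e-10)
    expect_equal(got$p, stats::pchisq(oracle_chisq(margins), 2,
                                      lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("paired-agreement extras behave on reference tables", {
  perfect <- cross_table(c(10, 0, 0, 0, 20, 0, 0, 0, 5))
  pa <- paired_agreement(perfect)
  expect_equal(pa$value[pa$statistic_name == "cohen_kappa"], 1)

  pa4 <- paired_agreement(cross_table(table4_counts))
  kappa <- pa4$value[pa4$statistic_name == "cohen_kappa"]
  expect_gt(kappa, 0.5)  # substantial agreement in the validation table
  expect_lt(kappa, 1)
})

test_that("the end-to-end synthetic evaluation matches its ground truth", {
  sim <- simulate_cohort(150, scenario = "mixed", seed = 88)
  via_widths <- satr(sim$cohort)$value_pct
  pred <- classify_ratio(via_widths, satr_standard())
  pred_truth <- classify_ratio(sim$truth$true_satr_pct, satr_standard())
  gold <- classify_ratio(sim$truth$true_abr_pct, bolton_standard())
  # labels derived from regenerated widths equal labels from stored truth
  expect_equal(as.character(pred), as.character(pred_truth))
  t3 <- cross_tabulate(pred, gold)
  expect_equal(sum(t3), 150)
  m <- diagnostic_metrics(collapse_to_binary(t3))
  expect_true(all(!is.na(unlist(m[2:5]))))
})
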