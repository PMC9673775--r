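diag3 <- c("deficient", "normal", "excess")
diag2 <- c("normal", "abnormal")

#' Construct a 3x3 diagnosis cross-table from counts
#'
#' Rows are the screening-test (SATR) diagnosis, columns the gold-standard
#' (anterior Bolton) diagnosis, both ordered deficient/normal/excess.
#'
#' @param counts A 3x3 matrix or a length-9 vector in row-major order
#'   (deficient row first).
#' @return An integer matrix of class `cross_table` with diagnosis dimnames.
#' @examples
#' cross_table(c(29, 5, 0,
#'               13, 59, 2,
#'               0, 12, 22))
#' @export
cross_table <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 3, 3, byrow = TRUE)
  if (!all(dim(m) == c(3, 3))) abort("`counts` must form a 3x3 table.")
  if (any(m < 0) || any(m != round(m))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(m) == 0) abort("The table must have a positive grand total.")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(test = diag3, gold = diag3)
  structure(m, class = c("cross_table", "matrix", "array"))
}

#' Cross-tabulate paired diagnoses
#'
#' Counts subjects by (screening-test label, gold-standard label) from two
#' aligned label vectors.
#'
#' @param pred Screening-test labels (deficient/normal/excess).
#' @param gold Gold-standard labels, aligned with `pred` by subject.
#' @return A 3x3 [cross_table()].
#' @examples
#' cross_tabulate(c("normal", "excess"), c("normal", "normal"))
#' @export
cross_tabulate <- function(pred, gold) {
  if (is.data.frame(pred)) {
    abort("Pass two label vectors; extract columns from your data frame first.")
  }
  if (length(pred) != length(gold)) {
    abort("`pred` and `gold` must have equal length (aligned by subject).")
  }
  if (length(pred) == 0) abort("Need at least one paired diagnosis.")
  pred <- factor(as.character(pred), levels = diag3)
  gold <- factor(as.character(gold), levels = diag3)
  if (anyNA(pred) || anyNA(gold)) {
    abort("Labels must be one of: deficient, normal, excess.")
  }
  cross_table(unclass(table(test = pred, gold = gold)))
}

#' Collapse a 3-class cross-table to normal vs abnormal
#'
#' Deficient and excess pool into `abnormal` on both margins; the normal
#' row/column is preserved. The grand total is unchanged.
#'
#' @param t3 A 3x3 [cross_table()].
#' @return A 2x2 matrix of class `cross_table2`, rows/cols
#'   `normal`/`abnormal` (test rows, gold columns).
#' @export
collapse_to_binary <- function(t3) {
  stopifnot(inherits(t3, "cross_table"))
  ab_r <- c("deficient", "excess")
  m <- matrix(c(
    t3["normal", "normal"], sum(t3["normal", ab_r]),
    sum(t3[ab_r, "normal"]), sum(t3[ab_r, ab_r])
  ), 2, 2, byrow = TRUE,
  dimnames = list(test = diag2, gold = diag2))
  storage.mode(m) <- "integer"
  structure(m, class = c("cross_table2", "matrix", "array"))
}

#' Sensitivity, specificity and predictive values of the screening test
#'
#' Standard 2x2 diagnostic-test proportions. The positive condition
#' defaults to `"normal"`: in this screening setting the test's task is to
#' recognise a normal anterior ratio, so sensitivity is the fraction of
#' gold-normal subjects the test calls normal. With
#' `positive = "abnormal"` sensitivity/specificity (and PPV/NPV) swap roles.
#'
#' @param t2 A 2x2 table from [collapse_to_binary()], test rows, gold
#'   columns, order normal/abnormal.
#' @param positive `"normal"` (default) or `"abnormal"`.
#' @return A one-row tibble: `positive`, `sensitivity_pct`,
#'   `specificity_pct`, `ppv_pct`, `npv_pct`, `n`. A metric whose
#'   denominator is zero is `NA` (flagged undefined); the others are still
#'   computed.
#' @examples
#' t2 <- collapse_to_binary(cross_table(c(29, 5, 0, 13, 59, 2, 0, 12, 22)))
#' diagnostic_metrics(t2)
#' @export
diagnostic_metrics <- function(t2, positive = c("normal", "abnormal")) {
  positive <- match.arg(positive)
  stopifnot(inherits(t2, "cross_table2"))
  neg <- setdiff(diag2, positive)
  tp <- t2[positive, positive]; fn <- t2[neg, positive]
  fp <- t2[positive, neg]; tn <- t2[neg, neg]
  ratio_or_na <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble(
    positive = positive,
    sensitivity_pct = ratio_or_na(tp, tp + fn),
    specificity_pct = ratio_or_na(tn, tn + fp),
    ppv_pct = ratio_or_na(tp, tp + fp),
    npv_pct = ratio_or_na(tn, tn + fn),
    n = as.integer(sum(t2))
  )
}

#' Marginal chi-square consistency test
#'
#' Tests whether the two diagnostic methods produce the same distribution
#' over the three categories: the test's row marginals and the gold
#' standard's column marginals form a 2x3 table, and Pearson's chi-square
#' (no continuity correction, df = 2) compares them. This is a consistency
#' check on the marginal diagnosis distributions, not a paired-agreement
#' test; see [paired_agreement()] for kappa and marginal-homogeneity
#' alternatives.
#'
#' @param t3 A 3x3 [cross_table()].
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
marginal_chi_square <- function(t3) {
  stopifnot(inherits(t3, "cross_table"))
  margins <- rbind(test = rowSums(t3), gold = colSums(t3))
  if (any(colSums(margins) == 0)) {
    abort("A diagnosis category has zero total in both margins: expected count 0.")
  }
  if (all(margins["test", ] == margins["gold", ])) {
    return(tibble(statistic = 0, df = 2L, p = 1))
  }
  ht <- suppressWarnings(chisq.test(margins, correct = FALSE))
  tibble(statistic = unname(ht$statistic),
         df = as.integer(unname(ht$parameter)),
         p = ht$p.value)
}

#' Paired-agreement extras for a 3-class cross-table
#'
#' Optional companions to [marginal_chi_square()] that use the paired
#' structure of the table: Cohen's kappa (unweighted) and the
#' Stuart-Maxwell marginal-homogeneity test. These are not part of the
#' standard report; they are offered for users who want chance-corrected
#' agreement.
#'
#' @param t3 A 3x3 [cross_table()].
#' @return A tibble with one row per statistic: `statistic_name`, `value`,
#'   `df`, `p`.
#' @export
paired_agreement <- function(t3) {
  stopifnot(inherits(t3, "cross_table"))
  n <- sum(t3)
  po <- sum(diag(t3)) / n
  pe <- sum(rowSums(t3) * colSums(t3)) / n^2
  kappa <- (po - pe) / (1 - pe)

  # Stuart-Maxwell: d = first two row-col margin differences,
  # covariance from off-diagonal cells
  d <- (rowSums(t3) - colSums(t3))[1:2]
  s <- matrix(0, 2, 2)
  for (i in 1:2) {
    s[i, i] <- rowSums(t3)[i] + colSums(t3)[i] - 2 * t3[i, i]
  }
  s[1, 2] <- s[2, 1] <- -(t3[1, 2] + t3[2, 1])
  sm <- tryCatch(as.numeric(t(d) %*% solve(s) %*% d),
                 error = function(e) NA_real_)

  tibble(
    statistic_name = c("cohen_kappa", "stuart_maxwell"),
    value = c(kappa, sm),
    df = c(NA_integer_, 2L),
    p = c(NA_real_,
          if (is.na(sm)) NA_real_ else pchisq(sm, df = 2, lower.tail = FALSE))
  )
}

#' @export
print.cross_table <- function(x, ...) {
  cat("3-class diagnosis cross-table (test rows, gold columns)\n")
  print(unclass(x)); invisible(x)
}

#' @export
print.cross_table2 <- function(x, ...) {
  cat("2-class diagnosis cross-table (test rows, gold columns)\n")
  print(unclass(x)); invisible(x)
}
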