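# Independent closed-form oracles. These deliberately re-derive each
# statistic from textbook formulas, independently of the implementation
# paths they are used to check.

oracle_t <- function(a, b, pooled = TRUE) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# published validation cross-table, row-major (test deficient/normal/excess
# rows by gold deficient/normal/excess columns)
table4_counts <- c(29, 5, 0,
                   13, 59, 2,
                   0, 12, 22)
table5_counts <- matrix(c(59, 15, 17, 51), 2, 2, byrow = TRUE)

# one subject whose widths are the normal-group mean of each tooth type,
# identical on both sides
mean_width_cohort <- function(subject_id = "ref") {
  p <- cohort_params()
  ref <- anterior_teeth()
  as_cohort(tibble::tibble(
    subject_id = subject_id,
    tooth_fdi = ref$fdi,
    width_mm = unname(p$means[paste(ref$arch, ref$tooth_type, sep = "_")])
  ), layout = "long")
}

# an 18-row test table carrying the published significance pattern
# (p values of the derivation comparisons, by arch and tooth type)
table1_p_pattern <- function() {
  tidyr::expand_grid(
    arch = c("upper", "lower"),
    tooth_type = c("central", "lateral", "canine"),
    comparison = c("normal_vs_low", "normal_vs_high", "low_vs_high")
  ) |>
    dplyr::mutate(
      t = 0, df = 100, variant = "pooled",
      p = c(
        0.082, 0.076, 0.002,   # upper central
        0.016, 0.009, 0.0001,  # upper lateral
        0.167, 0.268, 0.024,   # upper canine
        0.0001, 0.559, 0.0001, # lower central
        0.003, 0.025, 0.0001,  # lower lateral
        0.508, 0.376, 0.098    # lower canine
      )
    )
}

label_pairs_from_counts <- function(counts) {
  # counts are row-major: pred (rows) varies slowest
  labs <- c("deficient", "normal", "excess")
  pred <- rep(rep(labs, each = 3), counts)
  gold <- rep(rep(labs, times = 3), counts)
  # fixed shuffle so the table construction does not depend on input order
  o <- withr::with_seed(421, sample(length(pred)))
  list(pred = pred[o], gold = gold[o])
}
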