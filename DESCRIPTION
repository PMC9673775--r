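Package: toothratio
Title: Anterior Bolton Ratio and Simplified Anterior Tooth Ratio Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anterior inter-arch tooth-size analysis on mesiodistal
    crown widths of the twelve permanent anterior teeth (FDI notation).
    Computes the anterior Bolton ratio and the simplified anterior tooth
    ratio (SATR) based on the lateral incisors, reproduces the key-tooth
    derivation (Bolton-ratio stratification with pairwise t tests),
    establishes mean +/- k*SD normative standards, classifies subjects into
    deficient/normal/excess ratio categories, and evaluates SATR as a
    screening test against the anterior Bolton gold standard (three- and
    two-class cross-tables, sensitivity/specificity/predictive values, and
    a marginal chi-square consistency test). Includes a seeded synthetic
    cohort generator with a shared tooth-size factor and lateral-incisor
    shift scenarios for testing the full pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
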