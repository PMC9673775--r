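---
title: "Anterior tooth-ratio screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anterior tooth-ratio screening: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothratio)
```

## The two ratios

Bolton's anterior ratio (ABR) summarises inter-arch tooth-size proportion
over the twelve permanent anterior teeth,

$$\mathrm{ABR}\% = 100 \cdot
  \frac{\sum_{\text{mandibular}} w}{\sum_{\text{maxillary}} w},$$

where each $w$ is a mesiodistal crown width in mm. The simplified anterior
tooth ratio (SATR) restricts the sums to the lateral incisors,

$$\mathrm{SATR}\% = 100 \cdot \frac{w_{32} + w_{42}}{w_{12} + w_{22}},$$

because lateral-incisor size variation — microdontia of the upper laterals
in particular — is the dominant clinical driver of anterior tooth-size
discrepancy. Both are implemented as special cases of `generic_ratio()`,
which takes any arch-consistent tooth sets; that generality is what the
key-tooth derivation stage exercises.

When both sides are present, the ratio computed from side *sums* equals the
ratio of bilateral *means* (the factor 2 cancels), so the package stores
widths per tooth and sums them; bilateral means are used only where group
comparisons per tooth type need one value per subject
(`bilateral_means()`).

## Key-tooth derivation

`pairwise_tooth_tests()` reproduces the derivation design: subjects are
stratified by ABR into low (< 77.08%), normal (77.08–80.52%) and high
(> 80.52%) groups — the boundaries are the Chinese normative value
78.8% ± 1.72%, and boundary values belong to the normal group — and, for
each arch × tooth type, the bilateral mean widths are compared between all
three group pairs with independent-samples t tests (18 tests). A tooth
type qualifies as the key tooth of its arch when all three of its
comparisons are significant at $\alpha = 0.05$ (`select_key_teeth()`).
Two conventions matter:

* **Variance handling.** The default `variant = "auto"` applies Levene's
  test centred at the group mean and uses the pooled (Student) statistic
  when homogeneity is not rejected at 0.05, Welch otherwise. The variant
  actually used is recorded per test for audit. `"pooled"` and `"welch"`
  force one path.
* **No multiplicity correction by default.** The derivation design tests
  18 hypotheses without correction; `p_adjust` accepts any
  `stats::p.adjust` method for sensitivity analyses, default `"none"`.

Degenerate inputs follow explicit rules: two zero-variance samples with
equal means give $t = 0, p = 1$; with unequal means the statistic is
undefined and the call errors. If more than one tooth type qualifies in an
arch the selection is ambiguous and errors rather than picking silently —
this genuinely occurs when a cohort is stratified on the ratio itself,
since selection on a ratio induces differences in every tooth entering it.

## Association and prediction

`fit_satr_abr()` fits ordinary least squares of ABR on SATR and reports
the Pearson correlation, with `tidy()`/`glance()` accessors. Regression
is carried out on ratio *fractions* (0.857, not 85.7): a published-style
relation $y = 0.503 + 0.328x$ is dimensionally consistent only on that
scale, so percent inputs are converted internally and `predict_abr()`
reports percent by default. Plugging the standard SATR mean (85.69%) into
those coefficients predicts an ABR of 78.41%, inside the 77.08–80.52%
normal band — the consistency check between the two standards.

## Normative standards and classification

A standard is a mean ± k·SD band (`norm_standard()`); `k = 1` because the
published SATR thresholds equal mean ± 1 SD exactly (82.12 = 85.69 − 3.57,
89.26 = 85.69 + 3.57). `establish_standard()` computes a standard from
data using the n − 1 sample SD. `classify_ratio()` maps values below the
band to *deficient*, above to *excess*, and the band itself (bounds
inclusive) to *normal*.

Numerical conventions:

* Thresholds are kept at full precision; a decimal like 85.69 + 3.57 is
  not exactly representable in binary, so classification applies a 1e-9
  tie tolerance — a value equal to a bound at decimal precision is
  normal, as the inclusive-band rule requires.
* `strict_paper = TRUE` instead compares against thresholds rounded to
  2 decimals, reproducing tables built from printed thresholds. Whether a
  study used rounded or exact thresholds is usually unknowable from its
  text, so both modes exist; they differ only for values between a rounded
  and an exact bound.

## Diagnostic validation

With ABR classification as the gold standard, `cross_tabulate()` builds
the 3×3 table of paired diagnoses, `collapse_to_binary()` pools deficient
and excess into *abnormal*, and `diagnostic_metrics()` computes
sensitivity, specificity, PPV and NPV. The positive condition defaults to
**normal**: the screening question is "can SATR recognise a normal
anterior ratio", and under this convention the published 2×2 table
(59, 15 / 17, 51) yields Sen 59/76 = 77.63% and Spe 51/66 = 77.27%.
Setting `positive = "abnormal"` swaps the roles; a metric whose
denominator is empty is reported `NA` rather than dropped.

The consistency test (`marginal_chi_square()`) compares the two methods'
*marginal* diagnosis distributions: the test's row totals and the gold
standard's column totals form a 2×3 table tested with Pearson's chi-square
without continuity correction (df = 2). This marginal construction is the
one that reproduces the published consistency statistic
(χ² = 2.59, p = 0.27 on margins 34/74/34 vs 42/76/24); it is *not* a
paired-agreement test, so chance-corrected alternatives (Cohen's kappa and
Stuart–Maxwell marginal homogeneity) are available separately in
`paired_agreement()` and are excluded from the standard report. Accuracy
is likewise excluded: with deficient and excess pooled as abnormal it is
ambiguous enough to mislead.

## The synthetic cohort generator

Real dental-cast datasets of this kind are not public, so
`simulate_cohort()` generates width records with the statistical structure
the analysis assumes:

$$w_{s,\,\text{type},\,\text{side}} = \mu_{\text{type}}
  + \lambda_{\text{type}} Z_s + \tau_{\text{type}} U_{s,\text{type}}
  + \text{shift}_{\text{type}}(\text{scenario})
  + \varepsilon_{s,\,\text{type},\,\text{side}}$$

with $Z_s$ a standard-normal per-subject size factor shared by the whole
mouth, $U$ a per-(subject, arch, tooth-type) effect shared by the two
sides, and $\varepsilon$ independent left–right noise. The variance is
decomposed as $\sigma^2_{\text{type}} = \lambda^2 + \tau^2 +
\sigma^2_{\text{asym}}$ with $\lambda^2 =
\text{share}\cdot\sigma^2_{\text{type}}$, so the marginal per-tooth SD
equals the input SD exactly — the property the generator's moment-recovery
tests pin down (sample means and SDs within 0.05 mm of the inputs at
n = 2000). Defaults:

* per-tooth-type means/SDs: the normal-ABR derivation group's values
  (upper central 8.650 ± 0.490 mm, upper lateral 7.216 ± 0.511, upper
  canine 8.007 ± 0.522; lower central 5.654 ± 0.418, lower lateral
  6.172 ± 0.350, lower canine 6.961 ± 0.531). The implied mean-record
  ratios are ABR 78.70% and SATR 85.53%.
* `size_factor_sd_share = 0.5`: half of each tooth's variance is the
  shared size factor. Inter-tooth width correlations in the source
  population are unreported, so this is a modelling default chosen to make
  tooth sizes covary realistically within a mouth; it is configurable and
  deliberately not tuned.
* `asymmetry_sd_mm = 0.15`: small independent left–right noise, an order
  of magnitude below tooth-type SDs, reflecting that contralateral teeth
  are nearly but not exactly symmetric.
* Scenario shifts are deterministic, not drawn, so ground truth is exact
  and power analyses are interpretable. Names describe the *upper*
  lateral incisors: `lateral_deficient` subtracts `lateral_shift_mm` from
  the upper laterals and adds `lower_shift_frac` times it to the lower
  laterals (raising SATR and ABR together); `lateral_excess` mirrors it.
  `lower_shift_frac = 0.6` mirrors the roughly 0.43 : 0.30 mm ratio of
  upper to lower lateral group differences observed in derivation-style
  data. `lateral_shift_mm = 0.4` mm makes the three-group design
  (`simulate_three_group_study()`) plant group mean ABRs of about
  76.4 / 78.7 / 81.1%, clearing the 77.08/80.52 stratification bounds;
  shifts too small to clear them produce a warning.
* Generated widths are clipped to the 3–15 mm plausibility window with a
  warning and a count (`n_clipped`); malformed-tooth (peg-shaped)
  morphology is deliberately not simulated, matching the exclusion
  criteria such studies apply.

What the generator does *not* emulate: empirical inter-tooth correlation
structure (only the single shared factor), measurement error of a specific
scanner or operator, and the tighter SATR dispersion of a real
perfect-occlusion sample — the synthetic SATR SD (≈ 5–7%) exceeds the
published 3.57% because only four teeth enter SATR and their residual
variance is conservative here. Consequently, synthetic diagnostic
operating characteristics are lower bounds, and passing tests demonstrate
correctness of the pipeline's logic, not clinical performance on real
casts.

## Pipeline and configuration

`run_pipeline()` sequences ratio computation, derivation, association,
standard establishment, classification and diagnostic evaluation on one
cohort; each stage checks its own completeness requirement
(Bolton-complete for derivation/association, SATR-complete for
classification) and errors naming the stage otherwise. The evaluation
stage needs a gold diagnosis: the cohort's own ABR classification when all
12 teeth are present, or caller-supplied labels for lateral-only cohorts.
`pipeline_config()` carries every constant (bounds, standard, alpha,
variant, positive condition, strict-paper flag) with the published values
as defaults and round-trips through YAML (`write_config()`,
`read_config()`), so a report is fully determined by cohort + config.

## Problem sizes and test design

The test suite generates everything programmatically: oracle checks run
the closed-form statistic implementations against 100 random small
instances at 1e-10; the type-I-error simulation uses 1000 replicates of a
60-subject null cohort (rejection rate 3–7% around the nominal 5%); the
key-tooth power simulation uses 100 replicates of the 80-per-group design
(> 95% select the laterals in both arches); moment recovery uses one
2000-subject cohort. These sizes give stable Monte-Carlo estimates —
the binomial SE of the null rejection rate at 18,000 tests is under
0.2 percentage points — while keeping the suite quick to run.

## Known limitations

* The generator's covariance model is a single shared factor; real crown
  widths have richer correlation (neighbouring teeth, arch-specific
  factors), so synthetic SATR/ABR dispersions and their correlation
  (r ≈ 0.6–0.75 at defaults) should not be read as population estimates.
* The marginal chi-square construction is identified from the published
  statistic; other software may label a different consistency test the
  same way. The paired-agreement extras are provided for that reason.
* Ratios require complete tooth sets: missing teeth make a record
  ineligible for the affected ratio rather than being imputed, matching
  the complete-dentition eligibility such studies enforce.
* Intraoral-scan processing, landmark picking and reliability (ICC)
  analysis of repeated measurements are out of scope; the package starts
  from measured widths.
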