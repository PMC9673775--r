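# toothratio

Anterior inter-arch tooth-size analysis for orthodontic screening:
the anterior Bolton ratio, the lateral-incisor-based simplified anterior
tooth ratio (SATR), and the statistics used to derive, standardise and
validate SATR as a quick chairside screening test.

## The problem

A harmonious bite requires the mesiodistal crown widths of the upper and
lower anterior teeth to be in proportion. The classical index is Bolton's
anterior ratio,

```
ABR% = 100 * (sum of the 6 mandibular anterior widths)
           / (sum of the 6 maxillary anterior widths)
```

which needs 12 measurements per patient. Because lateral-incisor size
variation is the main driver of anterior tooth-size discrepancy, a
simplified ratio over the four lateral incisors,

```
SATR% = 100 * (w32 + w42) / (w12 + w22)        (FDI codes)
```

can screen patients with four measurements. This package implements the
whole analysis pipeline around that idea, for orthodontists and
biostatisticians working with dental-cast width data:

* **data model & I/O** — per-subject widths keyed by FDI code, wide/long
  CSV readers and writers, completeness and plausibility validation;
* **ratios** — `anterior_bolton_ratio()`, `satr()`, and `generic_ratio()`
  for arbitrary arch-consistent tooth sets;
* **derivation** — stratify a cohort at ABR 77.08%/80.52%, run the 18
  pairwise per-tooth-type t tests (Levene-gated pooled/Welch) and select
  the key tooth type per arch (`pairwise_tooth_tests()`,
  `select_key_teeth()`);
* **association** — Pearson correlation and OLS of ABR on SATR, with
  `tidy()`/`glance()`/`autoplot()` methods and `predict_abr()`;
* **norms** — mean ± k·SD standards (`satr_standard()`: 85.69% ± 3.57%,
  normal band 82.12–89.26%; `bolton_standard()`: 78.8% ± 1.72%) and
  three-way classification into deficient/normal/excess;
* **diagnostics** — 3×3 and collapsed 2×2 screening-vs-gold cross-tables,
  sensitivity/specificity/PPV/NPV (positive condition = "normal"), and a
  marginal chi-square consistency test;
* **synthetic cohorts** — a seeded generator with a shared per-subject
  tooth-size factor, left–right asymmetry noise and lateral-incisor shift
  scenarios, so the full pipeline is testable without patient data.

## Worked example

```r
library(toothratio)

# key-tooth derivation on a three-group synthetic study (80 per group)
tg  <- simulate_three_group_study(c(80, 80, 80), seed = 2024)
der <- run_pipeline(tg$cohort, stages = "derive")
der$derive$selection
#>   arch  tooth_type
#> 1 upper lateral
#> 2 lower lateral

# association, standard and diagnostic validation on a mixed cohort
val <- simulate_cohort(142, scenario = "mixed", seed = 2024)
rep <- run_pipeline(val$cohort,
                    stages = c("associate", "norm", "classify", "evaluate"))
rep
#> Anterior tooth-ratio analysis report
#>   stages: associate, norm, classify, evaluate
#> SATR-Bolton linear association (OLS on ratio fractions)
#>   abr = 0.5436 + 0.2806 * satr   (n = 142)
#>   Pearson r = 0.633, p = 3.03e-17
#> Normative standard: 85.67% +/- 1 x 7.56%  (normal 78.11-93.23%, n = 142)
#> # A tibble: 1 x 6
#>   positive sensitivity_pct specificity_pct ppv_pct npv_pct     n
#>   <chr>              <dbl>           <dbl>   <dbl>   <dbl> <int>
#> 1 normal              52.5            74.7    59.6    68.9   142
#> # A tibble: 1 x 3
#>   statistic    df     p
#>       <dbl> <int> <dbl>
#> 1      1.27     2 0.529
```

The derivation stage recovers the lateral incisors as the key teeth in
both arches — the planted mechanism. In the validation stage the fitted
line (`abr = 0.544 + 0.281 satr`) and the positive correlation (r = 0.63)
show SATR tracking the Bolton ratio; the sensitivity/specificity block is
the screening performance of the SATR classification against the Bolton
gold standard on this synthetic cohort, and the chi-square line (p = 0.53)
says the two methods' diagnosis distributions are statistically
consistent. Synthetic SATR scatters more than a real perfect-occlusion
sample would (the generator's inter-tooth correlations are conservative),
so these synthetic operating characteristics are a lower bound; see the
methods vignette.

Classifying a single new patient needs only the four lateral incisors:

```r
pt <- as_cohort(data.frame(subject_id = "new",
                           `12` = 7.4, `22` = 7.3, `32` = 5.9, `42` = 6.0,
                           check.names = FALSE))
satr(pt)                                  # 81.0%
classify_ratio(satr(pt)$value_pct, satr_standard())   # deficient
```

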