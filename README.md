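# dlrplan

Quantitative bias analysis for the **planning** stage of a comparative
cohort database study whose outcome is identified by an imperfect claims- or
EMR-based phenotype algorithm.

When an outcome is read from administrative data through a phenotype
algorithm, validation studies report how imperfect that algorithm is:
sensitivity (Se), specificity (Sp), prevalence, PPV, NPV. The pivotal
quantity for carrying those results into a *new* study is the **positive
diagnostic likelihood ratio**,

```
DLR+ = Se / (1 - Sp),
```

the factor converting pre-test disease odds into post-test odds. Because it
does not depend on prevalence, DLR+ travels between populations where PPV
does not. `dlrplan` implements the workflow built on it:

* **Validation summary** — all seven measures from the 2×2 cell counts,
  with exact Clopper–Pearson intervals for the proportions and Katz
  log-scale intervals for DLR+ and DLR− (`summarize_validation()`).
* **Planning projections** — the expected PPV of the planned study at an
  assumed prevalence `p`, `PPV = DLR+·p / (DLR+·p + 1 − p)`, and the
  expected risk ratio under non-differential outcome misclassification,

  ```
  RR_exp = RR_true + (1 − RR_true) / (R_con·(DLR+ − 1) + 1),
  ```

  with ranges propagated from the DLR+ confidence interval
  (`plan_db_study()`, `expected_ppv()`, `expected_rr()`,
  `assess_over_ranges()`). For a true RR above 1 the bias is always
  negative: attenuation toward the null.
* **PPV-only reports** — back-solve `DLR+ = post-test odds / pre-test odds`
  from a reported PPV and a plausible prevalence (`dlr_from_ppv()`), and
  derive plausible DLR+ spans from whole collections of PPV-only algorithms
  over a prevalence band (`dlr_span()`, `plot_dlr_band()`).
* **Monte-Carlo oracle** — seeded generators for synthetic validation
  tables and misclassified two-group cohorts (`simulate_validation()`,
  `simulate_cohort()`, `empirical_rr()`) used to verify every closed form
  empirically.
* **Figures** — `ggplot2` renderers for the standard displays
  (`plot_ppv_vs_dlr()`, `plot_rr_vs_dlr()`, `autoplot()` on a fitted plan,
  `plot_dlr_band()`), plus broom-style `tidy()`/`glance()` methods and a
  thin command-line wrapper (`exec/dlrplan`).

## Worked example

Three published validation studies of acute-MI phenotype algorithms
(cell counts TP/FP/FN/TN as published):

```r
library(dlrplan)

studies <- data.frame(
  label = c("Kennedy", "Pladevall", "Austin"),
  n_tp  = c(67,    401,  20048),
  n_fp  = c(43,    333,   2594),
  n_fn  = c(4,      95,   2521),
  n_tn  = c(20272, 4500, 33653)
)

plan <- plan_db_study(studies, prevalence_db = 0.05,
                      control_risk = 0.03, true_rr = 2)
plan
```

The report prints, per study, the validation block and the planning block.
For Kennedy:

```
== Kennedy (N = 20386: TP 67, FP 43, FN 4, TN 20272)
  Validation study          Estimate   95% CI
  sensitivity                  0.944   0.862, 0.984
  specificity                  0.998   0.997, 0.998
  prevalence                   0.003   0.003, 0.004
  ppv                          0.609   0.511, 0.701
  npv                          1.000   0.999, 1.000
  dlr_pos                      445.8   329.0, 604.2
  dlr_neg                        0.1   0.0, 0.1
  Planned DB study          Expected   Range (DLR+ CI)
  ppv_db                       0.959   0.945, 0.970
  rr_expected                  1.930   1.908, 1.948
  bias_relative_pct            -3.49   -4.61, -2.62
```

Reading: although Kennedy's own PPV is only 0.609 (its validation
population had prevalence 0.003), its DLR+ of 445.8 implies that in a
planned study with prevalence 0.05 the algorithm would achieve an expected
PPV of 0.959, and a true risk ratio of 2 would be attenuated by only about
3.5% at a control-group risk of 0.03. The other two studies (DLR+ ≈ 12)
project expected PPVs below 0.4 and attenuation near −37%, so the choice of
validation study dominates the planning assessment.

When only PPVs are published, a plausible DLR+ span over a prevalence band:

```r
algos <- data.frame(
  label = c("Merry 2009", "Kiyota 2004p", "Ainla 2006", "Kiyota 2004s",
            "Barchielli 2010", "Hammar 2001", "Heckbert 2004",
            "Varas-Lorenzo 2008"),
  ppv = c(0.9688, 0.9411, 0.933, 0.9245, 0.8602, 0.8583, 0.8302, 0.7202)
)
dlr_span(algos, c(0.1, 0.3), rule = "all")
#> # A tibble: 1 × 4
#>   rule  lower upper n_algorithms
#>   <chr> <dbl> <dbl>        <int>
#> 1 all    6.01  279.            8
```

so DLR+ values from about 6 to about 279 are consistent with all eight
algorithms; `rule = "median"` narrows this to the central algorithms
(≈ 14.4–110.2). `plot_dlr_band(algos, c(0.1, 0.3))` draws the curves, the
band, and both spans.

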