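---
title: "Planning database studies with the diagnostic likelihood ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning database studies with the diagnostic likelihood ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlrplan)
```

## The problem

A comparative cohort study built on an administrative claims or EMR
database does not observe its outcome directly: it observes a *phenotype
algorithm* — a combination of diagnosis, prescription and procedure codes —
that imperfectly identifies the true outcome. Validation studies quantify
that imperfection against a gold standard as a 2×2 table of true/false
positives and negatives, from which sensitivity (Se), specificity (Sp),
prevalence, PPV and NPV are estimated.

The difficulty at the *planning* stage is that the most intuitive measure,
the PPV, is prevalence-dependent: an algorithm with PPV 0.61 in a
population with prevalence 0.003 can deliver PPV 0.96 where prevalence is
0.05. `dlrplan` is organized around the measure that transfers: the
positive diagnostic likelihood ratio

$$\mathrm{DLR}^+ = \frac{Se}{1 - Sp},$$

the ratio of post-test to pre-test disease odds. Under the two working
assumptions below, DLR+ is invariant across populations, so a single number
from a validation study determines the whole planning analysis.

## Model and assumptions

Two assumptions underlie every projection in the package, and they are
stated in the report footer rather than buried:

1. **Transportability**: Se and Sp are the same in the validation
   population and the planned study population.
2. **Non-differential misclassification**: Se and Sp are the same in the
   test (exposed) and control groups of the planned cohort.

Given these, three closed forms drive everything:

* **Expected PPV** (Bayes' theorem in odds form):
  $\mathrm{PPV} = \dfrac{\mathrm{DLR}^+ \, p}{\mathrm{DLR}^+ \, p + 1 - p}$
  for planned-study prevalence $p$ (`expected_ppv()`); the NPV analogue
  uses $\mathrm{DLR}^- = (1-Se)/Sp$ (`expected_npv()`).
* **Odds inversion**: $\mathrm{DLR}^+ =
  \dfrac{\mathrm{PPV}/(1-\mathrm{PPV})}{p/(1-p)}$ (`dlr_from_ppv()`), the
  exact inverse of the previous form, used when a validation study reports
  only a PPV.
* **Expected risk ratio**: with true risk ratio $RR$ and true control-group
  risk $R_{con}$, the expected observed risks are
  $R\,Se + (1-R)(1-Sp)$ per group (`expected_risk()`), and their ratio
  reduces to
  $$RR_{exp} = RR + \frac{1 - RR}{R_{con}(\mathrm{DLR}^+ - 1) + 1}$$
  (`expected_rr()`). The second term is the bias; for $RR > 1$ it is
  negative for every finite DLR+ and every valid $R_{con}$ — attenuation
  toward the null — and vanishes as $\mathrm{DLR}^+ \to \infty$. Both of
  these facts are asserted as property tests, and the reduction from the
  ratio-of-expected-risks form is checked to machine precision.

Relative bias is reported as $100 \cdot (RR_{exp} - RR)/RR$ percent, so
attenuation carries a negative sign.

## Confidence intervals

* Proportions (Se, Sp, prevalence, PPV, NPV) get exact **Clopper–Pearson**
  intervals, each treated as a simple binomial with its own numerator and
  denominator (prevalence uses diseased-out-of-N). The implementation uses
  the beta-quantile form; the test suite checks it for all `x` at several
  `n` against an independent bisection on the binomial tail probabilities,
  and against `stats::binom.test()`.
* DLR+ and DLR− get the **Katz log-scale** interval for a ratio of two
  binomial proportions: $\exp(\ln D \pm z\,SE)$ with
  $SE^2 = 1/a - 1/(a{+}c) + 1/b - 1/(b{+}d)$ (cells relabelled for DLR−).
  The interval is symmetric about the estimate on the log scale, and its
  log-width shrinks like $1/\sqrt{k}$ when all cells are scaled by $k$
  (both asserted). The $z$ quantile is computed from the requested level,
  never hard-coded, so non-0.95 levels work throughout.
* A cell of zero in a ratio's numerator makes the Katz variance undefined;
  the interval is then reported as **not estimable** (`NA`, printed `NE`)
  rather than silently corrected. An optional Haldane-style 0.5
  continuity correction (`correction = TRUE`) is available but off by
  default, because a correction that engages silently changes reported
  numbers.

## Range propagation

Scenario parameters (DLR+, prevalence, control risk) may be ranges — most
usefully, the DLR+ confidence interval. Every projection above is monotone
in each argument, so the extremes over a box of parameters occur at its
corners; `assess_over_ranges()` therefore evaluates only the endpoint
combinations, which is exact and fast. A test compares the endpoint result
against a dense 41×41 grid to confirm the monotonicity argument, and full
grids are still used where they belong: drawing curves.

Degenerate ranges (lower = upper) collapse to the point calculation, and
`dlr_pos = Inf` is handled as the exact limit (PPV 1, zero bias), never as
a large sentinel value.

## PPV-only collections

When several algorithms are known only through PPVs, each PPV plus a
plausible prevalence band $[p_{min}, p_{max}]$ yields an interval of
compatible DLR+ values (the curve `dlr_from_ppv(ppv, ·)` is strictly
decreasing in prevalence). Two span rules are provided:

* `"all"`: from the lowest-PPV curve at $p_{max}$ up to the highest-PPV
  curve at $p_{min}$ — the smallest interval consistent with every
  algorithm (the first curves met by horizontal lines moving up from below
  and down from above).
* `"median"`: the same construction restricted to the central algorithm
  (odd count) or the central two (even count) after sorting by PPV. Ties
  are broken by a stable sort on (ppv, label); tied central PPVs collapse
  to one curve. This rule is a pragmatic narrowing device, not an
  inferential procedure.

The band itself is an investigator judgement; the package deliberately does
not infer it from data. Span endpoints are kept at full precision and
rounded to integers only for display.

## The synthetic-data generators

`simulate_validation()` draws the four table cells from a multinomial with
probabilities $(p\,Se,\ (1-p)(1-Sp),\ p(1-Se),\ (1-p)Sp)$ — the
random-sample model of a validation study. `simulate_cohort()` draws, per
group, true positives as binomial$(n, \text{risk})$ and observed positives
as a binomial thinning at Se plus binomial false positives at $1-Sp$. Both
take an explicit seed and are pure functions of their arguments (no global
RNG state leaks). Replicates with zero observed control positives have an
undefined empirical risk ratio; `empirical_rr()` sets them to `NA` and
counts them rather than continuity-correcting, so the Monte-Carlo oracle is
never quietly biased.

These generators emulate exactly the idealized world of the closed forms:
simple random sampling, perfectly known gold standard, non-differential
errors, binary outcome, no censoring or person-time. Passing Monte-Carlo
tests therefore validates the algebra, not the realism of any particular
application: real validation studies have imperfect gold standards,
cluster structure, and possibly differential misclassification, all outside
scope here.

Problem sizes in the test suite were chosen so the whole default run stays
comfortably interactive: parameter recovery uses 40 replicates of n = 10⁴;
the risk-ratio oracle grid uses 500 replicates of n = 10⁴ per cell over a
3×3×3 grid of (true RR, control risk, DLR+), comparing the mean empirical
RR with the closed form at 3 Monte-Carlo standard errors. When realizing a
target DLR+ as (Se, Sp) for simulation, sensitivity is fixed at 0.9 and
specificity solved for, which keeps expected event counts large enough that
the small Jensen bias of the ratio estimator stays well inside the
Monte-Carlo tolerance.

## Numerical and design choices

* All computation is at full precision; the conventional display rounding
  (3 decimals for proportions, 1 for likelihood ratios) exists only in
  formatted reports.
* Projection ranges use full-precision DLR+ CI endpoints, not their rounded
  display values — this reproduces published planning tables to the printed
  digit.
* `expected_ppv(0, p) = 0`, `expected_ppv(Inf, p>0) = 1`, and
  `dlr_from_ppv()` refuses PPV or prevalence at exactly 0 or 1 (infinite
  odds) instead of returning infinities that would propagate silently.
* Per-measure failures never abort a multi-study summary: each study ×
  measure cell degrades to `NA` independently.
* Reports normalize any Unicode minus/dash to ASCII so the CSV and text
  outputs are machine-readable everywhere.

## Limitations

Differential misclassification, risk-difference and odds-ratio effect
measures, NPV-based planning beyond the direct DLR− analogue,
survival/person-time outcomes, meta-analytic pooling of DLR+ across
studies, and post-study bias adjustment are all out of scope. The
projections are planning heuristics under strong assumptions; they inform
design choices (including the choice to run a new validation study), not
post-hoc corrections.
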