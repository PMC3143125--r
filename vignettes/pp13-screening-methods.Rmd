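---
title: "MoM normalization and ABO-adjusted PP13 screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MoM normalization and ABO-adjusted PP13 screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pp13screen)
```

## The problem

Placental protein 13 (PP13, galectin-13) is a placenta-specific lectin whose
maternal serum concentration rises through pregnancy; abnormally low
first-trimester levels, and elevated later levels, mark pregnancies that go
on to develop preeclampsia or intrauterine growth restriction (IUGR). PP13
binds beta-galactosides — the terminal sugars of ABO blood-group antigens —
so red blood cells can sequester circulating PP13 to a degree that depends
on the mother's ABO group: binding is strongest to group AB cells and
weakest to group B cells, which inversely mirrors serum levels (group B
women have the highest serum PP13, group AB the lowest in the first
trimester). Blood group is therefore a confounder of the PP13 screening
test, and adjusting for it should sharpen disease discrimination.

This package implements that analysis chain end to end, together with a
synthetic cohort generator that reproduces the statistical structure the
chain assumes, so every stage is testable without access to the original
cohorts.

## The normalization model

Serum concentrations are heavily right-skewed and strongly
gestational-age-dependent, so screening works on multiples of the median
(MoM):

$$\mathrm{MoM}_i = \frac{C_i}{m(w_i)},$$

where $m(w)$ is the median concentration among unaffected pregnancies at
gestational week $w$ (`fit_median_curve()`, weekly bins, midpoint median
convention for even counts, undersized bins merged into the nearest
neighbour). A MoM of 1.0 means "typical for this week".

MoMs are then **sequentially** adjusted for BMI, ethnicity, smoking,
maternal age and parity (`fit_covariate_adjustment()`): for each covariate
in that order, $\log \mathrm{MoM}$ is regressed on the covariate among
unaffected records, the centred fitted component is removed, and the
residuals feed the next covariate. Working on the log scale treats the
effects as multiplicative, which matches the ratio nature of MoMs; centring
each step preserves the geometric mean, so the adjustment recenters without
rescaling. A joint multiple-regression mode (`joint = TRUE`) is provided
for sensitivity analysis; the sequential form is the default because that
is how stepwise MoM adjustment is done in prenatal screening practice.

Finally, ABO blood-group factors are fitted
(`fit_blood_group_factors()`): the factor for group $g$ (per trimester by
default, since the group effect shrinks as pregnancy advances) is the
median covariate-adjusted MoM among unaffected women of that group, and
each record is divided by its stratum's factor. After this step every
group's unaffected median sits at 1.0 — exactly so in odd-count strata,
because the middle order statistic divided by itself is 1.

Strata with fewer than 5 records fall back to a factor of 1.0 with a
warning rather than an estimate: a median from 2-4 observations is noise,
and real AB strata can be that small.

## Out-of-sample scoring and evaluation

Because the subjects being scored are also the subjects the models were
fitted on, in-sample risk scores are optimistically biased. `loo_scores()`
therefore refits *all three* fitted components — median curve, covariate
model, blood-group factors — with each subject excluded in turn, and
scores her held-out samples with those models. If the held-out subject's
gestational week vanishes from the refitted curve, the nearest fitted
week's median is used (lower week on ties).

Screening performance is evaluated with hand-built ROC machinery
(`roc_curve()`, `auc()`, `sensitivity_at_fpr()`), whose conventions
matter and are therefore fixed in-package rather than delegated:

* first-trimester scoring treats **low** MoM as screen positive
  (`direction = "low"`); later trimesters would use `"high"`, matching the
  sign flip of the disease effect;
* tied scores collapse into a single ROC step and contribute half credit
  to the AUC, making the trapezoidal AUC equal to the pairwise rank
  probability (the Mann-Whitney statistic scaled to [0, 1]);
* sensitivity at a fixed false-positive rate uses the conservative step
  convention — the best TPR among realized operating points with
  FPR $\le$ target, with no interpolation — because that is what a
  laboratory deploying a threshold can actually achieve. The realized FPR
  is reported alongside the nominal target.

Likelihood ratios follow the standard definitions
$LR^+ = \mathrm{sens}/(1-\mathrm{spec})$,
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$, overall $LR = LR^+/LR^-$.
A reporting mode rounds $LR^\pm$ to two decimals before the ratio, which
is how published screening tables are typically assembled.

No published method exists for testing the significance of a sensitivity
difference between two scorings of the same cohort at fixed FPR, so
`compare_sensitivities()` uses a paired subject bootstrap (2000 resamples
by default, deterministic given a seed) and a two-sided tail p-value from
the centred bootstrap distribution. On discrete sensitivities the test is
conservative; the unit suite asserts size control from above only.

## What the synthetic generator emulates

`generate_cohort()` draws cohorts under the model

$$\log C = \log m_{w} + \log g_{b,t} + \log d_{o,t} + x'\beta +
  \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

with, by default:

* **Design**: 1078 subjects; outcome split 1006 unaffected / 52 IUGR /
  15 preeclampsia / 5 preeclampsia-with-IUGR; three sampling windows
  (6-10, 16-20, 24-28 weeks, uniform integer week within window); visit 1
  always observed, visits 2 and 3 each missing independently with
  probability 0.1 (sample counts then fall roughly 1078 → 970 → 970,
  emulating longitudinal attrition).
* **Baseline**: unaffected medians 119 / 121 / 212 pg/ml per window. Each
  sample uses its window's baseline (`baseline_by = "window"`); a
  piecewise-linear weekly curve through (8, 119), (18, 121), (26, 212)
  with end-slope extrapolation is available via `baseline_by = "week"`.
* **Blood groups**: frequencies O .47 / A .29 / B .17 / AB .07.
  First-trimester serum multipliers 0.94 / 1.01 / 1.57 / 0.58 — the
  observed group-specific MoM medians of a first-trimester cohort. The
  later-trimester multipliers are not published numerically anywhere, so
  they are the package's own calibration: the AB deficit attenuates
  (0.58 → 0.80 → 1.00) while the B excess persists (1.57 → 1.45 → 1.45).
  The persistent B elevation is deliberate: combined with the rising
  baseline it keeps group B's concentration-versus-week regression slope
  the steepest of the four groups, the qualitative trend the analysis is
  meant to exhibit. (A decaying B multiplier, e.g. 1.30 by trimester 3,
  silently *inverts* that ordering — the elevation it removes outweighs
  the baseline rise.)
* **Disease effects**: multiplicative MoM shifts per trimester — IUGR
  0.37 / 1.38 / 1.22, preeclampsia 0.27 / 1.71 / 1.82, preeclampsia with
  IUGR 0.25 / 1.91 / 1.62 — low in the first trimester, elevated later.
* **Noise**: $\sigma = 0.4$ on the natural-log scale, a realistic
  inter-individual spread for a serum placental protein (interquartile
  ratio around 1.7); covariates default to a small BMI effect (0.01 per
  kg/m², centred) and null effects elsewhere, since published covariate
  correlations are reported as P-values without coefficients.

One global seed drives a single vectorized RNG stream, so a fixed
configuration reproduces byte-identical tables.

What the generator does **not** emulate: assay-level measurement error
structure (plates, batches), correlation of a subject's repeated visits
beyond her fixed multipliers, gestational-age estimation error, covariate
interactions (BMI-by-ethnicity and GA-by-BMI terms are reported
significant in real cohorts but without coefficients; they are absent
here), and the event-level flow-cytometry distributions behind the
binding panel (only summarized MFI means/SEMs are produced). Tests passing
on these cohorts therefore validate the *pipeline arithmetic and its
statistical behaviour under the assumed structure*, not the clinical
performance of PP13 on real populations — in particular, published AUCs
and P-values from the original cohorts are not reproducible from
synthetic data and are not asserted anywhere.

## The binding panel and the inverse-mirror statistic

`generate_binding_panel()` produces the summarized output of an
erythrocyte-binding assay: MFI following a saturating curve
$b_0 + B_g c/(c+K)$ with capacities ordered AB > A ≈ O > B
(1000 / 620 / 600 / 350 fluorescence units, $K = 20$ µg/ml, floor 60),
four ligand concentrations (6.25-50 µg/ml), five replicate experiments
with 5% CV, and CRD-deficient controls (truncated PP13, BSA) at the
floor. `proportional_profile()` converts per-group values into percent
shares ("percent of four-group total" — the interpretation adopted for
comparing serum and binding panels; a per-group-over-conditions variant
was considered and rejected as it destroys cross-panel comparability).
`inverse_mirror_score()` is the Spearman rank correlation between serum
and binding shares; with the A/O near-tie mid-ranks keep the statistic
stable, and the default panels score $-0.8$ (perfect inversion would be
$-1$; the A ≈ O pair is deliberately *not* tied exactly).

## Numerical conventions and degenerate inputs

* Medians: midpoint interpolation at even counts, everywhere.
* Median 95% CIs in reports: binomial order-statistic method (no
  distributional assumption, honest at small n).
* Constant covariates: coefficient 0 with a warning, not an error.
* Unseen covariate levels at apply time: adjustment 0 with a warning.
* A queried gestational week with no fitted bin: error naming the week,
  except in held-out scoring where the nearest-bin fallback applies.
* Degenerate (constant) profiles in `inverse_mirror_score()`: score 0
  with a `degenerate` attribute rather than NA.
* FPR 0 with positive sensitivity: explicit "infinite LR+" error.

## Problem sizes in the test suite

The unit and acceptance suites run entirely on generated data: cohorts of
40-2700 subjects for structural checks, 50 replicate cohorts of n = 1000
for the adjustment-benefit property (AUC after ABO adjustment exceeds AUC
before in ≥ 90% of seeds; under a null group effect the mean AUC change
stays below 0.02), n = 2000 for parameter recovery (blood-group factors
within 10% of generator truth), and n = 200 for the leave-one-out
equality against an independently coded brute-force refit oracle at
1e-12. These sizes give each check comfortable statistical margin while
keeping the default suite under a minute.

## Known limitations

* The sequential adjustment is order-dependent by construction; the order
  (BMI, ethnicity, smoking, age, parity) is fixed to the conventional
  one, and the joint mode exists to quantify sensitivity to it.
* Whether the original covariate adjustment was fitted on unaffected
  women only or the full cohort is not documented; this package fits on
  unaffected only, consistent with the MoM convention of referencing
  everything to unaffected pregnancies.
* Per-trimester blood-group factors assume enough unaffected women per
  group per trimester; pooled mode (`per_trimester = FALSE`) is the
  escape hatch for small cohorts.
* The bootstrap sensitivity comparison is a documented substitute for an
  unspecified published method, not a reconstruction of it.
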