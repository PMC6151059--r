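---
title: "Methods: scoring, complication coding, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, complication coding, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msas)
```

## The score

The surgical Apgar score condenses intraoperative physiology into three
binned components: estimated blood loss (EBL, mL; 0–3 points), lowest mean
arterial pressure (MAP, mmHg; 0–3) and lowest heart rate (HR, beats/min;
0–4), summing to 0–10 with low totals flagging high-risk cases. The
modified variant (MSAS) used throughout this package compresses only the
EBL bins (≤50 / 51–150 / 151–300 / >300 mL) for minimally invasive
surgery, where losses above 300 mL are already exceptional. MAP and HR
minima are taken over the anesthesia chart, nominally sampled every
5 minutes; the two minima need not be simultaneous.

Three boundary conventions deserve care, and are fixed here once:

* Printed ranges like "55–65" are closed at their printed endpoints, ">x"
  is strict, "≤x"/"≥x" inclusive. To cover *all* real-valued measurements
  (not just integers) each bin is half-opened toward its neighbour, e.g.
  MSAS EBL is [0,50], (50,150], (150,300], (300,∞).
* The HR column prints both "≤55" (4 points) and "55–65" (3 points); 55 is
  awarded 4 points, i.e. the 3-point bin is effectively (55, 65], matching
  the original score's convention.
* EBL exactly 300 mL earns 1 point under the MSAS **and** constitutes a
  bleeding complication: the complication rule "≥300 mL" is inclusive
  while the 0-point bin ">300" is strict. The two printed rules disagree
  only on this boundary and the package follows both literally rather than
  harmonizing them.

Rubrics are data objects (`score_rubric()`), not hard-coded branching, so
alternative cutoff systems — e.g. the classic low-SAS ≤ 4 dichotomy used
after open surgery — are one YAML file away. The dichotomization used here
is MSAS ≤ 6 ("low"), and the three-level stratification is 7–10 low,
5–6 moderate, 0–4 high risk; moderate and high together are exactly the
low-score group, and both partitions are validated against each other in
the tests.

## Complication coding

Events are coded, not inferred: the package's taxonomy has four
intraoperative codes (bleeding ≥ 300 mL, transfusion within 72 h, bowel
injury, bladder/ureter injury) and eleven postoperative ones (fever
> 37.8 °C lasting > 24 h, urinary distention, ileus, vault bleeding,
readmission < 30 days, lymphedema, dysrhythmia, nerve palsy, wound
dehiscence, fistula, peritonitis). Clavien–Dindo grades are derived from
the intensity of treatment required (none/bedside → I, drugs → II,
intervention → III, ICU/life-threatening → IV, death → V); grades IIIa and
IIIb are not distinguished. Tabulations use two denominators deliberately:
per-code percentages divide by the number of *patients*, per-grade
percentages by the number of *complications*, so the grade column sums to
100 %. Patient-level flags (any / intraoperative / postoperative / both)
count each patient once and satisfy the inclusion–exclusion identity
`n(both) = n(intra) + n(post) − n(any)`.

## Statistics

All tests are implemented from their defining formulas, with base R's
implementations serving as independent cross-checks in the test suite:

* **Pearson chi-square (2×2)** without continuity correction by default —
  the statistic most plausibly reported by SPSS-based clinical analyses —
  with a flag for the Yates correction.
* **Fisher's exact test**, two-sided by the "sum of hypergeometric
  probabilities ≤ the observed table's" convention (the SPSS/R convention,
  not the doubling convention), with a 1 + 1e−7 relative tolerance for
  floating-point ties.
* **Linear-by-linear association** (Mantel–Haenszel trend):
  M² = (N−1)·r² where r is the Pearson correlation between row score and
  outcome indicator over all N subjects, on 1 df. Default stratum scores
  are 1, 2, 3 (low/moderate/high); since the p-value is invariant under
  affine rescaling of scores, this choice is innocuous. On a 2-row table
  M² equals (N−1)/N times the Pearson chi-square, an identity the tests
  verify numerically.
* **Odds ratios** are crude (a·d)/(b·c) with Woolf log-normal 95 %
  intervals; when any cell is zero the Haldane–Anscombe 0.5 correction is
  applied to all four cells and flagged. No adjusted or regression-based
  OR is computed.
* **Student's t** is the pooled-variance two-sample test.
* The **chi-square/Fisher selector** uses the minimum-expected-count < 5
  rule of thumb, and every selection is recorded in the report.

p-values are kept at full precision internally; `format_p()` reproduces
the usual display style ("< 0.001", otherwise two decimals).

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` emulates
the *shape* of a single-center robotic-assisted radical
hysterectomy/trachelectomy cohort of 138 cervical-cancer patients, which
is the default configuration of `sim_config()`:

* **Covariates** are independent Normals/Bernoullis at the published
  marginal moments (age 44.1 ± 10.1 y, BMI 22.9 ± 3.0 kg/m², surgical time
  190 ± 70.9 min truncated to [60, 480], preoperative Hb 13.0 ± 1.2 g/dL;
  trachelectomy fraction 21/138, neoadjuvant-chemotherapy fraction 7/138).
  No correlation structure between covariates was published, so
  independence is assumed and stated here.
* **Vitals** are independent stationary AR(1) processes (coefficient 0.8)
  around patient-specific Normal baselines (MAP 78 ± 7 mmHg, HR
  70 ± 8 bpm; innovation SDs 6 and 5), sampled every 5 min over the drawn
  surgical time and floored at physiologic bounds (MAP ≥ 20, HR ≥ 30; the
  floor is applied to the recorded value, the latent state evolves
  untruncated). Distribution families — Normal covariates, log-normal EBL,
  AR(1) vitals, logistic event links — are the generator's own modelling
  choices, made for simplicity and closed-form checkability.
* **EBL** is log-normal with median 100 mL and log-SD 0.93, putting
  P(EBL ≥ 300) ≈ 0.119, near the published 16/138 bleeding prevalence; the
  tests compare the simulated rate against this closed-form tail.
* **Complications**: EBL ≥ 300 mL *is* a bleeding event (the definitional
  coupling; disabling it substitutes an independent Bernoulli of the same
  marginal rate, the null configuration for type-I calibration).
  Transfusion is Bernoulli with logit −2.8 + 1.0·(6.5 − MSAS) — centering
  at 6.5 puts nontrivial signal at cohort-scale n; organ injuries are rare
  independent Bernoullis (1/138 each); a postoperative event occurs with
  logit −0.95 + 0.35·(time − 190)/70.9 + 0.15·(6.5 − MSAS) (at most one
  per patient) and its code is drawn from the published postoperative
  frequency profile. Each event's Clavien grade is multinomial
  (0.731, 0.194, 0.075, 0, 0) — grades IV/V have probability 0 by default
  but are configurable.

The vitals baselines and the two intercepts were calibrated once, by
simulation at n = 20 000, so that the MSAS mean lands near 6.9, the
low-score fraction near 0.36 (target 52/138 ≈ 0.38), intraoperative
prevalence near 0.18 (target 27/138 ≈ 0.20) and postoperative prevalence
near 0.27 (target 38/138). The transfusion and intraoperative targets pull
against each other — the published cohort had almost no overlap between
bleeders and transfusions, whereas the logistic link induces some — so the
defaults split the difference.

The generator reproduces stated marginals and the score–outcome link, and
nothing more. Real anesthesia charts have artifacts (cuff errors, gaps,
induction/emergence transients), covariate correlations, and
surgeon/period effects that it does not emulate; passing tests therefore
validate the *pipeline's arithmetic and inference machinery*, not any
clinical claim about real data.

## Printed-table entry point and known inconsistencies

`analyze_count_table()` analyzes published count tables as given,
bypassing cohort-level consistency checks. This matters because the
emulated study's printed tables are not mutually consistent: its
stratified panel has 15/90/33 patients per stratum while its dichotomized
table has 52 patients with MSAS ≤ 6 (moderate + high should equal that
group, but 90 + 33 = 123 ≠ 52); its abstract reports "1 (1.2%) vs
21 (40.4%)" where the table prints 1 vs 26 (50 %); and several printed
percentages do not match their own fractions. The package reproduces each
printed table as given and does not guess which figure was intended —
cohort-level invariants are asserted only on program-generated cohorts.
Likewise the published OR of 3.57 for intraoperative complications cannot
be derived from the printed 2×2 counts (which give a crude OR of 85); the
pipeline computes and labels **crude** ORs only.

## Numerical and degenerate-input behavior

Zero-variance situations refuse loudly rather than return NaN: a zero
marginal makes the chi-square error, constant groups make the pooled t
error, and an all-events or no-events column makes the trend test error —
the pipeline catches these and reports "not computable" with the reason.
Records missing EBL or vitals minima are rejected by `score_cohort()`
naming the patient, mirroring the exclusion of incomplete records in
chart-review practice. Vitals minima use available samples only (no
imputation), warning below 3 samples; no artifact-cleaning rule is applied
because none was published.

## Problem sizes

The test suite exercises exhaustive rubric grids (EBL 0–1200 × MAP
30–120 × HR 40–120, per component), Fisher-vs-enumeration on margins ≤ 30,
and the generator's power/type-I study at n = 5000 with 200 replicates per
arm — sizes chosen so the full suite runs in about a minute on a single
core while keeping Monte-Carlo error on the type-I rate near 1.5
percentage points. Re-running `run_analysis()` on a fixed cohort is
bit-identical; every random draw in the package flows from an explicit
seed.

## Limitations

The package does not adjudicate complications from clinical notes, fit
multivariable or logistic models, adjust for multiple testing (the
emulated analysis applied none), or interface with EHR formats; those are
out of scope by design.
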