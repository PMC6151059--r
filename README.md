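# msas

Intraoperative risk scoring and perioperative complication analysis for
minimally invasive gynecologic surgery.

## The problem

The surgical Apgar score (SAS) is a 10-point intraoperative risk score built
from three quantities every anesthesia and surgical record already contains:
estimated blood loss (EBL, mL), the lowest mean arterial pressure (MAP,
mmHg) and the lowest heart rate (HR, beats/min) during surgery. Each
component is binned and awarded points (EBL and MAP up to 3, HR up to 4);
the total runs from 0 (worst) to 10 (best). Because robotic-assisted
surgery loses far less blood than open surgery, the original EBL bins are
nearly uninformative there; the *modified* SAS (MSAS) compresses them to
≤50 / 51–150 / 151–300 / >300 mL while keeping the MAP and HR components.

| Points | 0 | 1 | 2 | 3 | 4 |
|---|---|---|---|---|---|
| EBL, SAS (mL) | >1000 | 601–1000 | 101–600 | ≤100 | — |
| EBL, MSAS (mL) | >300 | 151–300 | 51–150 | ≤50 | — |
| Lowest MAP (mmHg) | <40 | 40–54 | 55–69 | ≥70 | — |
| Lowest HR (bpm) | >85 | 76–85 | 66–75 | 55–65 | ≤55 |

This package computes both scores, dichotomizes (MSAS ≤ 6 is the low-score
group) and risk-stratifies them (7–10 low, 5–6 moderate, 0–4 high risk),
codes perioperative complications into an intraoperative/postoperative
taxonomy with Clavien–Dindo grades, and runs the associated statistics:
Pearson chi-square and Fisher's exact test for 2×2 tables, crude odds
ratios with Woolf confidence intervals, pooled-variance t-tests, and the
linear-by-linear association (Mantel–Haenszel trend) test
M² = (N−1)·r² for ordered score strata against a binary outcome. A seeded
synthetic-cohort generator emulates a 138-patient robotic-assisted radical
hysterectomy cohort so the full pipeline is testable without patient data.

Intended users: biostatisticians and surgical-outcomes researchers who want
a scripted, reproducible version of this analysis for their own cohorts.

## Worked example

```r
library(msas)

# Score one case: EBL 200 mL, lowest MAP 60 mmHg, lowest HR 70 bpm
compute_score(200, 60, 70)
#>   rubric ebl_points map_points hr_points total
#> 1 MSAS            1          2         2     5

# A seeded synthetic cohort, analyzed end to end
co  <- generate_cohort(sim_config(seed = 7))
rep <- run_analysis(co)
print(rep)
#> == Cohort ==
#> Patients: 138  (low MSAS <= 6: 42; MSAS > 6: 96)
#> Risk strata: low 96 / moderate 36 / high 6
#> ...
#> == Risk-stratified trend (linear-by-linear) ==
#>   perioperative: low 22/96 (22.9%), moderate 22/36 (61.1%), high 5/6 (83.3%)
#>     M^2 = 22.395, p = < 0.001
#>   intraoperative: low 4/96 (4.2%), moderate 14/36 (38.9%), high 4/6 (66.7%)
#>     M^2 = 35.218, p = < 0.001
```

The trend panel reads: within each risk stratum, the fraction of patients
with the outcome, then the trend statistic testing whether that fraction
changes monotonically across strata. In this simulated cohort the
intraoperative complication rate climbs steeply as the score falls, which
is exactly the mechanism the generator builds in (transfusion risk rises as
the MSAS drops, and EBL ≥ 300 mL is *by definition* a bleeding
complication).

Published tables given only as counts can be analyzed directly:

```r
tab <- contingency_table(c("low", "moderate", "high"),
                         events = c(0, 15, 10), nonevents = c(15, 75, 23))
analyze_count_table(tab)$trend$p.value
#> [1] 0.009872551
```

## Cohort CSV schema

`read_cohort()`/`write_cohort()` use one row per patient with header
`patient_id, age_years, bmi_kg_m2, underlying_disease,
previous_pelvic_surgery, nac, procedure, surgical_time_min, preop_hb_g_dl,
postop_hb_g_dl, ebl_ml, lowest_map_mmhg, lowest_hr_bpm, events`; `events`
is a semicolon-separated list of `code:treatment_level` tokens (see
`complication_codes()` and `grade_clavien()`). An optional companion vitals
file (`patient_id,time_min,map_mmHg,hr_bpm`, charted every 5 min) supplies
the series from which the minima are computed when they are not
precomputed. Example fixtures live in `inst/extdata/` (synthetic, generated
by this package). Units are fixed: mL, mmHg, beats/min, minutes, g/dL.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "msas", package = "msas"))')
Rscript $CLI score --ebl 200 --map 60 --hr 70
Rscript $CLI simulate --n 138 --seed 7 --out cohort.csv --vitals vitals.csv
Rscript $CLI analyze --cohort cohort.csv --vitals vitals.csv --format json
Rscript $CLI tables --counts counts.csv     # header: label,score,events,nonevents
```

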