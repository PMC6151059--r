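Package: msas
Title: Modified Surgical Apgar Score and Perioperative Complication Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the surgical Apgar score (SAS) and its modified variant
    (MSAS) for minimally invasive surgery from intraoperative estimated blood
    loss, lowest mean arterial pressure, and lowest heart rate; codes
    perioperative complications into an intraoperative/postoperative taxonomy
    with Clavien-Dindo grades; and runs the associated contingency-table
    analyses (Pearson chi-square, Fisher's exact test, Woolf odds ratios,
    pooled-variance t-tests, and the linear-by-linear association trend test).
    Includes a seeded synthetic-cohort generator emulating a robotic-assisted
    radical hysterectomy cohort, CSV cohort input/output, and an analysis
    pipeline producing a structured, renderable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
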