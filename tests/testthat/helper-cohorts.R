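# Deterministic cohort builders used across the suite. No file fixtures:
# everything is constructed in code.

# Minimal valid patients table; measurement columns recycled, covariates
# given mild deterministic variation so group comparisons are computable.
make_patients <- function(n, ebl = 100, map = 75, hr = 70) {
  tibble::tibble(
    patient_id = sprintf("S%04d", seq_len(n)),
    age_years = 44 + (seq_len(n) %% 7) - 3,
    bmi_kg_m2 = 23 + (seq_len(n) %% 5) / 2 - 1,
    underlying_disease = (seq_len(n) %% 6) == 0,
    previous_pelvic_surgery = (seq_len(n) %% 3) == 0,
    nac = (seq_len(n) %% 20) == 0,
    procedure = ifelse((seq_len(n) %% 7) == 0, "radical_trachelectomy",
                       "radical_hysterectomy"),
    surgical_time_min = 150 + 2 * (seq_len(n) %% 40),
    preop_hb_g_dl = 12 + (seq_len(n) %% 4) / 2,
    postop_hb_g_dl = 11.5 + (seq_len(n) %% 4) / 2,
    ebl_ml = rep_len(ebl, n),
    lowest_map_mmhg = rep_len(map, n),
    lowest_hr_bpm = rep_len(hr, n)
  )
}

make_events <- function(patient_id, code, treatment = "none_or_bedside") {
  n <- max(length(patient_id), length(code), length(treatment))
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    code = rep_len(code, n),
    treatment_level = rep_len(treatment, n),
    grade = msas::grade_clavien(rep_len(treatment, n))
  )
}

# 138-patient cohort engineered to the published complication structure:
# 67 events (49 grade I, 13 II, 5 III) in 53 patients; 27 intraoperative,
# 38 postoperative, 12 both; 16 bleeding events (EBL >= 300).
complication_shaped_cohort <- function() {
  p <- make_patients(138)
  # patients 1..16 bleed; patient 1 also receives transfusion
  p$ebl_ml[1:16] <- 400
  ev <- dplyr::bind_rows(
    make_events(sprintf("S%04d", 1:16), "bleeding_ge_300"),
    make_events(sprintf("S%04d", c(1, 17:25)), "transfusion_72h",
                "pharmacological"),
    make_events("S0026", "bowel_injury", "intervention"),
    make_events("S0027", "bladder_ureter_injury", "intervention")
  )
  # 38 postoperative patients: 12 of the intraoperative ones + 26 new.
  post_ids <- sprintf("S%04d", c(1:12, 28:53))
  post_codes <- c(rep("fever_gt_24h", 17), rep("urinary_distention", 6),
                  rep("ileus", 3), rep("vault_bleeding", 2),
                  rep("readmission_30d", 2), rep("lymphedema", 2),
                  rep("dysrhythmia", 2), rep("nerve_palsy", 2),
                  "wound_dehiscence", "fistula", "peritonitis")
  # 39 postoperative events for 38 patients: the first patient gets two.
  post_pid <- c(post_ids[1L], post_ids)
  post_treat <- rep("none_or_bedside", 39)
  post_treat[post_codes %in% c("fistula", "peritonitis", "vault_bleeding")
             & !duplicated(post_codes)] <- "intervention"
  post_treat[post_codes == "fever_gt_24h"][1:3] <- "pharmacological"
  ev <- dplyr::bind_rows(ev, make_events(post_pid, post_codes, post_treat))
  msas::msas_cohort(p, events = ev)
}

# 138-patient cohort whose risk strata and outcomes match the published
# stratified panel: strata 15/90/33; intraoperative events 0/15/10;
# perioperative events 7/32/14.
strata_shaped_cohort <- function() {
  p <- make_patients(138)
  set_meas <- function(p, idx, ebl, map, hr) {
    p$ebl_ml[idx] <- ebl; p$lowest_map_mmhg[idx] <- map
    p$lowest_hr_bpm[idx] <- hr; p
  }
  lo <- 1:15; mo <- 16:105; hi <- 106:138
  p <- set_meas(p, lo, 50, 70, 70)    # MSAS 3+3+2 = 8 -> low risk
  p <- set_meas(p, mo, 200, 60, 60)   # MSAS 1+2+3 = 6 -> moderate
  p <- set_meas(p, hi, 200, 50, 80)   # MSAS 1+1+1 = 3 -> high
  p <- set_meas(p, 106:115, 400, 50, 70)  # MSAS 0+1+2 = 3, bleeders
  ev <- dplyr::bind_rows(
    make_events(p$patient_id[1:7], "fever_gt_24h"),            # low: 7 peri
    make_events(p$patient_id[16:30], "transfusion_72h",
                "pharmacological"),                            # moderate intra
    make_events(p$patient_id[31:47], "fever_gt_24h"),          # moderate post
    make_events(p$patient_id[106:115], "bleeding_ge_300"),     # high intra
    make_events(p$patient_id[116:119], "fever_gt_24h")         # high post
  )
  msas::msas_cohort(p, events = ev)
}

# Brute-force interval-scan oracle for bin lookup: scalar loop, no reuse
# of score_component's vectorized masks.
naive_points <- function(value, bins) {
  for (i in seq_len(nrow(bins))) {
    lo_ok <- if (bins$min_incl[i]) value >= bins$min[i] else value > bins$min[i]
    hi_ok <- if (bins$max_incl[i]) value <= bins$max[i] else value < bins$max[i]
    if (lo_ok && hi_ok) return(bins$points[i])
  }
  NA_integer_
}

# Enumeration oracle for Fisher's exact test: walk every table with the
# observed margins, probability from the log-factorial formula.
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  n <- r1 + r2
  logp <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(-Inf)
    (lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
       lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
       lfactorial(d))
  }
  p_obs <- logp(m[1, 1])
  total <- 0
  for (a in 0:min(r1, c1)) {
    lp <- logp(a)
    if (is.finite(lp) && lp <= p_obs + 1e-7) total <- total + exp(lp)
  }
  min(1, total)
}
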