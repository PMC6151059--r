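test_that("vitals series have the 5-minute grid and respect the seed", {
  cfg <- sim_config()
  set.seed(1)
  v <- generate_vitals(60, cfg)
  expect_equal(nrow(v), 13L)
  expect_equal(v$time_min, seq(0, 60, by = 5))
  set.seed(33)
  a <- generate_vitals(200, cfg)
  set.seed(33)
  b <- generate_vitals(200, cfg)
  expect_identical(a, b)
  expect_error(generate_vitals(0, cfg), "positive")
  expect_error(generate_vitals(-5, cfg), "positive")
})

test_that("zero innovation variance gives a constant series at baseline", {
  cfg <- sim_config(map_innov_sd = 0, hr_innov_sd = 0)
  set.seed(2)
  v <- generate_vitals(100, cfg, baseline_map = 80, baseline_hr = 66)
  expect_true(all(v$map_mmHg == 80))
  expect_true(all(v$hr_bpm == 66))
})

test_that("the default configuration carries the published targets", {
  cfg <- sim_config()
  expect_equal(cfg$age_mean, 44.1)
  expect_equal(cfg$bmi_mean, 22.9)
  expect_equal(cfg$time_mean, 190.0)
  expect_equal(cfg$time_sd, 70.9)
  expect_equal(cfg$sampling_interval_min, 5)
  expect_equal(unname(cfg$grade_probs), c(0.731, 0.194, 0.075, 0, 0))
  expect_equal(cfg$n_patients, 138L)
  expect_error(sim_config(n_patients = 0), "positive integer")
  expect_error(sim_config(grade_probs = c(1, 1, 0, 0, 0)), "probability")
  expect_error(sim_config(ar_coef = 1), "phi")
})

test_that("the same seed yields a byte-identical cohort CSV", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  write_cohort(generate_cohort(sim_config(n_patients = 40, seed = 77)), f1)
  write_cohort(generate_cohort(sim_config(n_patients = 40, seed = 77)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  write_cohort(generate_cohort(sim_config(n_patients = 40, seed = 78)), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("dropping the vitals table changes no other draw", {
  a <- generate_cohort(sim_config(n_patients = 30, seed = 4), keep_vitals = TRUE)
  b <- generate_cohort(sim_config(n_patients = 30, seed = 4),
                       keep_vitals = FALSE)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_null(b$vitals)
})

test_that("stored minima equal the minima of the stored series", {
  co <- generate_cohort(sim_config(n_patients = 20, seed = 6))
  for (pid in co$patients$patient_id) {
    v <- co$vitals[co$vitals$patient_id == pid, ]
    expect_equal(co$patients$lowest_map_mmhg[co$patients$patient_id == pid],
                 min(v$map_mmHg))
    expect_equal(co$patients$lowest_hr_bpm[co$patients$patient_id == pid],
                 min(v$hr_bpm))
  }
})

test_that("switching every intraoperative mechanism off silences events", {
  cfg <- sim_config(n_patients = 200, seed = 8,
                    transfusion_intercept = -30, transfusion_slope = 0,
                    organ_injury_prob = 0,
                    ebl_median = 50, ebl_log_sd = 0.01)
  co <- generate_cohort(cfg, keep_vitals = FALSE)
  timing <- classify_event(co$events$code)
  expect_equal(sum(timing == "intraoperative"), 0L)
})

test_that("bleeding events track the log-normal EBL tail", {
  cfg <- sim_config(n_patients = 5000, seed = 12)
  co <- generate_cohort(cfg, keep_vitals = FALSE)
  # definitional coupling: every EBL >= 300 has a bleeding event and no other
  bleeders <- co$patients$patient_id[co$patients$ebl_ml >= 300]
  coded <- co$events$patient_id[co$events$code == "bleeding_ge_300"]
  expect_setequal(coded, bleeders)
  # empirical rate within 3 Monte-Carlo SEs of the closed-form tail
  p_true <- 1 - plnorm(300, log(cfg$ebl_median), cfg$ebl_log_sd)
  p_hat <- length(bleeders) / cfg$n_patients
  se <- sqrt(p_true * (1 - p_true) / cfg$n_patients)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("default marginals sit near the emulated cohort's shape", {
  co <- generate_cohort(sim_config(n_patients = 5000, seed = 21),
                        keep_vitals = FALSE)
  p <- score_cohort(co)
  expect_gt(mean(p$msas), 6.4)
  expect_lt(mean(p$msas), 7.2)
  expect_gt(mean(p$low_msas), 0.25)
  expect_lt(mean(p$low_msas), 0.50)
  expect_equal(mean(p$age_years), 44.1, tolerance = 0.05)
  expect_equal(sd(p$age_years), 10.1, tolerance = 0.05)
})
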