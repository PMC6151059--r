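test_that("component bins reproduce the printed rubric values", {
  msas <- msas_rubric()
  sas <- sas_rubric()
  # EBL, modified rubric: <=50 / 51-150 / 151-300 / >300
  expect_identical(score_component(c(0, 50, 51, 150, 151, 300, 300.5, 1e6),
                                   msas$ebl_bins),
                   c(3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L))
  # EBL, original rubric: <=100 / 101-600 / 601-1000 / >1000
  expect_identical(score_component(c(100, 101, 600, 601, 1000, 1001),
                                   sas$ebl_bins),
                   c(3L, 2L, 2L, 1L, 1L, 0L))
  # MAP shared: <40 / 40-54 / 55-69 / >=70
  expect_identical(score_component(c(39.9, 40, 54, 54.9, 55, 69, 70, 120),
                                   msas$map_bins),
                   c(0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  # HR shared: <=55 wins the printed 55 overlap; 55-65 reads (55, 65]
  expect_identical(score_component(c(30, 55, 55.5, 65, 65.5, 75, 76, 85, 86),
                                   msas$hr_bins),
                   c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L, 0L))
})

test_that("compute_score sums components and hits the documented examples", {
  expect_equal(compute_score(50, 70, 55)$total, 10L)
  expect_equal(compute_score(400, 35, 90)$total, 0L)
  res <- compute_score(200, 60, 70)
  expect_equal(unlist(res[c("ebl_points", "map_points", "hr_points")],
                      use.names = FALSE), c(1L, 2L, 2L))
  expect_equal(res$total, 5L)
  # non-integer measurements are fine, scores stay integer
  expect_type(compute_score(150.5, 69.9, 65.01)$total, "integer")
})

test_that("invalid measurements error", {
  expect_error(compute_score(-1, 70, 70), "outside")
  expect_error(compute_score(100, 0, 70), "outside")
  expect_error(compute_score(100, 70, -5), "outside")
  expect_error(compute_score(NA, 70, 70), "missing")
})

test_that("extract_minima takes elementwise minima over the series", {
  v <- tibble::tibble(time_min = c(0, 5, 10), map_mmHg = c(80, 65, 70),
                      hr_bpm = c(72, 68, 75))
  expect_equal(extract_minima(v), list(lowest_map = 65, lowest_hr = 68))
  expect_warning(
    m1 <- extract_minima(tibble::tibble(time_min = 0, map_mmHg = 90,
                                        hr_bpm = 60)),
    "fewer than 3")
  expect_equal(m1, list(lowest_map = 90, lowest_hr = 60))
  expect_error(extract_minima(v[0, ]), "empty")
  expect_error(extract_minima(v[c(1, 1), ]), "strictly increasing")
})

test_that("planted minima in a long series are recovered", {
  # 40 samples; minima planted at different times (MAP at t=35, HR at t=120)
  times <- seq(0, by = 5, length.out = 40)
  map <- 70 + (seq_len(40) %% 9)
  hr <- 68 + (seq_len(40) %% 7)
  map[times == 35] <- 52
  hr[times == 120] <- 58
  v <- tibble::tibble(time_min = times, map_mmHg = map, hr_bpm = hr)
  got <- extract_minima(v)
  expect_equal(got$lowest_map, min(map))
  expect_equal(got$lowest_hr, min(hr))
  expect_equal(got, list(lowest_map = 52, lowest_hr = 58))
})

test_that("dichotomization and stratification agree on every total", {
  expect_true(is_low_msas(6L))
  expect_false(is_low_msas(7L))
  expect_true(is_low_msas(0L))
  expect_equal(as.character(stratify_risk(c(5, 10, 4))),
               c("moderate", "low", "high"))
  totals <- 0:10
  strat <- stratify_risk(totals)
  low_flag <- is_low_msas(totals)
  expect_true(all(low_flag[strat %in% c("moderate", "high")]))
  expect_true(all(!low_flag[strat == "low"]))
  # exhaustive and mutually exclusive partition
  expect_false(anyNA(strat))
  expect_error(is_low_msas(11), "0, 10")
  expect_error(stratify_risk(-1), "0, 10")
})

test_that("totals stay in 0-10 and are monotone in EBL and MAP", {
  set.seed(71)
  ebl <- runif(300, 0, 1500)
  map <- runif(300, 25, 130)
  hr <- runif(300, 35, 130)
  for (r in list(sas_rubric(), msas_rubric())) {
    tot <- compute_score(ebl, map, hr, r)$total
    expect_true(all(tot >= 0 & tot <= 10))
    # more bleeding never raises the score; higher MAP never lowers it
    expect_true(all(compute_score(ebl + 100, map, hr, r)$total <= tot))
    expect_true(all(compute_score(ebl, pmin(map + 10, 200), hr, r)$total >= tot))
  }
})

test_that("the two rubrics differ only in the EBL component", {
  set.seed(72)
  map <- runif(200, 25, 130)
  hr <- runif(200, 35, 130)
  ebl <- runif(200, 0, 1500)
  a <- compute_score(ebl, map, hr, sas_rubric())
  b <- compute_score(ebl, map, hr, msas_rubric())
  expect_equal(a$map_points, b$map_points)
  expect_equal(a$hr_points, b$hr_points)
})

test_that("vectorized bin lookup agrees with a scalar interval scan", {
  for (r in list(sas_rubric(), msas_rubric())) {
    for (comp in c("ebl_bins", "map_bins", "hr_bins")) {
      grid <- c(seq(0.5, 120, by = 1.7), seq(120, 1250, by = 13.3))
      bins <- r[[comp]]
      expect_identical(score_component(grid, bins),
                       vapply(grid, naive_points, integer(1L), bins = bins))
    }
  }
})

test_that("rubrics round-trip through YAML and match the bundled files", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_rubric(msas_rubric(), tmp)
  expect_equal(read_rubric(tmp), msas_rubric())
  for (nm in c("sas", "msas")) {
    bundled <- system.file("extdata", paste0("rubric_", nm, ".yaml"),
                           package = "msas")
    expect_equal(read_rubric(bundled), as_rubric(nm))
  }
})

test_that("as_rubric resolves names and rejects unknowns", {
  expect_equal(as_rubric("SAS")$name, "SAS")
  expect_error(as_rubric("apgar"), "unknown rubric")
  # malformed rubric: overlapping bins
  bad <- msas_rubric()
  expect_error(
    score_rubric("bad", bad$ebl_bins[c(1, 1, 2, 3, 4), ], bad$map_bins,
                 bad$hr_bins),
    "contiguous")
})
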