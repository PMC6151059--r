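test_that("2x2 chi-square matches hand computation and base R", {
  # dichotomized-score table: (events/nonevents) = (1/85) vs (26/26)
  m <- rbind(c(1, 85), c(26, 26))
  res <- chi_square_2x2(m)
  expect_equal(unname(res$statistic), 49.11293, tolerance = 1e-6)
  expect_lt(res$p.value, 0.001)
  # identical proportions: no association
  flat <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)
  # cross-check against the independent base-R implementation
  set.seed(11)
  for (i in 1:25) {
    mm <- matrix(sample(1:40, 4, replace = TRUE), 2)
    for (correct in c(FALSE, TRUE)) {
      ref <- suppressWarnings(stats::chisq.test(mm, correct = correct))
      got <- chi_square_2x2(mm, correct = correct)
      expect_equal(unname(got$statistic), unname(ref$statistic),
                   tolerance = 1e-12)
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("chi-square is invariant under transposition and double swap", {
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    s0 <- unname(chi_square_2x2(m)$statistic)
    expect_equal(unname(chi_square_2x2(t(m))$statistic), s0)
    expect_equal(unname(chi_square_2x2(m[2:1, 2:1])$statistic), s0)
  }
})

test_that("Fisher exact p-values match enumeration and base R", {
  expect_equal(fisher_exact_2x2(rbind(c(2, 3), c(3, 2)))$p.value, 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p.value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(0, 5), c(0, 5)))$p.value, 1)
  set.seed(13)
  for (i in 1:30) {
    m <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    got <- fisher_exact_2x2(m)$p.value
    expect_equal(got, fisher_enum_p(m), tolerance = 1e-10)
    expect_equal(got, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("trend test reproduces the published stratified p-values", {
  intra <- contingency_table(c("low", "moderate", "high"),
                             events = c(0, 15, 10), nonevents = c(15, 75, 23))
  peri <- contingency_table(c("low", "moderate", "high"),
                            events = c(7, 32, 14), nonevents = c(8, 58, 19))
  p_intra <- linear_by_linear(intra)$p.value
  p_peri <- linear_by_linear(peri)$p.value
  expect_equal(p_intra, 0.0098726, tolerance = 1e-4)
  expect_equal(round(p_intra, 2), 0.01)
  expect_equal(round(p_peri, 2), 0.98)
  # zero correlation: identical proportions in every stratum
  flat <- linear_by_linear(cbind(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)
  expect_error(linear_by_linear(cbind(c(5, 5), c(0, 0))), "zero variance")
})

test_that("two-row trend equals (N-1)/N times the Pearson chi-square", {
  set.seed(14)
  for (i in 1:40) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    n <- sum(m)
    expect_equal(unname(linear_by_linear(m)$statistic),
                 (n - 1) / n * unname(chi_square_2x2(m)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("trend p is invariant under affine rescaling of the scores", {
  m <- cbind(c(0, 15, 10), c(15, 75, 23))
  p0 <- linear_by_linear(m, scores = c(1, 2, 3))$p.value
  expect_equal(linear_by_linear(m, scores = c(10, 30, 50))$p.value, p0,
               tolerance = 1e-12)
  expect_equal(linear_by_linear(m, scores = c(-3, -5, -7))$p.value, p0,
               tolerance = 1e-12)
})

test_that("odds ratios use Woolf intervals and the Haldane correction", {
  expect_equal(odds_ratio_2x2(rbind(c(10, 10), c(10, 10)))$estimate, 1)
  expect_equal(odds_ratio_2x2(rbind(c(20, 10), c(10, 20)))$estimate, 4)
  # crude OR from the dichotomized intraoperative table
  or <- odds_ratio_2x2(rbind(c(26, 26), c(1, 85)))
  expect_equal(or$estimate, 85)
  expect_false(or$corrected)
  expect_true(or$conf_low <= or$estimate && or$estimate <= or$conf_high)
  zero <- odds_ratio_2x2(rbind(c(5, 0), c(2, 3)))
  expect_true(zero$corrected)
  set.seed(15)
  for (i in 1:30) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(odds_ratio_2x2(m[2:1, ])$estimate,
                 1 / odds_ratio_2x2(m)$estimate, tolerance = 1e-12)
  }
})

test_that("pooled t-test matches the base-R reference to 1e-10", {
  same <- c(1, 2, 3, 4)
  res <- students_t(same, same)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  expect_error(students_t(rep(0, 4), rep(1, 4)), "pooled variance")
  set.seed(16)
  a <- rnorm(50, 190, 70.9)
  b <- rnorm(50, 221, 90)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  got <- students_t(a, b)
  expect_equal(unname(got$statistic), unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(got$parameter), 98)
})

test_that("test selector applies the minimum-expected-count rule", {
  sel <- test_selector(rbind(c(1, 85), c(26, 26)))
  expect_equal(as.character(sel), "chi_square")
  expect_equal(attr(sel, "min_expected"), 27 * 52 / 138, tolerance = 1e-12)
  expect_equal(as.character(test_selector(rbind(c(1, 5), c(2, 4)))), "fisher")
  expect_equal(as.character(test_selector(rbind(c(50, 50), c(50, 50)))),
               "chi_square")
})

test_that("contingency tables validate and round-trip through CSV", {
  tab <- contingency_table(c("low", "moderate", "high"), c(0, 15, 10),
                           c(15, 75, 23))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_counts(tab, tmp)
  expect_equal(read_counts(tmp), tab)
  expect_error(contingency_table("one", 1, 2), "2 rows")
  expect_error(contingency_table(c("a", "b"), c(-1, 2), c(3, 4)),
               "non-negative")
  expect_error(contingency_table(c("a", "b"), c(1, 2), c(3, 4),
                                 score = c(1, 1)), "monotone")
})
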