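#' Score every patient in a cohort
#'
#' Adds per-patient score columns under both built-in rubrics (or a custom
#' one), the low-score (<= 6) flag, and the three-level risk stratum.
#'
#' @param cohort An [msas_cohort] or patients tibble with `ebl_ml`,
#'   `lowest_map_mmhg`, `lowest_hr_bpm`.
#' @param rubric Rubric used for the dichotomization and stratification;
#'   default MSAS.
#' @return The patients tibble with columns `msas` (total under `rubric`),
#'   `sas` (original rubric), `low_msas`, `risk_stratum` appended.
#' @export
score_cohort <- function(cohort, rubric = msas_rubric()) {
  cohort <- as_msas_cohort(cohort)
  rubric <- as_rubric(rubric)
  p <- cohort$patients
  miss <- is.na(p$ebl_ml) | is.na(p$lowest_map_mmhg) | is.na(p$lowest_hr_bpm)
  if (any(miss)) {
    stop("unscoreable record(s): patient ",
         paste(head(p$patient_id[miss], 5L), collapse = ", "),
         " missing EBL or vitals minima", call. = FALSE)
  }
  p$msas <- compute_score(p$ebl_ml, p$lowest_map_mmhg, p$lowest_hr_bpm,
                          rubric)$total
  p$sas <- compute_score(p$ebl_ml, p$lowest_map_mmhg, p$lowest_hr_bpm,
                         sas_rubric())$total
  p$low_msas <- is_low_msas(p$msas)
  p$risk_stratum <- stratify_risk(p$msas)
  p
}

# 2x2 outcome-by-group test via the selector; returns a one-row tibble.
run_2x2 <- function(events_g0, n_g0, events_g1, n_g1) {
  m <- rbind(c(events_g0, n_g0 - events_g0), c(events_g1, n_g1 - events_g1))
  sel <- test_selector(m)
  res <- tryCatch(
    if (sel == "fisher") fisher_exact_2x2(m) else chi_square_2x2(m),
    error = function(e) NULL
  )
  tibble::tibble(
    method = as.character(sel),
    min_expected = attr(sel, "min_expected"),
    statistic = if (!is.null(res) && !is.null(res$statistic))
      unname(res$statistic) else NA_real_,
    p_value = if (!is.null(res)) res$p.value else NA_real_,
    note = if (is.null(res)) "not computable" else NA_character_
  )
}

compare_continuous <- function(x, by, variable) {
  a <- x[!by]; b <- x[by]
  res <- tryCatch(students_t(a, b), error = function(e) e$message)
  tibble::tibble(
    variable = variable, type = "continuous",
    group0 = sprintf("%.1f (±%.1f)", mean(a, na.rm = TRUE),
                     stats::sd(a, na.rm = TRUE)),
    group1 = sprintf("%.1f (±%.1f)", mean(b, na.rm = TRUE),
                     stats::sd(b, na.rm = TRUE)),
    method = "students_t",
    p_value = if (is.character(res)) NA_real_ else res$p.value,
    note = if (is.character(res)) paste("not computable:", res)
    else NA_character_
  )
}

compare_binary <- function(x, by, variable) {
  n0 <- sum(!by); n1 <- sum(by)
  e0 <- sum(x[!by], na.rm = TRUE); e1 <- sum(x[by], na.rm = TRUE)
  t22 <- run_2x2(e0, n0, e1, n1)
  tibble::tibble(
    variable = variable, type = "categorical",
    group0 = sprintf("%d (%.1f)", e0, 100 * e0 / n0),
    group1 = sprintf("%d (%.1f)", e1, 100 * e1 / n1),
    method = t22$method,
    p_value = t22$p_value,
    note = if (!is.na(t22$note)) t22$note else NA_character_
  )
}

#' Run the full scoring-and-association analysis on a cohort
#'
#' Computes per-patient scores, summarizes complications with both
#' denominators, compares covariates between patients with and without
#' complications (pooled t for continuous, chi-square/Fisher per
#' [test_selector()] for categorical), repeats the comparison between the
#' low (<= 6) and high score groups including the three outcome classes,
#' reports crude odds ratios (Woolf CIs) of each outcome class for the low
#' score group, and runs the linear-by-linear trend test of each outcome
#' class across the three risk strata (scores 1, 2, 3 for low, moderate,
#' high risk). Cohorts whose recorded events contradict the EBL >= 300 mL
#' bleeding rule trigger a warning. Re-running on the same cohort is
#' bit-identical: nothing here is randomized.
#'
#' @param cohort An [msas_cohort].
#' @param rubric Scoring rubric (default MSAS).
#' @param trend_scores Ordinal scores for the low/moderate/high strata.
#' @return An object of class `msas_report`; see [render_report()].
#' @export
run_analysis <- function(cohort, rubric = msas_rubric(),
                         trend_scores = c(1, 2, 3)) {
  cohort <- as_msas_cohort(cohort)
  rubric <- as_rubric(rubric)
  p <- score_cohort(cohort, rubric)
  ev <- cohort$events
  n <- nrow(p)

  # Definitional coupling check (events are input, not inferred).
  bleed_ids <- ev$patient_id[ev$code == "bleeding_ge_300"]
  should_bleed <- p$patient_id[p$ebl_ml >= 300]
  if (!setequal(intersect(should_bleed, bleed_ids), should_bleed) ||
      length(setdiff(bleed_ids, should_bleed)) > 0L) {
    warning("recorded bleeding events are inconsistent with the ",
            "EBL >= 300 mL rule", call. = FALSE)
  }

  complication_summary <- summarize_complications(cohort)
  flags <- patient_event_flags(p, ev)

  by_comp <- flags$any
  covariates_by_complication <- dplyr::bind_rows(
    compare_continuous(p$age_years, by_comp, "age_years"),
    compare_continuous(p$bmi_kg_m2, by_comp, "bmi_kg_m2"),
    compare_binary(p$underlying_disease, by_comp, "underlying_disease"),
    compare_binary(p$previous_pelvic_surgery, by_comp,
                   "previous_pelvic_surgery"),
    compare_continuous(p$surgical_time_min, by_comp, "surgical_time_min"),
    compare_continuous(p$preop_hb_g_dl, by_comp, "preop_hb_g_dl"),
    compare_continuous(p$postop_hb_g_dl, by_comp, "postop_hb_g_dl"),
    compare_binary(p$nac, by_comp, "nac"),
    compare_binary(p$procedure == "radical_trachelectomy", by_comp,
                   "radical_trachelectomy"),
    compare_continuous(p$sas, by_comp, "sas"),
    compare_continuous(p$msas, by_comp, "msas")
  )

  by_low <- p$low_msas
  msas_group_comparison <- dplyr::bind_rows(
    compare_continuous(p$age_years, by_low, "age_years"),
    compare_continuous(p$bmi_kg_m2, by_low, "bmi_kg_m2"),
    compare_binary(p$underlying_disease, by_low, "underlying_disease"),
    compare_binary(p$previous_pelvic_surgery, by_low,
                   "previous_pelvic_surgery"),
    compare_binary(p$nac, by_low, "nac"),
    compare_binary(p$procedure == "radical_trachelectomy", by_low,
                   "radical_trachelectomy"),
    compare_continuous(p$preop_hb_g_dl, by_low, "preop_hb_g_dl"),
    compare_binary(flags$any, by_low, "perioperative_complications"),
    compare_binary(flags$intra, by_low, "intraoperative_complications"),
    compare_binary(flags$post, by_low, "postoperative_complications")
  )

  # Crude ORs: exposure = low score, outcome = complication class.
  or_panel <- dplyr::bind_rows(lapply(
    list(perioperative = flags$any, intraoperative = flags$intra,
         postoperative = flags$post),
    function(fl) {
      a <- sum(fl & by_low); b <- sum(!fl & by_low)
      c_ <- sum(fl & !by_low); d <- sum(!fl & !by_low)
      m <- rbind(c(a, b), c(c_, d))
      or <- tryCatch(odds_ratio_2x2(m), error = function(e) NULL)
      t22 <- run_2x2(a, a + b, c_, c_ + d)
      tibble::tibble(
        or_estimate = if (is.null(or)) NA_real_ else or$estimate,
        ci_low = if (is.null(or)) NA_real_ else or$conf_low,
        ci_high = if (is.null(or)) NA_real_ else or$conf_high,
        corrected = if (is.null(or)) NA else or$corrected,
        p_value = t22$p_value,
        p_method = t22$method,
        label = "crude"
      )
    }), .id = "outcome")

  # Risk-stratified trend panel.
  strata <- levels(p$risk_stratum)
  trend_tables <- dplyr::bind_rows(lapply(
    list(perioperative = flags$any, intraoperative = flags$intra),
    function(fl) {
      tibble::tibble(
        stratum = strata,
        n = as.integer(table(p$risk_stratum)[strata]),
        events = as.integer(tapply(fl, p$risk_stratum, sum)[strata])
      )
    }), .id = "outcome")
  trend_tables$events[is.na(trend_tables$events)] <- 0L
  trend_tables$fraction <- ifelse(trend_tables$n > 0,
                                  trend_tables$events / trend_tables$n, NA)
  trend_tests <- dplyr::bind_rows(lapply(
    split(trend_tables, trend_tables$outcome),
    function(tt) {
      m <- cbind(tt$events, tt$n - tt$events)
      res <- tryCatch(linear_by_linear(m, scores = trend_scores),
                      error = function(e) e$message)
      tibble::tibble(
        outcome = tt$outcome[1L],
        statistic = if (is.character(res)) NA_real_
        else unname(res$statistic),
        p_value = if (is.character(res)) NA_real_ else res$p.value,
        note = if (is.character(res)) paste("not computable:", res)
        else NA_character_
      )
    }))

  group_sizes <- list(
    n_patients = n,
    n_low_msas = sum(by_low),
    n_high_msas = sum(!by_low),
    strata = as.list(table(p$risk_stratum))
  )

  structure(
    list(
      n_patients = n,
      scored_patients = p,
      complication_summary = complication_summary,
      covariates_by_complication = covariates_by_complication,
      msas_group_comparison = msas_group_comparison,
      odds_ratios = or_panel,
      trend_tables = trend_tables,
      trend_tests = trend_tests,
      group_sizes = group_sizes,
      provenance = list(
        rubric = rubric$name,
        trend_scores = trend_scores,
        package_version = as.character(utils::packageVersion("msas")),
        seed = attr(cohort, "seed", exact = TRUE)
      )
    ),
    class = "msas_report"
  )
}

#' Analyze a printed count table directly
#'
#' Entry point for published tables given as counts, bypassing the
#' cohort-level consistency checks (printed tables are reproduced as given,
#' internal inconsistencies and all). For a 2-row table the chi-square /
#' Fisher selection and the crude odds ratio are reported alongside the
#' trend test; for 3 or more rows, per-row event fractions and the
#' linear-by-linear trend test.
#'
#' @param table A contingency table from [contingency_table()] or
#'   [read_counts()].
#' @return A list with `rows` (the table with `n` and `fraction` added),
#'   `trend` (`htest`), and for 2-row tables also `selected_test`,
#'   `test` (`htest`) and `odds_ratio`.
#' @examples
#' fig <- contingency_table(c("low", "moderate", "high"),
#'                          events = c(0, 15, 10), nonevents = c(15, 75, 23))
#' analyze_count_table(fig)$trend$p.value
#' @export
analyze_count_table <- function(table) {
  m <- as_counts_matrix(table)
  rows <- tibble::as_tibble(table)
  rows$n <- rows$events + rows$nonevents
  rows$fraction <- ifelse(rows$n > 0, rows$events / rows$n, NA)
  out <- list(rows = rows)
  out$trend <- tryCatch(linear_by_linear(m, scores = table$score),
                        error = function(e) e$message)
  if (nrow(m) == 2L) {
    sel <- test_selector(m)
    out$selected_test <- as.character(sel)
    out$test <- tryCatch(
      if (sel == "fisher") fisher_exact_2x2(m) else chi_square_2x2(m),
      error = function(e) e$message)
    out$odds_ratio <- tryCatch(odds_ratio_2x2(m),
                               error = function(e) e$message)
  }
  out
}
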