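#' Format a p-value for display
#'
#' Matches the usual clinical-journal style: `"< 0.001"` below 0.001,
#' otherwise two decimals (three when rounding to two would print 0.00).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    if (x < 0.001) return("< 0.001")
    two <- sprintf("%.2f", x)
    if (two == "0.00") sprintf("%.3f", x) else two
  }, character(1L))
}

# Canonical plain-list form of a report: only atomic vectors and lists, so
# it survives a JSON round trip losslessly.
as_report_list <- function(report) {
  stopifnot(inherits(report, "msas_report"))
  cs <- report$complication_summary
  df_as_list <- function(d) lapply(as.data.frame(d), function(col) {
    if (is.factor(col)) col <- as.character(col)
    # canonical plain form: missing strings become "", so an all-NA note
    # column keeps its type through a JSON round trip
    if (is.character(col)) col[is.na(col)] <- ""
    col
  })
  list(
    n_patients = report$n_patients,
    complication_summary = list(
      n_patients = cs$n_patients,
      n_events = cs$n_events,
      per_code = df_as_list(cs$per_code),
      per_grade = df_as_list(cs$per_grade),
      patient_flags = df_as_list(cs$patient_flags)
    ),
    covariates_by_complication = df_as_list(report$covariates_by_complication),
    msas_group_comparison = df_as_list(report$msas_group_comparison),
    odds_ratios = df_as_list(report$odds_ratios),
    trend_tables = df_as_list(report$trend_tables),
    trend_tests = df_as_list(report$trend_tests),
    group_sizes = list(
      n_patients = report$group_sizes$n_patients,
      n_low_msas = report$group_sizes$n_low_msas,
      n_high_msas = report$group_sizes$n_high_msas,
      strata = lapply(report$group_sizes$strata, as.integer)
    ),
    provenance = report$provenance
  )
}

render_text <- function(report) {
  cs <- report$complication_summary
  gs <- report$group_sizes
  out <- character()
  add <- function(...) out <<- c(out, sprintf(...))

  add("== Cohort ==")
  add("Patients: %d  (low MSAS <= 6: %d; MSAS > 6: %d)", gs$n_patients,
      gs$n_low_msas, gs$n_high_msas)
  add("Risk strata: low %d / moderate %d / high %d",
      gs$strata$low, gs$strata$moderate, gs$strata$high)
  add("")
  add("== Complications (Clavien-Dindo) ==")
  add("Total complications: %d in %d patients", cs$n_events,
      sum(cs$patient_flags$n[cs$patient_flags$flag == "any"]))
  for (i in seq_len(nrow(cs$per_grade))) {
    add("  Grade %-3s %3d  (%.1f%% of complications)",
        cs$per_grade$grade[i], cs$per_grade$n[i], cs$per_grade$pct_events[i])
  }
  for (i in seq_len(nrow(cs$patient_flags))) {
    add("  %-16s %3d patients (%.1f%%)", cs$patient_flags$flag[i],
        cs$patient_flags$n[i], cs$patient_flags$pct_patients[i])
  }
  add("  Per code (%% of patients):")
  pc <- cs$per_code
  for (i in seq_len(nrow(pc))) {
    add("    %-22s %-14s %3d (%.2f%%)", pc$code[i], pc$timing[i], pc$n[i],
        pc$pct_patients[i])
  }
  add("")
  add("== Covariates by complication status ==")
  cov <- report$covariates_by_complication
  for (i in seq_len(nrow(cov))) {
    add("  %-26s no: %-14s yes: %-14s p = %s [%s]", cov$variable[i],
        cov$group0[i], cov$group1[i], format_p(cov$p_value[i]), cov$method[i])
  }
  add("")
  add("== Low (<=6) vs high MSAS group ==")
  mg <- report$msas_group_comparison
  for (i in seq_len(nrow(mg))) {
    add("  %-26s high: %-14s low: %-14s p = %s [%s]", mg$variable[i],
        mg$group0[i], mg$group1[i], format_p(mg$p_value[i]), mg$method[i])
  }
  add("")
  add("== Crude odds ratios for low MSAS ==")
  orp <- report$odds_ratios
  for (i in seq_len(nrow(orp))) {
    add("  %-16s OR %.3f (95%% CI %.2f-%.2f)%s p = %s [%s]",
        orp$outcome[i], orp$or_estimate[i], orp$ci_low[i], orp$ci_high[i],
        ifelse(isTRUE(orp$corrected[i]), " [Haldane-corrected]", ""),
        format_p(orp$p_value[i]), orp$label[i])
  }
  add("")
  add("== Risk-stratified trend (linear-by-linear) ==")
  tt <- report$trend_tables
  for (oc in unique(tt$outcome)) {
    sub <- tt[tt$outcome == oc, ]
    test <- report$trend_tests[report$trend_tests$outcome == oc, ]
    add("  %s: %s", oc,
        paste(sprintf("%s %d/%d (%.1f%%)", sub$stratum, sub$events, sub$n,
                      100 * sub$fraction), collapse = ", "))
    if (is.na(test$p_value)) {
      add("    trend: %s", test$note)
    } else {
      add("    M^2 = %.3f, p = %s", test$statistic, format_p(test$p_value))
    }
  }
  add("")
  add("== Provenance ==")
  add("rubric: %s; trend scores: %s; msas version %s%s",
      report$provenance$rubric,
      paste(report$provenance$trend_scores, collapse = ","),
      report$provenance$package_version,
      if (!is.null(report$provenance$seed))
        sprintf("; cohort seed %d", report$provenance$seed) else "")
  out
}

render_csv <- function(report) {
  lst <- as_report_list(report)
  rows <- list()
  flatten <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) flatten(x[[nm]], c(prefix, nm))
    } else {
      for (i in seq_along(x)) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          panel = prefix[1L],
          item = paste(c(prefix[-1L], if (length(x) > 1L) i), collapse = "."),
          value = as.character(x[i])
        )
      }
    }
  }
  for (nm in names(lst)) flatten(lst[[nm]], nm)
  dplyr::bind_rows(rows)
}

#' Render an analysis report
#'
#' @param report An `msas_report` from [run_analysis()].
#' @param format `"text"` (character vector of display lines), `"json"`
#'   (single JSON string; parses back to the report's canonical plain-list
#'   form), or `"csv"` (long tibble with one row per report cell).
#' @param path Optional file to write the rendering to.
#' @return The rendering (invisibly when `path` is given).
#' @export
render_report <- function(report, format = c("text", "json", "csv"),
                          path = NULL) {
  stopifnot(inherits(report, "msas_report"))
  format <- match.arg(format)
  out <- switch(format,
    text = render_text(report),
    json = jsonlite::toJSON(as_report_list(report), auto_unbox = TRUE,
                            digits = NA, null = "null"),
    csv = render_csv(report)
  )
  if (!is.null(path)) {
    switch(format,
      text = writeLines(out, path),
      json = writeLines(as.character(out), path),
      csv = readr::write_csv(out, path)
    )
    return(invisible(out))
  }
  out
}

#' @export
print.msas_report <- function(x, ...) {
  writeLines(render_text(x))
  invisible(x)
}
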