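#' Perioperative complication taxonomy
#'
#' The coded adverse events recognized by the package, split by timing
#' class. Intraoperative complications are transfusion within 72 h of
#' surgery, large blood loss (EBL >= 300 mL) and organ injury (bowel;
#' bladder or ureter); everything else -- fever > 37.8 C for more than 24 h,
#' urinary distention, ileus, vault bleeding, readmission within 30 days,
#' lymphedema, dysrhythmia, nerve palsy, wound dehiscence, fistula,
#' peritonitis -- is postoperative.
#'
#' @return A tibble with columns `code` and `timing`
#'   (`"intraoperative"`/`"postoperative"`), in canonical display order.
#' @export
complication_codes <- function() {
  tibble::tibble(
    code = c("bleeding_ge_300", "transfusion_72h", "bowel_injury",
             "bladder_ureter_injury",
             "fever_gt_24h", "urinary_distention", "ileus", "vault_bleeding",
             "readmission_30d", "lymphedema", "dysrhythmia", "nerve_palsy",
             "wound_dehiscence", "fistula", "peritonitis"),
    timing = c(rep("intraoperative", 4L), rep("postoperative", 11L))
  )
}

clavien_levels <- c("I", "II", "III", "IV", "V")
treatment_levels <- c("none_or_bedside", "pharmacological", "intervention",
                      "icu_life_threatening", "death")

#' Timing class of a complication code
#'
#' @param code Character vector of complication codes (see
#'   [complication_codes()]).
#' @return Character vector, `"intraoperative"` or `"postoperative"`.
#' @examples
#' classify_event(c("transfusion_72h", "fever_gt_24h"))
#' @export
classify_event <- function(code) {
  tax <- complication_codes()
  idx <- match(code, tax$code)
  if (anyNA(idx)) {
    stop("unknown complication code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "),
         "; valid codes are: ", paste(tax$code, collapse = ", "),
         call. = FALSE)
  }
  tax$timing[idx]
}

#' Bleeding complication implied by estimated blood loss
#'
#' Blood loss of 300 mL or more is itself an intraoperative complication
#' (`bleeding_ge_300`), by definition and regardless of any other event.
#' Note the deliberate boundary asymmetry with the modified rubric: the
#' complication threshold ">= 300 mL" is inclusive, while the 0-point EBL
#' bin is "> 300 mL" exclusive, so a patient at exactly 300 mL carries a
#' bleeding complication yet still earns 1 EBL point. Both printed rules
#' are followed literally rather than harmonized.
#'
#' @param ebl Estimated blood loss, mL (single non-negative number).
#' @return A one-row tibble (`code`, `timing`) when `ebl >= 300`, otherwise
#'   `NULL`.
#' @export
derive_bleeding_event <- function(ebl) {
  stopifnot(length(ebl) == 1L)
  if (is.na(ebl) || ebl < 0) stop("ebl must be a non-negative number",
                                  call. = FALSE)
  if (ebl >= 300) {
    tibble::tibble(code = "bleeding_ge_300", timing = "intraoperative")
  } else {
    NULL
  }
}

#' Clavien-Dindo grade from the intensity of treatment required
#'
#' Standard mapping: no treatment or bedside care only is grade I,
#' pharmacological treatment grade II, surgical/endoscopic/radiological
#' intervention grade III (IIIa/IIIb are not distinguished),
#' life-threatening complications needing ICU management grade IV, and
#' death grade V.
#'
#' @param treatment_level Character vector over `none_or_bedside`,
#'   `pharmacological`, `intervention`, `icu_life_threatening`, `death`.
#' @return Factor of grades with levels `I`..`V`.
#' @export
grade_clavien <- function(treatment_level) {
  idx <- match(treatment_level, treatment_levels)
  if (anyNA(idx)) {
    stop("unknown treatment level(s): ",
         paste(unique(treatment_level[is.na(idx)]), collapse = ", "),
         "; valid levels are: ", paste(treatment_levels, collapse = ", "),
         call. = FALSE)
  }
  factor(clavien_levels[idx], levels = clavien_levels)
}

#' Tabulate complications with the two standard denominators
#'
#' Per-code counts are event counts with the number of patients as
#' denominator; per-grade percentages use the number of complications as
#' denominator (so they sum to 100% up to rounding). Patient-level flags
#' count each patient once: a patient with both intraoperative and
#' postoperative events contributes to `intraoperative`, `postoperative`
#' and `both`, but only once to `any`.
#'
#' @param cohort An [msas_cohort] (or any list with a `patients` tibble
#'   carrying `patient_id` and an `events` tibble carrying `patient_id`,
#'   `code`, and optionally `grade`).
#' @return An object of class `msas_complication_summary`: a list with
#'   `n_patients`, `n_events`, `per_code`, `per_grade`, `patient_flags`.
#' @export
summarize_complications <- function(cohort) {
  cohort <- as_msas_cohort(cohort)
  patients <- cohort$patients
  events <- cohort$events
  n_pat <- nrow(patients)
  if (n_pat == 0L) stop("cohort is empty", call. = FALSE)
  tax <- complication_codes()
  if (nrow(events) > 0L) {
    events$timing <- classify_event(events$code)
  }
  n_ev <- nrow(events)

  code_counts <- table(factor(events$code, levels = tax$code))
  per_code <- tibble::tibble(
    code = tax$code,
    timing = tax$timing,
    n = as.integer(code_counts[tax$code]),
    pct_patients = 100 * as.integer(code_counts[tax$code]) / n_pat
  )

  if (n_ev > 0L && !is.null(events$grade)) {
    grade_counts <- table(factor(as.character(events$grade),
                                 levels = clavien_levels))
  } else {
    grade_counts <- table(factor(character(), levels = clavien_levels))
  }
  per_grade <- tibble::tibble(
    grade = clavien_levels,
    n = as.integer(grade_counts),
    pct_events = if (n_ev > 0L) 100 * as.integer(grade_counts) / n_ev else 0
  )

  flags <- patient_event_flags(patients, events)
  flag_counts <- c(any = sum(flags$any), intraoperative = sum(flags$intra),
                   postoperative = sum(flags$post), both = sum(flags$both))
  patient_flags <- tibble::tibble(
    flag = names(flag_counts),
    n = as.integer(flag_counts),
    pct_patients = 100 * as.integer(flag_counts) / n_pat
  )

  structure(
    list(n_patients = n_pat, n_events = n_ev, per_code = per_code,
         per_grade = per_grade, patient_flags = patient_flags),
    class = "msas_complication_summary"
  )
}

# One row per patient: any/intra/post/both logical flags.
patient_event_flags <- function(patients, events) {
  ids <- patients$patient_id
  if (nrow(events) > 0L) {
    timing <- classify_event(events$code)
    intra_ids <- unique(events$patient_id[timing == "intraoperative"])
    post_ids <- unique(events$patient_id[timing == "postoperative"])
  } else {
    intra_ids <- post_ids <- character()
  }
  intra <- ids %in% intra_ids
  post <- ids %in% post_ids
  tibble::tibble(patient_id = ids, intra = intra, post = post,
                 any = intra | post, both = intra & post)
}

#' @export
print.msas_complication_summary <- function(x, ...) {
  cat(sprintf("<msas_complication_summary> %d patients, %d complications\n",
              x$n_patients, x$n_events))
  af <- x$patient_flags
  cat(sprintf("  %s: %d (%.1f%%)\n", af$flag, af$n, af$pct_patients), sep = "")
  invisible(x)
}
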