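#' Cohort container
#'
#' An `msas_cohort` bundles the per-patient table with the long-format
#' event and vitals tables. The `patients` tibble has one row per surgical
#' case with the documented covariates plus `ebl_ml` and either precomputed
#' `lowest_map_mmhg`/`lowest_hr_bpm` or a vitals series from which they can
#' be derived -- at least one of the two must be present for a record to be
#' scoreable. `events` has one row per complication
#' (`patient_id`, `code`, `treatment_level`, `grade`); `vitals` (optional)
#' is long format (`patient_id`, `time_min`, `map_mmHg`, `hr_bpm`).
#'
#' @param patients Tibble of patient records.
#' @param events Tibble of complication events (may be empty).
#' @param vitals Optional long-format vitals tibble.
#' @return An object of class `msas_cohort`.
#' @export
msas_cohort <- function(patients, events = empty_events(), vitals = NULL) {
  patients <- tibble::as_tibble(patients)
  events <- tibble::as_tibble(events)
  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)][1L]
    stop("duplicate patient_id: ", dup, call. = FALSE)
  }
  if (nrow(events) > 0L) {
    unknown <- setdiff(events$patient_id, patients$patient_id)
    if (length(unknown) > 0L) {
      stop("events refer to unknown patient_id: ",
           paste(head(unknown, 3L), collapse = ", "), call. = FALSE)
    }
    events$timing <- classify_event(events$code)
  }
  structure(list(patients = patients, events = events, vitals = vitals),
            class = "msas_cohort")
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), code = character(),
                 treatment_level = character(),
                 grade = factor(character(), levels = clavien_levels),
                 timing = character())
}

#' @rdname msas_cohort
#' @param x Object to coerce: an `msas_cohort`, or a list with `patients`
#'   and optionally `events`/`vitals` elements.
#' @export
as_msas_cohort <- function(x) {
  if (inherits(x, "msas_cohort")) return(x)
  if (is.list(x) && !is.null(x$patients)) {
    return(msas_cohort(x$patients,
                       events = if (is.null(x$events)) empty_events() else x$events,
                       vitals = x$vitals))
  }
  if (is.data.frame(x)) return(msas_cohort(x))
  stop("cannot coerce to msas_cohort", call. = FALSE)
}

#' @export
print.msas_cohort <- function(x, ...) {
  cat(sprintf("<msas_cohort> %d patients, %d complication events%s\n",
              nrow(x$patients), nrow(x$events),
              if (!is.null(x$vitals))
                sprintf(", vitals series (%d samples)", nrow(x$vitals))
              else ""))
  invisible(x)
}

cohort_columns <- c(
  "patient_id", "age_years", "bmi_kg_m2", "underlying_disease",
  "previous_pelvic_surgery", "nac", "procedure", "surgical_time_min",
  "preop_hb_g_dl", "postop_hb_g_dl", "ebl_ml", "lowest_map_mmhg",
  "lowest_hr_bpm", "events"
)

procedure_levels <- c("radical_trachelectomy", "radical_hysterectomy")

#' Read a cohort from CSV
#'
#' The cohort file has one row per patient with the documented header (see
#' [msas_cohort] and the package README); the `events` cell is a
#' semicolon-separated list of `code` or `code:treatment_level` tokens
#' (treatment level defaults to `none_or_bedside`, i.e. Clavien grade I).
#' An optional companion vitals file in long format
#' (`patient_id,time_min,map_mmHg,hr_bpm`) supplies the series from which
#' lowest MAP/HR are computed for rows that do not carry precomputed
#' minima. Units are fixed: mL, mmHg, beats/min, minutes, g/dL.
#'
#' Missing numeric covariates are empty cells and load as `NA`; records
#' missing both EBL-and-minima and a vitals series are rejected, since they
#' cannot be scored.
#'
#' @param path Path to the cohort CSV.
#' @param vitals_path Optional path to the companion vitals CSV.
#' @return An [msas_cohort].
#' @export
read_cohort <- function(path, vitals_path = NULL) {
  d <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    age_years = readr::col_double(),
    bmi_kg_m2 = readr::col_double(),
    underlying_disease = readr::col_logical(),
    previous_pelvic_surgery = readr::col_logical(),
    nac = readr::col_logical(),
    procedure = readr::col_character(),
    surgical_time_min = readr::col_double(),
    preop_hb_g_dl = readr::col_double(),
    postop_hb_g_dl = readr::col_double(),
    ebl_ml = readr::col_double(),
    lowest_map_mmhg = readr::col_double(),
    lowest_hr_bpm = readr::col_double(),
    events = readr::col_character()
  ), na = c("", "NA"))
  missing_cols <- setdiff(cohort_columns, names(d))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$patient_id)) {
    dup <- unique(d$patient_id[duplicated(d$patient_id)])
    stop("duplicate patient_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_proc <- which(!is.na(d$procedure) & !d$procedure %in% procedure_levels)
  if (length(bad_proc) > 0L) {
    stop("row ", bad_proc[1L], ": unknown procedure '",
         d$procedure[bad_proc[1L]], "'", call. = FALSE)
  }
  if (any(!is.na(d$ebl_ml) & d$ebl_ml < 0)) {
    stop("ebl_ml must be non-negative", call. = FALSE)
  }

  events <- parse_event_tokens(d$patient_id, d$events)
  d$events <- NULL

  vitals <- NULL
  if (!is.null(vitals_path)) {
    vitals <- read_vitals(vitals_path)
    need <- is.na(d$lowest_map_mmhg) | is.na(d$lowest_hr_bpm)
    for (i in which(need)) {
      v <- vitals[vitals$patient_id == d$patient_id[i], ]
      if (nrow(v) > 0L) {
        mins <- extract_minima(v)
        d$lowest_map_mmhg[i] <- mins$lowest_map
        d$lowest_hr_bpm[i] <- mins$lowest_hr
      }
    }
  }
  unscoreable <- is.na(d$lowest_map_mmhg) | is.na(d$lowest_hr_bpm)
  if (any(unscoreable)) {
    stop("row(s) ", paste(head(which(unscoreable), 3L), collapse = ", "),
         " (patient ", paste(head(d$patient_id[unscoreable], 3L),
                             collapse = ", "),
         "): no lowest MAP/HR and no vitals series", call. = FALSE)
  }
  msas_cohort(d, events = events, vitals = vitals)
}

read_vitals <- function(path) {
  v <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    time_min = readr::col_double(),
    map_mmHg = readr::col_double(),
    hr_bpm = readr::col_double()
  ))
  missing_cols <- setdiff(c("patient_id", "time_min", "map_mmHg", "hr_bpm"),
                          names(v))
  if (length(missing_cols) > 0L) {
    stop("vitals file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v
}

# "code" or "code:treatment_level" tokens, ';'-separated per patient cell.
parse_event_tokens <- function(patient_id, tokens) {
  out <- list()
  for (i in seq_along(tokens)) {
    cell <- tokens[i]
    if (is.na(cell) || !nzchar(trimws(cell))) next
    parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    for (tok in parts) {
      bits <- strsplit(tok, ":", fixed = TRUE)[[1L]]
      if (length(bits) > 2L) {
        stop("row ", i, ": unparseable event token '", tok, "'",
             call. = FALSE)
      }
      code <- bits[1L]
      lvl <- if (length(bits) == 2L) bits[2L] else "none_or_bedside"
      if (!code %in% complication_codes()$code) {
        stop("row ", i, ": unknown complication code '", code, "'",
             call. = FALSE)
      }
      if (!lvl %in% treatment_levels) {
        stop("row ", i, ": unknown treatment level '", lvl, "'",
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        patient_id = patient_id[i], code = code, treatment_level = lvl)
    }
  }
  if (length(out) == 0L) return(empty_events())
  ev <- dplyr::bind_rows(out)
  ev$grade <- grade_clavien(ev$treatment_level)
  ev$timing <- classify_event(ev$code)
  ev
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: events are packed back into
#' `code:treatment_level` tokens and the result re-reads to field-level
#' equality (numbers at full double precision).
#'
#' @param cohort An [msas_cohort].
#' @param path Output path for the cohort CSV.
#' @param vitals_path Optional output path for the vitals CSV (written only
#'   when the cohort carries a vitals table).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, vitals_path = NULL) {
  cohort <- as_msas_cohort(cohort)
  d <- cohort$patients
  ev <- cohort$events
  token_by_patient <- character(nrow(d))
  if (nrow(ev) > 0L) {
    toks <- paste(ev$code, ev$treatment_level, sep = ":")
    agg <- tapply(toks, factor(ev$patient_id, levels = d$patient_id),
                  paste, collapse = ";")
    token_by_patient <- as.character(ifelse(is.na(agg), "", agg))
  }
  d$events <- token_by_patient
  readr::write_csv(d[, cohort_columns], path, na = "")
  if (!is.null(vitals_path) && !is.null(cohort$vitals)) {
    readr::write_csv(cohort$vitals, vitals_path)
  }
  invisible(path)
}
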