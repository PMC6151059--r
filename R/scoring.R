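#' Lowest MAP and HR over an intraoperative vitals series
#'
#' Vitals are assumed to be charted on the anesthesia record at a nominal
#' 5-minute interval; gaps are permitted and no imputation is done -- the
#' minima are taken over the samples that are present (with a warning when
#' fewer than 3 samples are available). The two minima may occur at
#' different times.
#'
#' @param vitals Data frame with columns `time_min` (strictly increasing,
#'   non-negative), `map_mmHg` (> 0) and `hr_bpm` (> 0).
#' @return A list with elements `lowest_map` and `lowest_hr`.
#' @examples
#' v <- tibble::tibble(time_min = c(0, 5, 10),
#'                     map_mmHg = c(80, 65, 70), hr_bpm = c(72, 68, 75))
#' extract_minima(v)
#' @export
extract_minima <- function(vitals) {
  vitals <- as.data.frame(vitals)
  needed <- c("time_min", "map_mmHg", "hr_bpm")
  if (!all(needed %in% names(vitals))) {
    stop("vitals must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(vitals) == 0L) {
    stop("vitals series is empty: record is invalid", call. = FALSE)
  }
  if (anyNA(vitals[needed])) {
    stop("vitals series contains missing values", call. = FALSE)
  }
  if (any(diff(vitals$time_min) <= 0)) {
    stop("vitals time offsets must be strictly increasing", call. = FALSE)
  }
  if (any(vitals$map_mmHg <= 0) || any(vitals$hr_bpm <= 0)) {
    stop("MAP and HR must be positive", call. = FALSE)
  }
  if (nrow(vitals) < 3L) {
    warning("fewer than 3 vitals samples; minima may be unreliable",
            call. = FALSE)
  }
  list(lowest_map = min(vitals$map_mmHg), lowest_hr = min(vitals$hr_bpm))
}

#' Points for one score component
#'
#' Looks up the unique bin of `bins` containing each value. Values outside
#' the bins' joint domain (negative EBL, non-positive MAP/HR) are an error.
#'
#' @param value Numeric vector of measurements (reals are accepted; scores
#'   stay integer).
#' @param bins A bin table as found in an [score_rubric()] component.
#' @return Integer vector of points.
#' @export
score_component <- function(value, bins) {
  if (anyNA(value)) stop("measurement is missing (NA)", call. = FALSE)
  pts <- rep(NA_integer_, length(value))
  for (i in seq_len(nrow(bins))) {
    lo <- if (bins$min_incl[i]) value >= bins$min[i] else value > bins$min[i]
    hi <- if (bins$max_incl[i]) value <= bins$max[i] else value < bins$max[i]
    pts[lo & hi] <- bins$points[i]
  }
  if (anyNA(pts)) {
    bad <- value[is.na(pts)][1L]
    stop("value ", bad, " is outside the component's valid domain",
         call. = FALSE)
  }
  pts
}

#' Compute the surgical Apgar score
#'
#' Sums the per-component points for estimated blood loss, lowest MAP and
#' lowest HR under a rubric. All arguments are vectorized and recycled to a
#' common length.
#'
#' @param ebl Estimated blood loss, mL (>= 0).
#' @param lowest_map Lowest intraoperative mean arterial pressure, mmHg (> 0).
#' @param lowest_hr Lowest intraoperative heart rate, beats/min (> 0).
#' @param rubric Rubric, rubric name, or YAML path (see [as_rubric()]);
#'   default MSAS.
#' @return A tibble with columns `rubric`, `ebl_points`, `map_points`,
#'   `hr_points`, `total` (0--10 for the built-in rubrics).
#' @examples
#' compute_score(200, 60, 70)          # MSAS 1 + 2 + 2 = 5
#' compute_score(50, 70, 55)$total     # best bin everywhere: 10
#' @export
compute_score <- function(ebl, lowest_map, lowest_hr, rubric = msas_rubric()) {
  rubric <- as_rubric(rubric)
  n <- max(length(ebl), length(lowest_map), length(lowest_hr))
  ebl <- rep_len(ebl, n)
  lowest_map <- rep_len(lowest_map, n)
  lowest_hr <- rep_len(lowest_hr, n)
  e <- score_component(ebl, rubric$ebl_bins)
  m <- score_component(lowest_map, rubric$map_bins)
  h <- score_component(lowest_hr, rubric$hr_bins)
  tibble::tibble(
    rubric = rubric$name,
    ebl_points = e, map_points = m, hr_points = h,
    total = e + m + h
  )
}

check_total <- function(total) {
  if (anyNA(total) || any(total != round(total)) ||
      any(total < 0) || any(total > 10)) {
    stop("score total must be an integer in [0, 10]", call. = FALSE)
  }
  as.integer(total)
}

#' Dichotomize a score as low
#'
#' The low-score group is defined as a total of 6 or less (in contrast to
#' the <= 4 cutoff often used with the original score after open surgery).
#'
#' @param total Integer score total in 0--10.
#' @return Logical vector: `TRUE` when `total <= 6`.
#' @export
is_low_msas <- function(total) {
  check_total(total) <= 6L
}

#' Three-level risk stratification of a score
#'
#' Scores 7--10 are low risk, 5--6 moderate, and 0--4 high risk; the
#' partition is exhaustive and mutually exclusive, and the moderate and high
#' strata together are exactly the low-score (<= 6) group.
#'
#' @param total Integer score total in 0--10.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
stratify_risk <- function(total) {
  total <- check_total(total)
  out <- ifelse(total >= 7L, "low", ifelse(total >= 5L, "moderate", "high"))
  factor(out, levels = c("low", "moderate", "high"))
}
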