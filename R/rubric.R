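#' Scoring rubrics for the surgical Apgar score and its modified variant
#'
#' A rubric maps the three intraoperative measurements -- estimated blood
#' loss (EBL, mL), lowest mean arterial pressure (MAP, mmHg) and lowest
#' heart rate (HR, beats/min) -- to integer points via per-component bins.
#' The two built-in rubrics share the MAP and HR components and differ only
#' in the EBL bins: the modified rubric compresses them
#' (<=50 / 51--150 / 151--300 / >300 mL) to suit the lower blood loss of
#' robotic surgery, whereas the original uses
#' <=100 / 101--600 / 601--1000 / >1000 mL.
#'
#' Bins are real intervals, not integer ranges. Printed ranges such as
#' "55--65" are closed at their printed endpoints and the interval system is
#' made to cover all physically valid values by half-opening each bin on the
#' side facing its neighbour; e.g. the HR bins are (0,55], (55,65], (65,75],
#' (75,85], (85,Inf), so HR = 55 earns 4 points (the "<=55" bin wins the
#' printed overlap with "55--65", following the original surgical Apgar
#' convention), and a non-integer HR of 65.5 falls in the 2-point bin.
#'
#' @param name Rubric label, e.g. `"MSAS"`.
#' @param ebl_bins,map_bins,hr_bins Data frames with columns `min`, `max`,
#'   `min_incl`, `max_incl`, `points`: disjoint intervals that jointly cover
#'   the component's valid domain (EBL >= 0; MAP > 0; HR > 0).
#' @return An object of class `msas_rubric`: a list with elements `name`,
#'   `ebl_bins`, `map_bins`, `hr_bins`.
#' @examples
#' r <- msas_rubric()
#' score_component(300, r$ebl_bins) # 1 point: 151-300 mL band
#' @export
score_rubric <- function(name, ebl_bins, map_bins, hr_bins) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ebl_bins <- validate_bins(ebl_bins, domain_min = 0, domain_min_incl = TRUE,
                            component = "EBL")
  map_bins <- validate_bins(map_bins, domain_min = 0, domain_min_incl = FALSE,
                            component = "MAP")
  hr_bins <- validate_bins(hr_bins, domain_min = 0, domain_min_incl = FALSE,
                           component = "HR")
  structure(
    list(name = name, ebl_bins = ebl_bins, map_bins = map_bins,
         hr_bins = hr_bins),
    class = "msas_rubric"
  )
}

# A bin table is valid when its intervals are sorted, pairwise contiguous
# (each boundary belongs to exactly one side) and cover (domain_min, Inf).
validate_bins <- function(bins, domain_min, domain_min_incl, component) {
  bins <- as.data.frame(bins)
  needed <- c("min", "max", "min_incl", "max_incl", "points")
  if (!all(needed %in% names(bins))) {
    stop(component, " bins must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  bins <- bins[order(bins$min), needed]
  if (nrow(bins) < 1L) stop(component, " bins are empty", call. = FALSE)
  if (any(bins$points < 0) || any(bins$points != round(bins$points))) {
    stop(component, " bin points must be non-negative integers", call. = FALSE)
  }
  bins$points <- as.integer(bins$points)
  if (bins$min[1L] != domain_min || bins$min_incl[1L] != domain_min_incl) {
    stop(component, " bins must start at the domain boundary (",
         if (domain_min_incl) "[" else "(", domain_min, ")", call. = FALSE)
  }
  n <- nrow(bins)
  if (!is.infinite(bins$max[n]) || bins$max_incl[n]) {
    stop(component, " bins must extend to Inf (open)", call. = FALSE)
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (bins$max[i] != bins$min[i + 1L] ||
          !xor(bins$max_incl[i], bins$min_incl[i + 1L])) {
        stop(component, " bins must be contiguous and disjoint at ",
             bins$max[i], call. = FALSE)
      }
    }
  }
  if (any(bins$min > bins$max)) {
    stop(component, " bins contain an empty interval", call. = FALSE)
  }
  tibble::as_tibble(bins)
}

rubric_bin <- function(min, max, min_incl, max_incl, points) {
  data.frame(min = min, max = max, min_incl = min_incl,
             max_incl = max_incl, points = as.integer(points))
}

# MAP and HR components shared by both built-in rubrics.
map_bins_default <- function() {
  rbind(
    rubric_bin(0, 40, FALSE, FALSE, 0),   # < 40
    rubric_bin(40, 55, TRUE, FALSE, 1),   # 40-54
    rubric_bin(55, 70, TRUE, FALSE, 2),   # 55-69
    rubric_bin(70, Inf, TRUE, FALSE, 3)   # >= 70
  )
}

hr_bins_default <- function() {
  rbind(
    rubric_bin(0, 55, FALSE, TRUE, 4),    # <= 55 (takes the boundary)
    rubric_bin(55, 65, FALSE, TRUE, 3),   # 55-65, effectively (55, 65]
    rubric_bin(65, 75, FALSE, TRUE, 2),   # 66-75
    rubric_bin(75, 85, FALSE, TRUE, 1),   # 76-85
    rubric_bin(85, Inf, FALSE, FALSE, 0)  # > 85
  )
}

#' @rdname score_rubric
#' @export
sas_rubric <- function() {
  score_rubric(
    "SAS",
    ebl_bins = rbind(
      rubric_bin(0, 100, TRUE, TRUE, 3),     # <= 100
      rubric_bin(100, 600, FALSE, TRUE, 2),  # 101-600
      rubric_bin(600, 1000, FALSE, TRUE, 1), # 601-1000
      rubric_bin(1000, Inf, FALSE, FALSE, 0) # > 1000
    ),
    map_bins = map_bins_default(),
    hr_bins = hr_bins_default()
  )
}

#' @rdname score_rubric
#' @export
msas_rubric <- function() {
  score_rubric(
    "MSAS",
    ebl_bins = rbind(
      rubric_bin(0, 50, TRUE, TRUE, 3),     # <= 50
      rubric_bin(50, 150, FALSE, TRUE, 2),  # 51-150
      rubric_bin(150, 300, FALSE, TRUE, 1), # 151-300
      rubric_bin(300, Inf, FALSE, FALSE, 0) # > 300
    ),
    map_bins = map_bins_default(),
    hr_bins = hr_bins_default()
  )
}

#' @export
print.msas_rubric <- function(x, ...) {
  cat("<msas_rubric> ", x$name, "\n", sep = "")
  for (comp in c("ebl_bins", "map_bins", "hr_bins")) {
    b <- x[[comp]]
    lab <- sprintf("%s%g, %g%s", ifelse(b$min_incl, "[", "("), b$min, b$max,
                   ifelse(b$max_incl, "]", ")"))
    cat(sub("_bins", "", comp), ": ",
        paste(sprintf("%s=%d", lab, b$points), collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a rubric as YAML
#'
#' The serialized form holds `name` and one list of
#' `{min, max, min_incl, max_incl, points}` entries per component; `Inf`
#' round-trips as YAML `.inf`. The built-in rubrics are bundled under
#' `system.file("extdata", package = "msas")`.
#'
#' @param path File path.
#' @param rubric An `msas_rubric`.
#' @return `read_rubric()` returns an `msas_rubric`; `write_rubric()`
#'   returns `path` invisibly.
#' @export
read_rubric <- function(path) {
  raw <- yaml::read_yaml(path)
  as_bins <- function(lst) {
    do.call(rbind, lapply(lst, function(b) {
      rubric_bin(as.numeric(b$min), as.numeric(b$max),
                 isTRUE(b$min_incl), isTRUE(b$max_incl), b$points)
    }))
  }
  score_rubric(raw$name, as_bins(raw$ebl_bins), as_bins(raw$map_bins),
               as_bins(raw$hr_bins))
}

#' @rdname read_rubric
#' @export
write_rubric <- function(rubric, path) {
  stopifnot(inherits(rubric, "msas_rubric"))
  as_list <- function(b) {
    lapply(seq_len(nrow(b)), function(i) {
      list(min = b$min[i], max = b$max[i], min_incl = b$min_incl[i],
           max_incl = b$max_incl[i], points = b$points[i])
    })
  }
  yaml::write_yaml(
    list(name = rubric$name, ebl_bins = as_list(rubric$ebl_bins),
         map_bins = as_list(rubric$map_bins), hr_bins = as_list(rubric$hr_bins)),
    path
  )
  invisible(path)
}

#' Resolve a rubric argument
#'
#' Accepts an `msas_rubric`, the strings `"sas"`/`"msas"` (case-insensitive),
#' or a path to a rubric YAML file.
#'
#' @param rubric Rubric, name, or file path.
#' @return An `msas_rubric`.
#' @export
as_rubric <- function(rubric) {
  if (inherits(rubric, "msas_rubric")) return(rubric)
  if (is.character(rubric) && length(rubric) == 1L) {
    key <- tolower(rubric)
    if (key == "sas") return(sas_rubric())
    if (key == "msas") return(msas_rubric())
    if (file.exists(rubric)) return(read_rubric(rubric))
    stop("unknown rubric '", rubric, "': use \"sas\", \"msas\", an ",
         "msas_rubric object, or a YAML file path", call. = FALSE)
  }
  stop("cannot interpret `rubric`", call. = FALSE)
}
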