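#' Build a contingency table of exposure levels against a binary outcome
#'
#' @param label Character vector of exposure-level labels (rows).
#' @param events,nonevents Non-negative integer counts per row.
#' @param score Ordinal score per row, used by the trend test; defaults to
#'   1, 2, ... in row order. Must be strictly monotone.
#' @return A tibble with columns `label`, `score`, `events`, `nonevents`.
#' @examples
#' contingency_table(c("low", "moderate", "high"),
#'                   events = c(0, 15, 10), nonevents = c(15, 75, 23))
#' @export
contingency_table <- function(label, events, nonevents,
                              score = seq_along(label)) {
  stopifnot(length(label) == length(events),
            length(events) == length(nonevents),
            length(score) == length(label))
  if (length(label) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (any(events < 0) || any(nonevents < 0) ||
      any(events != round(events)) || any(nonevents != round(nonevents))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(events) + sum(nonevents) == 0) {
    stop("table has no observations", call. = FALSE)
  }
  d <- diff(score)
  if (!(all(d > 0) || all(d < 0))) {
    stop("scores must be strictly monotone", call. = FALSE)
  }
  tibble::tibble(label = as.character(label), score = as.numeric(score),
                 events = as.integer(events), nonevents = as.integer(nonevents))
}

#' Read or write a contingency table as CSV
#'
#' The dialect is a plain CSV with header `label,score,events,nonevents`.
#'
#' @param path File path.
#' @param table A contingency table as from [contingency_table()].
#' @return `read_counts()` returns the validated table; `write_counts()`
#'   returns `path` invisibly.
#' @export
read_counts <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), score = readr::col_double(),
    events = readr::col_integer(), nonevents = readr::col_integer()
  ))
  missing_cols <- setdiff(c("label", "score", "events", "nonevents"), names(d))
  if (length(missing_cols) > 0L) {
    stop("counts file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  contingency_table(d$label, d$events, d$nonevents, score = d$score)
}

#' @rdname read_counts
#' @export
write_counts <- function(table, path) {
  readr::write_csv(table[, c("label", "score", "events", "nonevents")], path)
  invisible(path)
}

# Coerce a 2-column count input (contingency tibble, matrix, or data frame
# with events/nonevents) into a k x 2 integer matrix.
as_counts_matrix <- function(x, k = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("events", "nonevents") %in% names(x))) {
      stop("data-frame input needs `events` and `nonevents` columns",
           call. = FALSE)
    }
    m <- cbind(events = x$events, nonevents = x$nonevents)
    if (!is.null(x$label)) rownames(m) <- x$label
  } else if (is.matrix(x)) {
    if (ncol(x) != 2L) stop("count matrix must have 2 columns", call. = FALSE)
    m <- x
  } else {
    stop("cannot interpret counts input", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!is.null(k) && nrow(m) != k) {
    stop("expected a ", k, " x 2 table", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

new_htest <- function(statistic, parameter, p.value, method, data.name,
                      ...) {
  structure(
    c(list(statistic = statistic, parameter = parameter, p.value = p.value,
           method = method, data.name = data.name), list(...)),
    class = "htest"
  )
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Computed from the definition: the sum of (observed - expected)^2 /
#' expected over the four cells, referred to chi-square with 1 df. The
#' default is no Yates continuity correction (the plain Pearson statistic);
#' set `correct = TRUE` to subtract 0.5 from each |O - E|.
#'
#' @param x A 2 x 2 count matrix, or a 2-row data frame with
#'   `events`/`nonevents` columns (rows are exposure levels, columns
#'   outcome/non-outcome).
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   and `p.value`.
#' @examples
#' chi_square_2x2(rbind(c(1, 85), c(26, 26)))
#' @export
chi_square_2x2 <- function(x, correct = FALSE) {
  m <- as_counts_matrix(x, k = 2L)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chi-square statistic undefined: a marginal total is zero",
         call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  dev <- abs(m - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  new_htest(
    statistic = c("X-squared" = stat), parameter = c(df = 1),
    p.value = pchisq(stat, df = 1, lower.tail = FALSE),
    method = paste0("Pearson chi-square test",
                    if (correct) " with Yates continuity correction"),
    data.name = deparse1(substitute(x))
  )
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value conditional on the margins: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (with a small relative
#' tolerance for floating-point ties). Zero cells and zero margins are
#' handled; a degenerate margin gives p = 1.
#'
#' @inheritParams chi_square_2x2
#' @return An object of class `htest`.
#' @export
fisher_exact_2x2 <- function(x) {
  m <- as_counts_matrix(x, k = 2L)
  r1 <- sum(m[1L, ]); r2 <- sum(m[2L, ]); c1 <- sum(m[, 1L])
  a_obs <- m[1L, 1L]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a_obs, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  new_htest(
    statistic = NULL, parameter = NULL, p.value = p,
    method = "Fisher's exact test (two-sided, sum of probabilities <= observed)",
    data.name = deparse1(substitute(x))
  )
}

#' Linear-by-linear association (Mantel-Haenszel trend) test
#'
#' For an ordered k x 2 table the statistic is M^2 = (N - 1) r^2, where r
#' is the Pearson correlation over all N individuals between the row score
#' and the binary outcome indicator; M^2 is referred to chi-square with
#' 1 df. This is the statistic labelled "linear-by-linear association" in
#' SPSS output, and its p-value is invariant under affine transformation of
#' the scores.
#'
#' @param x A k x 2 count matrix or a contingency tibble (rows ordered).
#' @param scores Numeric row scores; default the table's `score` column, or
#'   1..k for matrix input.
#' @return An object of class `htest`.
#' @examples
#' tab <- contingency_table(c("low", "mod", "high"), c(0, 15, 10),
#'                          c(15, 75, 23))
#' linear_by_linear(tab)
#' @export
linear_by_linear <- function(x, scores = NULL) {
  if (is.null(scores) && is.data.frame(x) && !is.null(x$score)) {
    scores <- x$score
  }
  m <- as_counts_matrix(x)
  k <- nrow(m)
  if (is.null(scores)) scores <- seq_len(k)
  stopifnot(length(scores) == k)
  row_tot <- rowSums(m)
  n <- sum(row_tot)
  ev <- m[, 1L]
  mean_s <- sum(scores * row_tot) / n
  var_s <- sum(scores^2 * row_tot) / n - mean_s^2
  p_ev <- sum(ev) / n
  var_y <- p_ev * (1 - p_ev)
  if (var_s <= 0 || var_y <= 0) {
    stop("trend statistic undefined: zero variance in scores or outcome",
         call. = FALSE)
  }
  cov_sy <- sum(scores * ev) / n - mean_s * p_ev
  r <- cov_sy / sqrt(var_s * var_y)
  stat <- (n - 1) * r^2
  new_htest(
    statistic = c("M^2" = stat), parameter = c(df = 1),
    p.value = pchisq(stat, df = 1, lower.tail = FALSE),
    method = "Linear-by-linear association test",
    data.name = deparse1(substitute(x)),
    estimate = c(r = r)
  )
}

#' Odds ratio for a 2 x 2 table with a Woolf confidence interval
#'
#' OR = (a d) / (b c) with the exposed-event cell as `a` (first row, first
#' column). The confidence interval is the Woolf log-normal interval
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells, and the
#' result is flagged as corrected.
#'
#' @inheritParams chi_square_2x2
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `msas_odds_ratio`: list with `estimate`,
#'   `conf_low`, `conf_high`, `conf_level`, `corrected`, `method`.
#' @examples
#' odds_ratio_2x2(rbind(c(20, 10), c(10, 20)))  # OR = 4
#' @export
odds_ratio_2x2 <- function(x, conf_level = 0.95) {
  m <- as_counts_matrix(x, k = 2L)
  corrected <- any(m == 0)
  if (corrected) m <- m + 0.5
  a <- m[1L, 1L]; b <- m[1L, 2L]; c_ <- m[2L, 1L]; d <- m[2L, 2L]
  if (b * c_ == 0) {
    stop("odds ratio undefined: zero denominator cell", call. = FALSE)
  }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(estimate = or,
         conf_low = exp(log(or) - z * se),
         conf_high = exp(log(or) + z * se),
         conf_level = conf_level,
         corrected = corrected,
         method = "crude odds ratio, Woolf confidence interval"),
    class = "msas_odds_ratio"
  )
}

#' @export
print.msas_odds_ratio <- function(x, ...) {
  cat(sprintf("OR = %.3f, %d%% CI %.3f-%.3f (%s%s)\n", x$estimate,
              round(100 * x$conf_level), x$conf_low, x$conf_high, x$method,
              if (x$corrected) "; Haldane-Anscombe corrected" else ""))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t from the textbook formulas: pooled variance
#' sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2), statistic
#' (m1 - m2) / sqrt(sp^2 (1/n1 + 1/n2)), two-sided p on n1 + n2 - 2 df.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return An object of class `htest`.
#' @export
students_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values",
                               call. = FALSE)
  sp2 <- ((n1 - 1) * var(group_a) + (n2 - 1) * var(group_b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled variance is zero: t statistic undefined",
                     call. = FALSE)
  stat <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  new_htest(
    statistic = c(t = stat), parameter = c(df = df),
    p.value = 2 * pt(-abs(stat), df = df),
    method = "Two-sample t-test (pooled variance)",
    data.name = paste(deparse1(substitute(group_a)), "vs",
                      deparse1(substitute(group_b)))
  )
}

#' Choose between chi-square and Fisher's exact test
#'
#' Uses the common rule of thumb: Fisher's exact test when any expected
#' cell count under independence is below 5, the Pearson chi-square
#' otherwise. The minimum expected count is attached as an attribute so the
#' decision can be recorded in reports.
#'
#' @inheritParams chi_square_2x2
#' @return `"chi_square"` or `"fisher"`, with attribute `min_expected`.
#' @export
test_selector <- function(x) {
  m <- as_counts_matrix(x, k = 2L)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  min_e <- min(expected)
  structure(if (min_e < 5) "fisher" else "chi_square", min_expected = min_e)
}
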