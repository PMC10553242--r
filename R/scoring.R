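#' Score the ASRS-v1.1 six-item ADHD screener
#'
#' Responses are coded 0-4 (never, rarely, sometimes, often, very often).
#' The screener dichotomizes each item before summing: items 1-3 count as a
#' symptom at "sometimes" or above (code >= 2), items 4-6 only at "often"
#' or above (code >= 3). Four or more flagged items is a positive screen.
#' An optional settings indicator (symptoms present in two or more settings
#' over the past six months) is ANDed with the score rule when supplied;
#' the questionnaire items alone cannot compute it.
#'
#' @param responses Integer vector of 6 codes in 0-4 (or a 6-column
#'   matrix/data frame, one row per subject).
#' @param settings Optional logical vector (one per subject).
#' @return A tibble with `flag_1`..`flag_6`, `total` (0-6), `positive`.
#'   Rows with any missing item have `NA` total and `NA` positive: items
#'   are never imputed.
#' @export
score_asrs <- function(responses, settings = NULL) {
  m <- as_response_matrix(responses, 6, "ASRS", 0:4)
  flags <- cbind(m[, 1:3, drop = FALSE] >= 2, m[, 4:6, drop = FALSE] >= 3)
  storage.mode(flags) <- "integer"
  colnames(flags) <- paste0("flag_", 1:6)
  total <- rowSums(flags)
  positive <- total >= 4
  if (!is.null(settings)) positive <- positive & settings
  out <- tibble::as_tibble(as.data.frame(flags))
  out$total <- as.integer(total)
  out$positive <- positive
  out
}

#' Score the PHQ-9 depression questionnaire
#'
#' Item codes 0-3 are summed to a 0-27 total; totals of 10 or more screen
#' positive, with severity bands none/minimal (0-4), mild (5-9), moderate
#' (10-14), moderately severe (15-19) and severe (20-27).
#'
#' @param responses Integer vector of 9 codes in 0-3 (or matrix/data frame).
#' @return A tibble with `total`, `positive`, `band` (ordered factor).
#' @export
score_phq9 <- function(responses) {
  m <- as_response_matrix(responses, 9, "PHQ-9", 0:3)
  total <- rowSums(m)
  bands <- c("none", "mild", "moderate", "moderately_severe", "severe")
  band <- cut(total, breaks = c(-1, 4, 9, 14, 19, 27), labels = bands,
              ordered_result = TRUE)
  tibble::tibble(
    total = as.integer(total),
    positive = total >= 10,
    band = band
  )
}

#' Score the Insomnia Severity Index (7 items, codes 0-4; total 0-28)
#' @param responses Integer vector of 7 codes in 0-4 (or matrix/data frame).
#' @return A tibble with `total`.
#' @export
score_isi <- function(responses) {
  m <- as_response_matrix(responses, 7, "ISI", 0:4)
  tibble::tibble(total = as.integer(rowSums(m)))
}

#' Score the Oslo Social Support Scale (OSSS-3)
#'
#' Item 1 is coded 1-4 and items 2-3 are coded 1-5, giving totals in 3-14;
#' higher totals indicate better support.
#'
#' @param responses Integer vector of 3 codes (or matrix/data frame).
#' @return A tibble with `total`.
#' @export
score_osss3 <- function(responses) {
  m <- as_response_matrix(responses, 3, "OSSS-3", NULL)
  check_range(m[, 1], 1, 4, "OSSS-3 item 1")
  for (j in 2:3) check_range(m[, j], 1, 5, paste("OSSS-3 item", j))
  tibble::tibble(total = as.integer(rowSums(m)))
}

#' Score the Problematic Internet Use Questionnaire (PIUQ-9)
#'
#' Nine items coded 1-5 (never to always), summed to a 9-45 total.
#'
#' @param responses Integer vector of 9 codes in 1-5 (or matrix/data frame).
#' @return A tibble with `total`.
#' @export
score_piuq9 <- function(responses) {
  m <- as_response_matrix(responses, 9, "PIUQ-9", 1:5)
  tibble::tibble(total = as.integer(rowSums(m)))
}

as_response_matrix <- function(responses, k, label, range) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != k) {
    abort(sprintf("%s expects %d items, got %d columns", label, k, ncol(responses)))
  }
  storage.mode(responses) <- "double"
  if (!is.null(range)) {
    for (j in seq_len(k)) {
      check_range(responses[, j], min(range), max(range), paste(label, "item", j))
    }
  }
  responses
}

check_range <- function(x, lo, hi, label) {
  bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
  if (any(bad)) {
    abort(sprintf("%s: response code %s outside %d-%d",
                  label, format(x[bad][1]), lo, hi))
  }
  invisible(x)
}

#' Score every instrument in a subject-by-item table
#'
#' Expects the canonical column layout `asrs_1..asrs_6`, `phq_1..phq_9`,
#' `isi_1..isi_7`, `osss_1..osss_3`, `piuq_1..piuq_9` (plus any covariates,
#' which are carried through untouched is `keep_covariates`). Subjects with
#' a missing item on an instrument get `NA` scores for that instrument.
#'
#' @param data Data frame of item responses, e.g. from [simulate_survey()].
#' @param keep_covariates Carry non-item columns through to the output.
#' @return A tibble with one row per subject: ASRS flags/total/positive,
#'   PHQ total/positive/band, ISI/OSSS/PIUQ totals.
#' @export
score_instruments <- function(data, keep_covariates = FALSE) {
  grab <- function(prefix, k) {
    cols <- paste0(prefix, "_", seq_len(k))
    missing <- setdiff(cols, names(data))
    if (length(missing)) {
      abort(paste0("missing item columns: ", paste(missing, collapse = ", ")))
    }
    as.matrix(data[, cols])
  }
  asrs <- score_asrs(grab("asrs", 6))
  phq <- score_phq9(grab("phq", 9))
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id else seq_len(nrow(data)),
    asrs_total = asrs$total, asrs_positive = asrs$positive,
    phq_total = phq$total, phq_positive = phq$positive, phq_band = phq$band,
    isi_total = score_isi(grab("isi", 7))$total,
    osss_total = score_osss3(grab("osss", 3))$total,
    piuq_total = score_piuq9(grab("piuq", 9))$total
  )
  if (keep_covariates) {
    items <- unlist(lapply(
      list(c("asrs", 6), c("phq", 9), c("isi", 7), c("osss", 3), c("piuq", 9)),
      function(z) paste0(z[1], "_", seq_len(as.integer(z[2])))
    ))
    covs <- setdiff(names(data), c(items, "subject_id"))
    out <- dplyr::bind_cols(out, data[, covs, drop = FALSE])
  }
  out
}

#' Prevalence with a Wilson score interval
#'
#' @param count Number of positives.
#' @param n Number screened (> 0).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble `count`, `n`, `proportion`, `ci_low`, `ci_high`,
#'   `level`. Bounds always lie in `[0, 1]` and bracket the proportion.
#' @examples
#' prevalence(303, 1514)
#' @export
prevalence <- function(count, n, level = 0.95) {
  if (n <= 0) abort("`n` must be positive")
  if (count < 0 || count > n) abort("`count` must lie in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- count / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    count = count, n = n, proportion = p,
    ci_low = max(0, centre - half), ci_high = min(1, centre + half),
    level = level
  )
}

#' Prevalence report for scored survey data
#'
#' @param scores Output of [score_instruments()].
#' @param level Confidence level for the Wilson intervals.
#' @return A tibble with one row per outcome (ADHD screen, depression
#'   screen) with Wilson intervals over complete cases.
#' @export
prevalence_report <- function(scores, level = 0.95) {
  one <- function(outcome, flag) {
    flag <- flag[!is.na(flag)]
    dplyr::mutate(prevalence(sum(flag), length(flag), level),
                  outcome = outcome, .before = 1)
  }
  dplyr::bind_rows(
    one("adhd", scores$asrs_positive),
    one("depression", scores$phq_positive)
  )
}
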