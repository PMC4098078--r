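#' Practice index
#'
#' Cumulative writing-practice measure adapted from music-expertise research:
#' `(semester + years_writing) * hours_per_week`.
#'
#' @param semester Semesters of formal creative-writing study.
#' @param years_writing Years of creative-writing practice.
#' @param hours_per_week Weekly writing practice (hours) over recent months.
#' @return Numeric practice index (vectorized).
#' @examples
#' practice_index(7.1, 11.7, 21.0)  # 394.8
#' @export
practice_index <- function(semester, years_writing, hours_per_week) {
  n <- max(length(semester), length(years_writing), length(hours_per_week))
  args <- list(semester = semester, years_writing = years_writing,
               hours_per_week = hours_per_week)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop_restfc(sprintf("`%s` must be non-negative and finite.", nm))
    }
  }
  (rep_len(semester, n) + rep_len(years_writing, n)) * rep_len(hours_per_week, n)
}

#' Consensual creativity rating
#'
#' Grand mean of all judges' visual-analog-scale (0-10) creativity ratings
#' over both in-scanner texts (consensual assessment technique).
#'
#' @param judge_ratings Numeric matrix or data frame, judges x texts
#'   (typically 2 texts), values in \[0, 10\].
#' @return Single numeric rating.
#' @examples
#' creativity_rating(matrix(c(4, 5, 6, 7), nrow = 2))  # 5.5
#' @export
creativity_rating <- function(judge_ratings) {
  m <- as.matrix(judge_ratings)
  check_matrix(m, "judge_ratings")
  if (nrow(m) < 1L || ncol(m) != 2L) {
    stop_restfc("`judge_ratings` must be a judges x 2 (texts) matrix.")
  }
  if (any(m < 0 | m > 10)) {
    stop_restfc("VAS ratings must lie in [0, 10].")
  }
  mean(m)
}

#' Append creativity scores to a cohort table
#'
#' Computes the practice index (`pi_score`) from `semester`, `years_writing`
#' and `hours_per_week`, and the consensual creativity rating (`cr`) from
#' judge rating columns named `j<judge>_a` / `j<judge>_b` (one pair per
#' judge), when those inputs are present.
#'
#' @param cohort Cohort tibble.
#' @return The cohort tibble with `pi_score` and/or `cr` columns appended.
#' @export
add_behavior_scores <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (all(c("semester", "years_writing", "hours_per_week") %in% names(cohort))) {
    cohort$pi_score <- practice_index(cohort$semester, cohort$years_writing,
                                      cohort$hours_per_week)
  }
  judge_a <- sort(grep("^j[0-9]+_a$", names(cohort), value = TRUE))
  judge_b <- sort(grep("^j[0-9]+_b$", names(cohort), value = TRUE))
  if (length(judge_a) && length(judge_a) == length(judge_b)) {
    cohort$cr <- vapply(seq_len(nrow(cohort)), function(i) {
      creativity_rating(cbind(as.numeric(cohort[i, judge_a]),
                              as.numeric(cohort[i, judge_b])))
    }, numeric(1))
  }
  cohort
}
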