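#' Ordinal grades for the quality of a compositional analysis
#'
#' Ascending order of trustworthiness: `unclear` (methodology not
#' accessible), `method_stated` (methodology stated), `detailed` (detailed
#' description of analysis and measuring scope), `detailed_with_series`
#' (detailed description including a series of measurements).
#'
#' @return Character vector of the four grades, worst first.
#' @export
quality_grades <- function() {
  c("unclear", "method_stated", "detailed", "detailed_with_series")
}

#' Default five-level data-quality rubric
#'
#' Composition data for residues are compiled from heterogeneous literature;
#' each residue receives an ordinal quality score from 1 (good) to 5 (not
#' reliable), the best (lowest) level for which it meets all three criteria:
#' number of independent sources, grade of the analyses, and recency of the
#' newest source relative to the assessment's reference year.
#'
#' The default mapping is: level 1 requires more than 2 sources, grade
#' `detailed_with_series`, newest source less than 5 years old; level 2
#' more than 1 source, at least `detailed`, less than 10 years; level 3
#' more than 1 source, at least `method_stated`, less than 20 years;
#' level 4 at least 1 source, at least `method_stated`, less than 30 years;
#' level 5 is the fallback. The rubric is a plain tibble and can be
#' replaced by any alternative whose criteria relax monotonically with the
#' level.
#'
#' @return A tibble with columns `level`, `min_sources` (minimum count of
#'   sources), `min_grade` (minimum analysis grade), `max_age_years`
#'   (newest source must be strictly younger than this many years).
#' @export
default_quality_rubric <- function() {
  tibble(
    level = 1:4,
    min_sources = c(3L, 2L, 2L, 1L),
    min_grade = c("detailed_with_series", "detailed", "method_stated", "method_stated"),
    max_age_years = c(5L, 10L, 20L, 30L)
  )
}

#' Score the data quality of residue composition data
#'
#' Returns, for each residue, the best (lowest) quality level of the rubric
#' for which all three criteria are met; residues meeting no rubric row
#' score 5 (not reliable). The score is monotone: improving any single
#' criterion (more sources, better analysis grade, more recent source)
#' never worsens the level.
#'
#' @param n_sources Integer vector, number of independent literature sources
#'   (>= 1).
#' @param analysis_quality Character vector of grades, see [quality_grades()].
#' @param newest_source_year Integer vector, calendar year of the newest
#'   source.
#' @param reference_year Single calendar year of the assessment; the age of
#'   a residue's data is `reference_year - newest_source_year`.
#' @param rubric Rubric table, see [default_quality_rubric()].
#' @return Integer vector of quality levels in 1..5.
#' @export
#' @examples
#' # >2 sources, detailed incl. series, but 15 years old: recency caps it at 3
#' score_data_quality(3, "detailed_with_series", 2010, reference_year = 2025)
score_data_quality <- function(n_sources, analysis_quality, newest_source_year,
                               reference_year, rubric = default_quality_rubric()) {
  grades <- quality_grades()
  unknown <- !is.na(analysis_quality) & !analysis_quality %in% grades
  if (any(unknown)) {
    abort(sprintf("Unknown analysis_quality grade(s): %s",
                  paste(unique(analysis_quality[unknown]), collapse = ", ")))
  }
  stop_if_not_number(reference_year, "reference_year")
  n <- max(length(n_sources), length(analysis_quality), length(newest_source_year))
  n_sources <- rep_len(n_sources, n)
  analysis_quality <- rep_len(analysis_quality, n)
  newest_source_year <- rep_len(newest_source_year, n)
  if (any(n_sources < 1, na.rm = TRUE)) abort("n_sources must be >= 1.")
  if (any(newest_source_year > reference_year, na.rm = TRUE)) {
    abort("newest_source_year must not exceed reference_year.")
  }
  age <- reference_year - newest_source_year
  grade_rank <- match(analysis_quality, grades)
  rubric <- rubric[order(rubric$level), ]
  out <- rep.int(5L, n)
  for (i in rev(seq_len(nrow(rubric)))) {
    ok <- n_sources >= rubric$min_sources[i] &
      grade_rank >= match(rubric$min_grade[i], grades) &
      age < rubric$max_age_years[i]
    out[which(ok)] <- as.integer(rubric$level[i])
  }
  out[is.na(n_sources) | is.na(grade_rank) | is.na(age)] <- 5L
  out
}

#' Data-quality scores for every residue of a matrix
#'
#' @param matrix A [resource_matrix()] carrying quality metadata columns.
#' @param reference_year Assessment year; defaults to the matrix attribute.
#' @param rubric See [default_quality_rubric()].
#' @return A tibble with columns `id` and `quality_score`.
#' @export
score_matrix_quality <- function(matrix, reference_year = NULL,
                                 rubric = default_quality_rubric()) {
  stopifnot(inherits(matrix, "resource_matrix"))
  reference_year <- reference_year %||% attr(matrix, "reference_year")
  if (is.null(reference_year)) {
    abort("No reference_year: pass one or attach it to the matrix.")
  }
  tibble(
    id = matrix$id,
    quality_score = score_data_quality(matrix$n_sources, matrix$analysis_quality,
                                       matrix$newest_source_year, reference_year,
                                       rubric = rubric)
  )
}
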