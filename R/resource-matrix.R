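#' Construct a validated resource matrix
#'
#' A resource matrix is the central data structure of the assessment: one row
#' per biogenic residue, holding its origin sector, annual technical potential
#' (Mg dry matter per year), the usable share of that potential, a composition
#' profile of MIN/MEAN/MAX mass fractions for each of the seven biochemical
#' fractions (see [residue_fractions()]), and data-quality metadata (number of
#' independent literature sources, grade of the underlying analyses, year of
#' the newest source).
#'
#' Composition values are mass fractions of dry matter in \[0, 1\]; absent
#' values (`NA`) mean "unknown" and are preserved as such. The sum of the
#' present MEAN fractions of a residue may exceed 1 slightly because the
#' fractions come from heterogeneous assays; a sum above 1.05 raises a
#' warning and a sum above 1.20 is rejected as a data error.
#'
#' @param residues A data frame with columns `id`, `name`, `sector`,
#'   `technical_potential` (Mg DM per year), optionally `usable_share`
#'   (default 1), the 21 composition columns `<fraction>_min`,
#'   `<fraction>_mean`, `<fraction>_max` for the seven fractions (missing
#'   columns are created as `NA`), and the quality columns `n_sources`,
#'   `analysis_quality`, `newest_source_year`.
#' @param reference_year Calendar year of the assessment, used as the anchor
#'   for the recency criterion of the data-quality score.
#' @param provenance Free-text note on where the rows come from.
#'
#' @return A tibble of class `resource_matrix` with attributes
#'   `reference_year` and `provenance`.
#' @seealso [read_resource_matrix()], [apply_potential_cutoff()],
#'   [score_data_quality()]
#' @export
resource_matrix <- function(residues, reference_year = NULL, provenance = NULL) {
  x <- as_tibble(residues)
  required <- c("id", "name", "sector", "technical_potential")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"usable_share" %in% names(x)) x$usable_share <- 1
  x$usable_share[is.na(x$usable_share)] <- 1
  for (col in composition_columns()) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  for (col in c("n_sources", "newest_source_year")) {
    if (!col %in% names(x)) x[[col]] <- NA_integer_
  }
  if (!"analysis_quality" %in% names(x)) x$analysis_quality <- NA_character_
  x <- x[, c(required, "usable_share", composition_columns(),
             "n_sources", "analysis_quality", "newest_source_year")]
  validate_residue_rows(x)
  structure(x,
            class = c("resource_matrix", class(as_tibble(x))),
            reference_year = reference_year,
            provenance = provenance)
}

composition_columns <- function() {
  as.vector(t(outer(residue_fractions(), c("min", "mean", "max"), paste, sep = "_")))
}

# row-indexed validation of residue invariants; abort with all diagnostics
validate_residue_rows <- function(x) {
  problems <- character(0)
  bad <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, sprintf("row %d: %s", which(rows), msg))
    }
  }
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    problems <- c(problems, sprintf("duplicated residue id(s): %s", paste(dup, collapse = ", ")))
  }
  bad(is.na(x$id) | x$id == "", "missing id")
  bad(!x$sector %in% residue_sectors(), sprintf(
    "sector not one of {%s}", paste(residue_sectors(), collapse = ", ")))
  bad(!is.na(x$technical_potential) & x$technical_potential < 0, "technical_potential < 0")
  bad(is.na(x$technical_potential), "missing technical_potential")
  bad(x$usable_share <= 0 | x$usable_share > 1, "usable_share outside (0, 1]")
  for (col in composition_columns()) {
    v <- x[[col]]
    bad(!is.na(v) & (v < 0 | v > 1), sprintf("%s outside [0, 1]", col))
  }
  for (fr in residue_fractions()) {
    mn <- x[[paste0(fr, "_min")]]; me <- x[[paste0(fr, "_mean")]]; mx <- x[[paste0(fr, "_max")]]
    complete <- !is.na(mn) & !is.na(me) & !is.na(mx)
    bad(complete & (mn > me | me > mx), sprintf("%s min/mean/max not ordered", fr))
  }
  mean_cols <- paste0(residue_fractions(), "_mean")
  sums <- rowSums(as.matrix(x[, mean_cols]), na.rm = TRUE)
  bad(sums > 1.20, sprintf("sum of mean fractions %.3f exceeds 1.20", sums))
  if (length(problems) > 0) {
    abort(c("Invalid resource matrix:", problems))
  }
  high <- sums > 1.05 & sums <= 1.20
  if (any(high)) {
    warn(sprintf("Sum of mean fractions exceeds 1.05 in row(s) %s (max %.3f).",
                 paste(which(high), collapse = ", "), max(sums[high])))
  }
  invisible(x)
}

#' @export
print.resource_matrix <- function(x, ...) {
  ry <- attr(x, "reference_year")
  cat(sprintf("<resource_matrix> %d residue(s)%s\n", nrow(x),
              if (!is.null(ry)) sprintf(", reference year %s", ry) else ""))
  cat(sprintf("  total technical potential: %s Mg DM/a\n",
              format(signif3(sum(x$technical_potential)), big.mark = ",", scientific = FALSE)))
  print(as_tibble(x), ...)
  invisible(x)
}

# external (file) column header for the technical potential, unit-tagged
.potential_file_col <- "technical_potential_Mg_DM_a"

#' Read a resource matrix from a delimited text file
#'
#' The file is UTF-8 delimited text, comma- or tab-separated (auto-detected
#' from the header line), one row per residue. Expected columns: `id`,
#' `name`, `sector`, `technical_potential_Mg_DM_a`, optionally
#' `usable_share`, the 21 `<fraction>_{min,mean,max}` columns, `n_sources`,
#' `analysis_quality`, `newest_source_year`. Empty cells are unknown values
#' and stay `NA`.
#'
#' @param path Path to the file.
#' @param reference_year Assessment reference year attached to the matrix.
#' @param provenance Provenance note; defaults to the file path.
#' @return A [resource_matrix()].
#' @export
read_resource_matrix <- function(path, reference_year = NULL, provenance = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  char_cols <- intersect(c("id", "name", "sector", "analysis_quality"),
                         strsplit(header, delim, fixed = TRUE)[[1]])
  spec <- setNames(lapply(char_cols, function(.) readr::col_character()), char_cols)
  spec$.default <- readr::col_double()
  # parse problems are collected and reported as errors below
  x <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_types = do.call(readr::cols, spec),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE))
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(c(sprintf("Parse error(s) in %s:", path),
            sprintf("row %d, column %s: expected %s, got '%s'",
                    prob$row, prob$col, prob$expected, prob$actual)))
  }
  if (!.potential_file_col %in% names(x)) {
    abort(sprintf("Missing required column `%s` in %s", .potential_file_col, path))
  }
  names(x)[names(x) == .potential_file_col] <- "technical_potential"
  resource_matrix(x, reference_year = reference_year,
                  provenance = provenance %||% path)
}

#' Write a resource matrix to a delimited text file
#'
#' Round-trips with [read_resource_matrix()]: absent (`NA`) composition
#' values are written as empty cells and read back as `NA`, never coerced
#' to 0.
#'
#' @param matrix A [resource_matrix()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_resource_matrix <- function(matrix, path, delim = ",") {
  stopifnot(inherits(matrix, "resource_matrix"))
  x <- as_tibble(matrix)
  names(x)[names(x) == "technical_potential"] <- .potential_file_col
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}

#' Exclude residues below a technical-potential cutoff
#'
#' The assessment restricts itself to quantitatively relevant residues: all
#' residues with a technical potential below the cutoff (default
#' 250,000 Mg DM per year) are dropped. Residues exactly at the cutoff are
#' retained; row order is preserved, so the operation is idempotent.
#'
#' @param matrix A [resource_matrix()].
#' @param cutoff Minimum technical potential in Mg DM per year; must be >= 0.
#' @return A [resource_matrix()] with the retained residues.
#' @export
apply_potential_cutoff <- function(matrix, cutoff = 250000) {
  stopifnot(inherits(matrix, "resource_matrix"))
  stop_if_not_number(cutoff, "cutoff", nonneg = TRUE)
  keep <- matrix$technical_potential >= cutoff
  out <- matrix[keep, , drop = FALSE]
  resource_matrix(as_tibble(out), reference_year = attr(matrix, "reference_year"),
                  provenance = attr(matrix, "provenance"))
}

#' Summarise suitability classes by mass and share
#'
#' Aggregates the technical potential of the matrix over an assignment of
#' every residue to exactly one suitability class: usable in one of the
#' model processes, principally feasible for bioprocesses, not exploitable,
#' or below the potential cutoff.
#'
#' @param matrix A [resource_matrix()].
#' @param assignments Named character vector mapping every residue id to one
#'   of `"model_process"`, `"principal_feasibility"`, `"not_exploitable"`,
#'   `"below_cutoff"`.
#' @return A tibble with columns `class`, `mass` (Mg DM per year) and
#'   `share` (fractions of the total technical potential; sums to 1).
#' @export
suitability_summary <- function(matrix, assignments) {
  stopifnot(inherits(matrix, "resource_matrix"))
  classes <- c("model_process", "principal_feasibility", "not_exploitable", "below_cutoff")
  unassigned <- setdiff(matrix$id, names(assignments))
  if (length(unassigned) > 0) {
    abort(sprintf("Residue(s) not assigned to a suitability class: %s",
                  paste(unassigned, collapse = ", ")))
  }
  cls <- assignments[matrix$id]
  if (!all(cls %in% classes)) {
    abort(sprintf("Unknown suitability class(es): %s",
                  paste(unique(cls[!cls %in% classes]), collapse = ", ")))
  }
  total <- sum(matrix$technical_potential)
  if (total <= 0) abort("Total technical potential must be > 0.")
  mass <- vapply(classes, function(k) sum(matrix$technical_potential[cls == k]), numeric(1))
  tibble(class = classes, mass = unname(mass), share = unname(mass) / total)
}
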