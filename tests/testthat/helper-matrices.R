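# Build a small resource matrix from compact per-residue specs.
# Each ... argument: list(id, potential, <fraction> = mean value, ...,
# optionally usable = share, sector = sector).
toy_matrix <- function(..., reference_year = 2024L) {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    row <- tibble::tibble(
      id = s$id %||% sprintf("r%02d", i),
      name = s$id %||% sprintf("residue %d", i),
      sector = s$sector %||% "industry",
      technical_potential = s$potential,
      usable_share = s$usable %||% 1,
      n_sources = s$n_sources %||% 2L,
      analysis_quality = s$analysis_quality %||% "detailed",
      newest_source_year = s$newest_source_year %||% 2022L
    )
    for (fr in residue_fractions()) {
      if (!is.null(s[[fr]])) row[[paste0(fr, "_mean")]] <- s[[fr]]
    }
    row
  })
  resource_matrix(dplyr::bind_rows(rows), reference_year = reference_year)
}

`%||%` <- rlang::`%||%`

# columns only: drop provenance/reference-year metadata before comparing
plain_df <- function(m) {
  d <- as.data.frame(m)
  attr(d, "provenance") <- NULL
  attr(d, "reference_year") <- NULL
  d
}

# brute-force oracle: per-residue loop for tier membership
oracle_screen <- function(matrix, rule) {
  fav <- character(0); pos <- character(0)
  for (i in seq_len(nrow(matrix))) {
    v <- matrix[[paste0(rule$fraction, "_mean")]][i]
    if (is.na(v)) next
    hit <- function(thr) if (rule$comparison == "geq") v >= thr else v > thr
    if (hit(rule$favorable)) fav <- c(fav, matrix$id[i])
    else if (hit(rule$possible)) pos <- c(pos, matrix$id[i])
  }
  list(favorable = fav, possible = pos)
}

# brute-force oracle: element-wise pool summation
oracle_pools <- function(matrix, ids, fraction) {
  raw <- 0; frac <- 0
  for (id in ids) {
    i <- match(id, matrix$id)
    m <- matrix$technical_potential[i] * matrix$usable_share[i]
    raw <- raw + m
    frac <- frac + m * matrix[[paste0(fraction, "_mean")]][i]
  }
  list(raw_pool = raw, fraction_pool = frac)
}
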