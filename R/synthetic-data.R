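#' Configuration for the synthetic resource-matrix generator
#'
#' The generator emulates the statistical structure of a cross-sector
#' residue matrix: residues are assigned to sectors by weight, technical
#' potentials are drawn log-uniformly, and composition profiles are drawn
#' on the simplex around sector-specific archetype compositions (woody
#' sectors lignin-heavy, food-industry residues NFC-heavy) with a Dirichlet
#' concentration parameter controlling dispersion. Optional planted-truth
#' constraints force an exact number of residues above a screening
#' threshold with an exact fraction pool, so that screening and pooling can
#' be validated against known ground truth.
#'
#' @param n_residues Number of residues to generate.
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @param sector_weights Named probabilities over [residue_sectors()]
#'   (must sum to 1).
#' @param potential_range Length-2 numeric `(low, high)`, Mg DM per year;
#'   potentials are sampled log-uniformly on this interval.
#' @param archetypes Named list (one entry per sector) of named numeric
#'   vectors over [residue_fractions()]; each must sum to <= 1, the
#'   remainder being unassigned matter (water-solubles, extractives).
#' @param concentration Dirichlet concentration (> 0); larger values give
#'   compositions tighter around the archetype.
#' @param spread_max Maximum half-width of the MIN/MAX band around a mean
#'   fraction; spreads are drawn uniformly on `[0, spread_max]` and clipped
#'   to `[0, 1]`.
#' @param quality List with `n_sources_range` (length 2), `grade_probs`
#'   (named over [quality_grades()]), `max_age_years` (ages drawn uniformly
#'   on `0..max_age_years`).
#' @param planted_truth Optional list of constraints, each a list with
#'   `fraction`, `threshold`, `count` and `pool` (target fraction pool,
#'   Mg per year). Constraints must name distinct fractions and their
#'   counts must sum to at most `n_residues`.
#' @param cutoff_split Optional list with `cutoff` and `n_above`: exactly
#'   `n_above` residues get a potential at or above `cutoff`, the rest
#'   below.
#' @param reference_year Assessment year stamped on the matrix.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_residues, seed,
                             sector_weights = c(agriculture = 0.3, forestry = 0.2,
                                                industry = 0.25,
                                                municipal_waste_sewage = 0.15,
                                                other = 0.1),
                             potential_range = c(5e4, 1.5e7),
                             archetypes = default_archetypes(),
                             concentration = 60,
                             spread_max = 0.08,
                             quality = list(n_sources_range = c(1L, 6L),
                                            grade_probs = c(unclear = 0.1,
                                                            method_stated = 0.3,
                                                            detailed = 0.4,
                                                            detailed_with_series = 0.2),
                                            max_age_years = 25L),
                             planted_truth = NULL,
                             cutoff_split = NULL,
                             reference_year = 2024L) {
  stop_if_not_number(n_residues, "n_residues", positive = TRUE)
  stop_if_not_number(seed, "seed")
  if (!setequal(names(sector_weights), residue_sectors())) {
    abort("`sector_weights` must be named over the five sectors.")
  }
  if (abs(sum(sector_weights) - 1) > 1e-8) abort("`sector_weights` must sum to 1.")
  if (length(potential_range) != 2 || potential_range[1] <= 0 ||
      potential_range[1] >= potential_range[2]) {
    abort("`potential_range` must be (low, high) with 0 < low < high.")
  }
  if (!setequal(names(archetypes), residue_sectors())) {
    abort("`archetypes` must have one entry per sector.")
  }
  for (s in names(archetypes)) {
    a <- archetypes[[s]]
    if (!setequal(names(a), residue_fractions()) || any(a < 0) || sum(a) > 1) {
      abort(sprintf("Archetype for sector `%s` must be non-negative over the seven fractions and sum to <= 1.", s))
    }
  }
  stop_if_not_number(concentration, "concentration", positive = TRUE)
  if (!is.null(planted_truth)) {
    frs <- vapply(planted_truth, function(p) p$fraction, character(1))
    if (anyDuplicated(frs)) abort("Planted constraints must name distinct fractions.")
    if (!all(frs %in% residue_fractions())) abort("Unknown fraction in planted constraint.")
    counts <- vapply(planted_truth, function(p) p$count, numeric(1))
    if (sum(counts) > n_residues) {
      abort("Planted constraint counts exceed n_residues: unsatisfiable.")
    }
    for (p in planted_truth) {
      if (p$threshold <= 0 || p$threshold >= 1) abort("Planted threshold must be in (0, 1).")
      if (p$pool <= 0) abort("Planted pool must be > 0.")
      if (p$count < 1) abort("Planted count must be >= 1.")
    }
  }
  if (!is.null(cutoff_split)) {
    if (cutoff_split$n_above > n_residues || cutoff_split$n_above < 0) {
      abort("`cutoff_split$n_above` must be in 0..n_residues.")
    }
    if (cutoff_split$cutoff <= potential_range[1] ||
        cutoff_split$cutoff >= potential_range[2]) {
      abort("`cutoff_split$cutoff` must lie inside `potential_range`.")
    }
  }
  structure(list(n_residues = as.integer(n_residues), seed = as.integer(seed),
                 sector_weights = sector_weights, potential_range = potential_range,
                 archetypes = archetypes, concentration = concentration,
                 spread_max = spread_max, quality = quality,
                 planted_truth = planted_truth, cutoff_split = cutoff_split,
                 reference_year = as.integer(reference_year)),
            class = "generator_config")
}

#' Default sector composition archetypes
#'
#' Mean composition vectors per sector used by the generator: forestry
#' residues are lignin-heavy (~0.25 lignin), industry residues NFC-heavy
#' (~0.45 NFC), agriculture fibre-heavy, municipal waste mixed, other
#' intermediate. Each sums to below 1; the remainder is unassigned matter.
#'
#' @return Named list of named numeric vectors over [residue_fractions()].
#' @export
default_archetypes <- function() {
  f <- residue_fractions()
  mk <- function(...) setNames(c(...), f)
  list(
    agriculture = mk(0.33, 0.22, 0.12, 0.10, 0.08, 0.02, 0.08),
    forestry = mk(0.42, 0.25, 0.25, 0.01, 0.01, 0.01, 0.02),
    industry = mk(0.08, 0.05, 0.05, 0.45, 0.12, 0.08, 0.05),
    municipal_waste_sewage = mk(0.18, 0.10, 0.12, 0.22, 0.12, 0.08, 0.10),
    other = mk(0.28, 0.18, 0.15, 0.12, 0.08, 0.03, 0.08)
  )
}

# Dirichlet draw via normalized gamma variates; alpha of length k
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-6), rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a synthetic resource matrix with recorded ground truth
#'
#' Draws a matrix according to the configuration; the returned ground-truth
#' record stores, for every planted constraint, the exact set of residues
#' at or above the threshold and the exact raw and fraction pools they
#' imply, as well as the residues above the potential cutoff when a
#' `cutoff_split` is configured. Generation is deterministic for a fixed
#' seed and leaves the caller's random-number state untouched.
#'
#' @param config A [generator_config()].
#' @return A list with elements `matrix` (a [resource_matrix()]) and
#'   `truth` (list with per-constraint memberships and pools).
#' @export
generate_matrix <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_residues
  frs <- residue_fractions()
  sectors <- sample(residue_sectors(), n, replace = TRUE,
                    prob = config$sector_weights[residue_sectors()])
  lo <- log(config$potential_range[1]); hi <- log(config$potential_range[2])
  potential <- exp(runif(n, lo, hi))
  if (!is.null(config$cutoff_split)) {
    cs <- config$cutoff_split
    lc <- log(cs$cutoff)
    above <- seq_len(n) %in% sample.int(n, cs$n_above)
    potential[above] <- exp(runif(sum(above), lc, hi))
    potential[!above] <- exp(runif(sum(!above), lo, lc * (1 - 1e-12)))
    # strict split: nothing below the cutoff may round up to it
    potential[!above] <- pmin(potential[!above], cs$cutoff * (1 - 1e-9))
  }

  means <- matrix(NA_real_, n, length(frs), dimnames = list(NULL, frs))
  for (i in seq_len(n)) {
    arch <- config$archetypes[[sectors[i]]][frs]
    alpha <- c(arch, unassigned = max(1 - sum(arch), 1e-3)) * config$concentration
    draw <- rdirichlet1(alpha)
    means[i, ] <- draw[seq_along(frs)]
  }

  truth <- list(seed = config$seed, constraints = list())
  used <- rep(FALSE, n)
  if (!is.null(config$planted_truth)) {
    for (p in config$planted_truth) {
      idx <- which(!used)[seq_len(p$count)]
      used[idx] <- TRUE
      j <- match(p$fraction, frs)
      f_new <- runif(p$count, p$threshold, min(1, p$threshold + 0.15))
      for (k in seq_along(idx)) {
        i <- idx[k]
        old <- means[i, j]
        scale <- (1 - f_new[k]) / max(1 - old, 1e-9)
        means[i, ] <- means[i, ] * scale
        means[i, j] <- f_new[k]
      }
      # exact pool: equal fraction-mass weights across the designated set
      potential[idx] <- (p$pool / p$count) / f_new
      # everyone else stays strictly below the threshold
      others <- setdiff(seq_len(n), idx)
      margin <- min(0.01, p$threshold / 2)
      too_high <- others[means[others, j] >= p$threshold]
      means[too_high, j] <- p$threshold - margin
      truth$constraints[[p$fraction]] <- list(
        fraction = p$fraction, threshold = p$threshold,
        ids = sprintf("res_%04d", idx),
        raw_pool = sum(potential[idx]), fraction_pool = p$pool)
    }
  }
  if (!is.null(config$cutoff_split)) {
    truth$above_cutoff <- sprintf("res_%04d", which(
      potential >= config$cutoff_split$cutoff))
  }

  spread <- matrix(runif(n * length(frs), 0, config$spread_max), n)
  mins <- pmax(means - spread, 0)
  maxs <- pmin(means + spread, 1)

  q <- config$quality
  residues <- tibble(
    id = sprintf("res_%04d", seq_len(n)),
    name = sprintf("synthetic residue %d", seq_len(n)),
    sector = sectors,
    technical_potential = potential,
    usable_share = 1
  )
  for (j in seq_along(frs)) {
    residues[[paste0(frs[j], "_min")]] <- mins[, j]
    residues[[paste0(frs[j], "_mean")]] <- means[, j]
    residues[[paste0(frs[j], "_max")]] <- maxs[, j]
  }
  residues$n_sources <- sample(seq(q$n_sources_range[1], q$n_sources_range[2]),
                               n, replace = TRUE)
  residues$analysis_quality <- sample(names(q$grade_probs), n, replace = TRUE,
                                      prob = q$grade_probs)
  residues$newest_source_year <- config$reference_year -
    sample(0:q$max_age_years, n, replace = TRUE)

  mat <- resource_matrix(residues, reference_year = config$reference_year,
                         provenance = sprintf("synthetic matrix, seed %d", config$seed))
  list(matrix = mat, truth = truth)
}

#' Write a generator ground-truth record as sidecar JSON
#'
#' @param truth The `truth` element of a [generate_matrix()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
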