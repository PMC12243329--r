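#' Default end-to-end run configuration
#'
#' Ties the stages together for the three model processes: the packaged
#' German matrix, the default screening rules, the default conversion
#' chains (baseline and, for the lignin chain, idealized), and the default
#' market and land-use constants. The default cutoff is 0 because the
#' packaged matrix is already the post-cutoff excerpt of the national
#' residue compilation (which applied the 250,000 Mg DM/a relevance cutoff
#' before the composition assessment; the oil-waste stream is retained
#' there despite its small pooled mass). When assessing a full,
#' unfiltered matrix, set `cutoff = 250000`.
#' The two oil-fed chains are restricted to their respective feed streams
#' via `id_filter` (citric acid to oil waste, alpha-ketoglutarate to
#' biodiesel glycerol); filters are `NULL` for the other processes.
#'
#' Every element can be overridden; [read_run_config()] builds the same
#' structure from a YAML file.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    matrix = NULL, # NULL = packaged German matrix
    generator = NULL, # alternatively a generator_config
    cutoff = 0, # packaged matrix is already post-cutoff; use 250000 for raw matrices
    rules = default_screening_rules(),
    market = default_market_constants(),
    not_exploitable_ids = character(0),
    report_digits = 3L,
    processes = list(
      adipic_from_lignin = list(
        rule = "adipic_from_lignin", chain = "adipic_from_lignin",
        product = "adipic_acid", scenarios = c("baseline", "idealized"),
        id_filter = NULL,
        land = list(spec = "trunk_wood", feedstock_content = 0.25)),
      carboxylic_from_nfc = list(
        rule = "carboxylic_from_nfc", chain = "carboxylic_from_nfc",
        product = "c6_c8_acids", scenarios = "baseline", id_filter = NULL,
        land = list(spec = "corn_silage", feedstock_content = 1)),
      ca_from_oil = list(
        rule = "tca_from_oil", chain = "ca_from_oil", product = "citric_acid",
        scenarios = "baseline", id_filter = "oil_waste",
        land = list(spec = "rapeseed", feedstock_content = 1)),
      kga_from_glycerol = list(
        rule = "tca_from_oil", chain = "kga_from_glycerol", product = NULL,
        scenarios = "baseline", id_filter = "glycerol_biodiesel", land = NULL)
    )
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may override any element of [default_run_config()]: scalar
#' settings (`cutoff`, `report_digits`, `matrix` as a path), screening
#' rules (named entries with `fraction`, `favorable`, `possible`,
#' `comparison`), market constants (`gdp_share`, `global_production`,
#' `demand_override`, `land` entries with `crop`, `areal_yield`,
#' `content_factor`) and process definitions. Unspecified elements keep
#' their defaults.
#'
#' @param path Path to the YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  if (!is.null(raw$rules)) {
    for (nm in names(raw$rules)) {
      r <- raw$rules[[nm]]
      cfg$rules[[nm]] <- screening_rule(r$fraction, r$favorable,
                                        r$possible %||% r$favorable,
                                        r$comparison %||% "geq")
    }
    raw$rules <- NULL
  }
  if (!is.null(raw$market)) {
    m <- raw$market
    if (!is.null(m$gdp_share)) cfg$market$gdp_share <- m$gdp_share
    if (!is.null(m$global_production)) {
      cfg$market$global_production[names(m$global_production)] <-
        unlist(m$global_production)
    }
    if (!is.null(m$demand_override)) {
      cfg$market$demand_override[names(m$demand_override)] <-
        unlist(m$demand_override)
    }
    if (!is.null(m$land)) {
      for (nm in names(m$land)) {
        l <- m$land[[nm]]
        cfg$market$land[[nm]] <- land_use_spec(l$crop %||% nm, l$areal_yield,
                                               l$content_factor %||% 1)
      }
    }
    raw$market <- NULL
  }
  if (!is.null(raw$processes)) {
    for (nm in names(raw$processes)) {
      cfg$processes[[nm]] <- modifyList(cfg$processes[[nm]] %||% list(),
                                        raw$processes[[nm]])
    }
    raw$processes <- NULL
  }
  cfg <- modifyList(cfg, raw)
  structure(cfg, class = "run_config")
}

resolve_matrix <- function(config) {
  if (!is.null(config$matrix)) {
    if (inherits(config$matrix, "resource_matrix")) return(config$matrix)
    return(read_resource_matrix(config$matrix))
  }
  if (!is.null(config$generator)) return(generate_matrix(config$generator)$matrix)
  german_residue_matrix()
}

#' Run the full residue-to-product assessment
#'
#' Executes the pipeline for every configured process: potential cutoff,
#' composition screening into favorable/possible tiers, raw and fraction
#' mass pooling, conversion-chain runs for each configured scenario,
#' raw-material utilization ratios, national demand, demand-coverage and
#' required-fraction shares, and land-use savings; plus the matrix-level
#' suitability summary and data-quality tally. The run is deterministic
#' given the configuration and input matrix.
#'
#' @param config A `run_config`, see [default_run_config()].
#' @return An object of class `assessment_report`: a list of tibbles
#'   (`pools`, `flows`, `market`, `suitability`, `quality_tally`), the
#'   per-process `flow_results` (for ledger and Sankey export), and a
#'   `constants_log` recording every constant used.
#' @export
run_assessment <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  full <- resolve_matrix(config)
  mat <- apply_potential_cutoff(full, config$cutoff)
  log_lines <- c(
    sprintf("residueflow assessment, %d residue(s) in, %d after cutoff %s Mg DM/a",
            nrow(full), nrow(mat), format(config$cutoff, big.mark = ",")),
    sprintf("gdp_share = %g", config$market$gdp_share))

  pools <- list(); flows <- list(); market_rows <- list(); flow_results <- list()
  selected_ids <- character(0)

  for (pname in names(config$processes)) {
    p <- config$processes[[pname]]
    rule <- config$rules[[p$rule]]
    if (is.null(rule)) abort(sprintf("[%s] no screening rule `%s` configured.", pname, p$rule))
    sel <- screen_feedstocks(mat, rule, quiet = TRUE)
    keep <- function(ids) if (is.null(p$id_filter)) ids else intersect(ids, p$id_filter)
    ids_fav <- keep(sel$favorable)
    ids_ext <- keep(c(sel$favorable, sel$possible))
    selected_ids <- union(selected_ids, ids_ext)
    log_lines <- c(log_lines, sprintf(
      "[%s] rule %s fav %s %.3g / pos %.3g; favorable: %s; possible: %s",
      pname, rule$fraction, if (rule$comparison == "geq") ">=" else ">",
      rule$favorable, rule$possible, paste(ids_fav, collapse = ","),
      paste(setdiff(ids_ext, ids_fav), collapse = ",")))

    tiers <- list(favorable = ids_fav, extended = ids_ext)
    for (tname in names(tiers)) {
      pool <- tryCatch(pool_masses(mat, tiers[[tname]], rule$fraction),
                       error = function(e) abort(sprintf("[%s/%s] %s", pname, tname,
                                                         conditionMessage(e))))
      pools[[paste(pname, tname)]] <- tibble(
        process = pname, tier = tname, n_residues = length(tiers[[tname]]),
        raw_pool = pool$raw_pool, fraction_pool = pool$fraction_pool)
      for (scen in p$scenarios) {
        chain <- default_process_chains(scen)[[p$chain]]
        if (is.null(chain)) abort(sprintf("[%s] no chain `%s`.", pname, p$chain))
        res <- run_chain(pool$fraction_pool, chain)
        flow_results[[paste(pname, tname, scen, sep = "_")]] <- res
        eta <- if (pool$raw_pool > 0) res$product / pool$raw_pool else NA_real_
        flows[[paste(pname, tname, scen)]] <- tibble(
          process = pname, tier = tname, scenario = scen,
          chain_factor = chain_factor(chain),
          input_pool = pool$fraction_pool, product = res$product,
          side_stream_total = res$side_stream_total,
          co_substrate_total = res$co_substrate_total, eta_rm = eta)
      }
    }

    # market block (baseline chain, favorable tier product)
    if (!is.null(p$product)) {
      gp <- config$market$global_production[[p$product]]
      demand <- if (!is.null(config$market$demand_override) &&
                    p$product %in% names(config$market$demand_override)) {
        config$market$demand_override[[p$product]]
      } else if (!is.null(gp)) {
        national_demand(gp, config$market$gdp_share)
      } else NA_real_
      fav_pool <- pools[[paste(pname, "favorable")]]
      base_chain <- default_process_chains("baseline")[[p$chain]]
      fav_flow <- flows[[paste(pname, "favorable", "baseline")]]
      coverage <- req_share <- land_ha <- NA_real_
      if (!is.na(demand)) {
        if (fav_flow$product > 0) coverage <- demand_coverage_share(demand, fav_flow$product)
        if (fav_pool$fraction_pool > 0) {
          req_share <- required_fraction_share(demand, base_chain, fav_pool$fraction_pool)
        }
        if (!is.null(p$land)) {
          land_ha <- land_saving(fav_flow$product, base_chain,
                                 p$land$feedstock_content,
                                 config$market$land[[p$land$spec]])
        }
        log_lines <- c(log_lines, sprintf(
          "[%s] product %s: demand %s Mg/a", pname, p$product,
          format(demand, big.mark = ",")))
      }
      market_rows[[pname]] <- tibble(
        process = pname, product = p$product, national_demand = demand,
        product_potential = fav_flow$product, coverage_share = coverage,
        required_fraction_share = req_share, land_saving_ha = land_ha)
    }
  }

  assignments <- vapply(full$id, function(i) {
    if (full$technical_potential[match(i, full$id)] < config$cutoff) "below_cutoff"
    else if (i %in% config$not_exploitable_ids) "not_exploitable"
    else if (i %in% selected_ids) "model_process"
    else "principal_feasibility"
  }, character(1))
  suit <- suitability_summary(full, assignments)

  quality <- if (!anyNA(full$analysis_quality) && !is.null(attr(full, "reference_year"))) {
    sc <- score_matrix_quality(full)
    dplyr::count(sc, .data$quality_score, name = "n_residues")
  } else tibble(quality_score = integer(0), n_residues = integer(0))

  structure(list(
    n_residues_in = nrow(full), n_residues_after_cutoff = nrow(mat),
    cutoff = config$cutoff,
    pools = dplyr::bind_rows(pools), flows = dplyr::bind_rows(flows),
    market = dplyr::bind_rows(market_rows), suitability = suit,
    quality_tally = quality, flow_results = flow_results,
    report_digits = config$report_digits, constants_log = log_lines
  ), class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  d <- x$report_digits
  cat(sprintf("<assessment_report> %d residues (%d after cutoff %s Mg DM/a)\n",
              x$n_residues_in, x$n_residues_after_cutoff,
              format(x$cutoff, big.mark = ",")))
  cat("\nMass pools and products (Mg/a):\n")
  f <- dplyr::left_join(x$flows,
                        x$pools[, c("process", "tier", "raw_pool")],
                        by = c("process", "tier"))
  show <- round_numeric(f, d)
  print(as.data.frame(show[, c("process", "tier", "scenario", "raw_pool",
                               "input_pool", "product", "eta_rm")]), row.names = FALSE)
  cat("\nMarket context:\n")
  print(as.data.frame(round_numeric(x$market, d)), row.names = FALSE)
  cat("\nSuitability (share of total technical potential):\n")
  print(as.data.frame(dplyr::mutate(x$suitability, share = signif(.data$share, d))),
        row.names = FALSE)
  invisible(x)
}

#' Write an assessment report to disk
#'
#' Writes a combined summary table (`summary_table.csv`, mirroring raw
#' material / relevant fraction / product / utilization ratio, rounded to
#' the configured significant figures), one ledger table and one node-link
#' flow JSON per process and scenario, a full-precision machine-readable
#' `report.json`, and `run_log.txt` echoing every constant used. Output is
#' deterministic: re-running with the same config yields identical files.
#'
#' @param report An `assessment_report` from [run_assessment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_assessment_report <- function(report, dir) {
  stopifnot(inherits(report, "assessment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- report$report_digits
  paths <- character(0)

  combined <- dplyr::left_join(report$flows,
                               report$pools[, c("process", "tier", "raw_pool")],
                               by = c("process", "tier"))
  combined <- combined[, c("process", "tier", "scenario", "raw_pool", "input_pool",
                           "chain_factor", "product", "eta_rm")]
  names(combined)[names(combined) == "input_pool"] <- "fraction_pool"
  p <- file.path(dir, "summary_table.csv")
  readr::write_csv(round_numeric(combined, d), p); paths <- c(paths, p)

  p <- file.path(dir, "market_table.csv")
  readr::write_csv(round_numeric(report$market, d), p)
  paths <- c(paths, p)

  for (nm in names(report$flow_results)) {
    res <- report$flow_results[[nm]]
    p <- file.path(dir, sprintf("ledger_%s.csv", nm))
    readr::write_csv(mass_ledger_report(res), p); paths <- c(paths, p)
    p <- file.path(dir, sprintf("flow_%s.json", nm))
    flow_to_json(res, p); paths <- c(paths, p)
  }

  p <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    n_residues_in = report$n_residues_in,
    n_residues_after_cutoff = report$n_residues_after_cutoff,
    cutoff = report$cutoff, pools = report$pools, flows = report$flows,
    market = report$market, suitability = report$suitability,
    quality_tally = report$quality_tally
  ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  p <- file.path(dir, "run_log.txt")
  writeLines(report$constants_log, p); paths <- c(paths, p)
  invisible(paths)
}
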