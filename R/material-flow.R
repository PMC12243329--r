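#' Define a single conversion step
#'
#' A step converts an input mass stream into an output mass stream with a
#' dimensionless mass-per-mass conversion factor. Factors above 1 are
#' legitimate and indicate incorporation of co-substrates (e.g., water and
#' oxygen during microbial oxidation of oils to citric acid).
#'
#' @param name Step name, e.g. `"lignin depolymerization"`.
#' @param input Label of the incoming mass stream.
#' @param output Label of the outgoing mass stream.
#' @param factor Conversion factor > 0 (Mg out per Mg in).
#' @return An object of class `process_step`.
#' @export
process_step <- function(name, input, output, factor) {
  stop_if_not_number(factor, "factor", positive = TRUE)
  structure(list(name = name, input = input, output = output, factor = factor),
            class = "process_step")
}

#' Define a multi-step conversion chain
#'
#' A chain takes the mass pool of one target biomass fraction and applies an
#' ordered sequence of conversion steps to it, yielding a product mass.
#'
#' @param name Chain name, e.g. `"polymer bricks from lignin"`.
#' @param target_fraction The fraction feeding the chain, one of
#'   [residue_fractions()].
#' @param steps Non-empty list of [process_step()] objects.
#' @param scenario `"baseline"` (state of the art) or `"idealized"`
#'   (prospected technological improvements).
#' @param product Product name; defaults to the last step's output label.
#' @return An object of class `process_chain`.
#' @export
process_chain <- function(name, target_fraction, steps,
                          scenario = c("baseline", "idealized"), product = NULL) {
  scenario <- match.arg(scenario)
  if (!target_fraction %in% residue_fractions()) {
    abort(sprintf("Unknown target fraction `%s`.", target_fraction))
  }
  if (length(steps) == 0) abort("A chain needs at least one step.")
  ok <- vapply(steps, inherits, logical(1), what = "process_step")
  if (!all(ok)) abort("`steps` must be a list of process_step objects.")
  structure(list(name = name, target_fraction = target_fraction, steps = steps,
                 scenario = scenario,
                 product = product %||% steps[[length(steps)]]$output),
            class = "process_chain")
}

#' @export
print.process_chain <- function(x, ...) {
  cat(sprintf("<process_chain> %s [%s], from %s, overall factor %.5g\n",
              x$name, x$scenario, x$target_fraction, chain_factor(x)))
  for (s in x$steps) {
    cat(sprintf("  %-28s %s -> %s  x %.3g\n", s$name, s$input, s$output, s$factor))
  }
  invisible(x)
}

#' Overall conversion factor of a chain
#'
#' The product of the step factors; an empty suffix multiplies to 1.
#'
#' @param chain A [process_chain()].
#' @return A single dimensionless number.
#' @export
#' @examples
#' chain_factor(default_process_chains()$adipic_from_lignin) # 0.59*0.35*0.68*0.61
chain_factor <- function(chain) {
  stopifnot(inherits(chain, "process_chain"))
  prod(vapply(chain$steps, function(s) s$factor, numeric(1)))
}

#' Run a mass pool through a conversion chain
#'
#' Pushes `input_pool` Mg per year through the chain's steps, recording a
#' contiguous per-step mass ledger (each step's output is the next step's
#' input). The step delta (input minus output) is a side stream when
#' positive and co-substrate uptake when negative (factor > 1).
#'
#' @param input_pool Mass pool feeding the chain, Mg per year; must be >= 0.
#' @param chain A [process_chain()].
#' @return An object of class `flow_result`: list with `chain`,
#'   `input_pool`, `ledger` (tibble of step, input, output, delta),
#'   `product`, `side_stream_total` and `co_substrate_total`.
#' @export
run_chain <- function(input_pool, chain) {
  stopifnot(inherits(chain, "process_chain"))
  stop_if_not_number(input_pool, "input_pool", nonneg = TRUE)
  factors <- vapply(chain$steps, function(s) s$factor, numeric(1))
  outputs <- input_pool * cumprod(factors)
  inputs <- c(input_pool, head(outputs, -1L))
  delta <- inputs - outputs
  ledger <- tibble(
    step = vapply(chain$steps, function(s) s$name, character(1)),
    input_label = vapply(chain$steps, function(s) s$input, character(1)),
    output_label = vapply(chain$steps, function(s) s$output, character(1)),
    input = inputs, output = outputs, delta = delta
  )
  structure(list(chain = chain, input_pool = input_pool, ledger = ledger,
                 product = outputs[length(outputs)],
                 side_stream_total = sum(pmax(delta, 0)),
                 co_substrate_total = sum(pmax(-delta, 0))),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> %s [%s]\n", x$chain$name, x$chain$scenario))
  cat(sprintf("  input %s -> product %s Mg/a (side streams %s, co-substrates %s)\n",
              format(signif3(x$input_pool), big.mark = ","),
              format(signif3(x$product), big.mark = ","),
              format(signif3(x$side_stream_total), big.mark = ","),
              format(signif3(x$co_substrate_total), big.mark = ",")))
  invisible(x)
}

#' Raw-material utilization ratio of a bioprocess
#'
#' The utilization ratio eta_RM relates the product mass to the raw-material
#' mass it came from: `eta_rm = m_p / m_rm` (Mg product per Mg raw
#' material). It may exceed 1 when the process incorporates co-substrates.
#'
#' @param product Product mass `m_p`, Mg per year (>= 0).
#' @param raw_pool Raw-material mass `m_rm`, Mg per year (> 0).
#' @return A list of class `utilization_ratio` with `eta_rm`, `m_p`, `m_rm`.
#' @export
#' @examples
#' utilization_ratio(188000, 156000) # citric acid from oil waste, ~1.2
utilization_ratio <- function(product, raw_pool) {
  stop_if_not_number(product, "product", nonneg = TRUE)
  if (!is.numeric(raw_pool) || length(raw_pool) != 1L || is.na(raw_pool) || raw_pool <= 0) {
    abort("`raw_pool` must be > 0: the utilization ratio is undefined for an empty pool.")
  }
  structure(list(eta_rm = product / raw_pool, m_p = product, m_rm = raw_pool),
            class = "utilization_ratio")
}

#' @export
print.utilization_ratio <- function(x, ...) {
  cat(sprintf("<utilization_ratio> eta_RM = %.3g Mg/Mg (%s / %s)\n", x$eta_rm,
              format(signif3(x$m_p), big.mark = ","),
              format(signif3(x$m_rm), big.mark = ",")))
  invisible(x)
}

#' Per-fraction conversion factor from a whole-feedstock yield observation
#'
#' Converts an observed whole-feedstock yield into a factor on the target
#' fraction: a feedstock of `raw_mass` containing `nfc_mass` of the fraction
#' that yielded `acid_mass` of product implies `acid_mass / nfc_mass` Mg
#' product per Mg fraction. This is the extrapolation basis of the
#' fermentation factor for medium-chain carboxylic acids (1000 kg apple
#' pomace silage containing 345 kg NFC yield 32 kg acids, i.e. 0.093).
#'
#' @param raw_mass Whole-feedstock mass (> 0), any mass unit.
#' @param nfc_mass Mass of the target fraction in the feedstock (> 0,
#'   <= `raw_mass`), same unit.
#' @param acid_mass Observed product mass (> 0), same unit.
#' @return The per-fraction conversion factor (dimensionless).
#' @export
#' @examples
#' nfc_yield_basis(1000, 345, 32) # ~0.093
nfc_yield_basis <- function(raw_mass, nfc_mass, acid_mass) {
  stop_if_not_number(raw_mass, "raw_mass", positive = TRUE)
  stop_if_not_number(nfc_mass, "nfc_mass", positive = TRUE)
  stop_if_not_number(acid_mass, "acid_mass", positive = TRUE)
  if (nfc_mass > raw_mass) abort("`nfc_mass` cannot exceed `raw_mass`.")
  acid_mass / nfc_mass
}

#' Tabular mass ledger of a chain run
#'
#' Renders the per-step ledger of a [run_chain()] result with a totals row
#' (product, total side streams, total co-substrate uptake), suitable for a
#' material-flow figure.
#'
#' @param result A `flow_result` from [run_chain()].
#' @return A tibble with columns `step`, `input`, `output`, `delta`;
#'   the final row `"TOTAL"` carries product, side-stream total and (as a
#'   negative delta) co-substrate total.
#' @export
mass_ledger_report <- function(result) {
  stopifnot(inherits(result, "flow_result"))
  dplyr::bind_rows(
    result$ledger[, c("step", "input", "output", "delta")],
    tibble(step = "TOTAL", input = result$input_pool, output = result$product,
           delta = result$side_stream_total - result$co_substrate_total)
  )
}

#' Export a chain run as node-link flow JSON
#'
#' Writes (or returns) a node-link representation of the mass flow — nodes
#' are the stream labels, links carry the step masses, side streams and
#' co-substrate inflows — suitable for Sankey rendering.
#'
#' @param result A `flow_result` from [run_chain()].
#' @param path Optional output path; when `NULL` the list is returned.
#' @return The node-link list, invisibly when written to `path`.
#' @export
flow_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "flow_result"))
  led <- result$ledger
  nodes <- unique(c(led$input_label, led$output_label, "side stream", "co-substrate"))
  links <- list()
  for (i in seq_len(nrow(led))) {
    links[[length(links) + 1L]] <- list(source = led$input_label[i],
                                        target = led$output_label[i],
                                        step = led$step[i], mass = led$output[i])
    if (led$delta[i] > 0) {
      links[[length(links) + 1L]] <- list(source = led$input_label[i],
                                          target = "side stream",
                                          step = led$step[i], mass = led$delta[i])
    } else if (led$delta[i] < 0) {
      links[[length(links) + 1L]] <- list(source = "co-substrate",
                                          target = led$output_label[i],
                                          step = led$step[i], mass = -led$delta[i])
    }
  }
  out <- list(chain = result$chain$name, scenario = result$chain$scenario,
              unit = "Mg/a", nodes = lapply(nodes, function(n) list(id = n)),
              links = links)
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Default conversion chains for the three model processes
#'
#' Encodes the state-of-the-art conversion factors of the model processes:
#'
#' * adipic acid from lignin: lignin recovery from lignin-rich residues by
#'   organosolv decomposition (0.59, applied to the lignin fraction pool),
#'   base-catalyzed depolymerization to phenolic monomers (0.35, idealized
#'   0.50), electrochemical hydrogenation to cyclohexanols (0.68, idealized
#'   0.85) and microbial conversion to adipic acid (0.61, idealized 0.99);
#' * medium-chain (C6/C8) carboxylic acids from NFC by anaerobic
#'   mixed-culture fermentation (0.093 per Mg NFC, extrapolated from apple
#'   pomace silage, see [nfc_yield_basis()]);
#' * citric acid from waste oil by *Yarrowia lipolytica* (1.32; the
#'   wastewater process-water variant runs at 1.03) and alpha-ketoglutarate
#'   from raw glycerol (0.44).
#'
#' The idealized scenario replaces only the three factors with prospected
#' improvements (lignin depolymerization and the electrochemical/microbial
#' conversions); all other steps are unchanged.
#'
#' @param scenario `"baseline"` or `"idealized"`.
#' @return Named list of [process_chain()] objects: `adipic_from_lignin`,
#'   `carboxylic_from_nfc`, `ca_from_oil`, `ca_from_oil_wastewater`,
#'   `kga_from_glycerol`.
#' @export
default_process_chains <- function(scenario = c("baseline", "idealized")) {
  scenario <- match.arg(scenario)
  ideal <- scenario == "idealized"
  list(
    adipic_from_lignin = process_chain(
      "polymer bricks from lignin", "lignin", scenario = scenario, steps = list(
        process_step("biomass decomposition", "total lignin", "lignin fraction", 0.59),
        process_step("lignin depolymerization", "lignin fraction", "phenolic monomers",
                     if (ideal) 0.50 else 0.35),
        process_step("electrochemical conversion", "phenolic monomers",
                     "cyclohexanol (incl. derivatives)", if (ideal) 0.85 else 0.68),
        process_step("microbial conversion", "cyclohexanol (incl. derivatives)",
                     "adipic acid", if (ideal) 0.99 else 0.61))),
    carboxylic_from_nfc = process_chain(
      "carboxylic acids from NFC", "nfc", scenario = scenario, steps = list(
        process_step("anaerobic fermentation", "NFC", "C6/C8 carboxylic acids", 0.093))),
    ca_from_oil = process_chain(
      "citric acid from waste oil", "fats_oils", scenario = scenario, steps = list(
        process_step("microbial conversion", "waste oil", "citric acid", 1.32))),
    ca_from_oil_wastewater = process_chain(
      "citric acid from waste oil (wastewater process water)", "fats_oils",
      scenario = scenario, steps = list(
        process_step("microbial conversion", "waste oil", "citric acid", 1.03))),
    kga_from_glycerol = process_chain(
      "alpha-ketoglutarate from glycerol", "fats_oils", scenario = scenario,
      steps = list(
        process_step("microbial conversion", "raw glycerol", "alpha-ketoglutarate", 0.44)))
  )
}
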