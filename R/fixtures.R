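#' Packaged matrix of German residues for the three model processes
#'
#' Loads the packaged resource matrix of the 20 German biogenic residues
#' that are feasible feedstocks for the three model processes: ten
#' lignin-rich residues (bark, wood-processing by-products, industrial
#' waste wood, brewery residues, deciduous and coniferous logging residues,
#' landscape wood, waste wood, and — at the relaxed threshold — green waste
#' and leaves), eight NFC-rich residues (bakery, starch, milk-processing,
#' sugar and bioethanol residues, kitchen/canteen waste, cattle solid
#' manure, roadside stalks) and the two oil/glycerol streams (oil waste,
#' biodiesel glycerol).
#'
#' The relevant composition fractions, the usable share of the starch
#' residues (0.8, the potato-pulp share) and the per-residue source counts
#' are published values. The per-residue technical potentials are
#' *synthetic*: the publicly available compilation prints only pooled
#' tonnages, so the packaged potentials were constructed to reproduce the
#' published pool totals exactly (see [reference_pools()]). The non-relevant
#' composition fractions and the analysis-grade/source-year metadata are
#' likewise representative synthetic values. Treat per-residue masses as
#' illustrative; pooled masses as the published figures.
#'
#' @return A [resource_matrix()] of 20 residues, reference year 2024.
#' @export
#' @examples
#' m <- german_residue_matrix()
#' screen_feedstocks(m, default_screening_rules()$adipic_from_lignin)
german_residue_matrix <- function() {
  path <- system.file("extdata", "german_residues_synthetic_potentials.csv",
                      package = "residueflow", mustWork = TRUE)
  read_resource_matrix(path, reference_year = 2024L,
                       provenance = "packaged German residue matrix (synthetic per-residue potentials)")
}

#' Published pool totals and product potentials for the model processes
#'
#' The pooled tonnages of the published assessment, used as report inputs
#' where per-residue data cannot reproduce them: for each process the raw
#' pool and relevant-fraction pool of the favorable tier and of the
#' extended (favorable plus possible) tier, and the printed biogenic
#' product potentials. All masses in Mg per year.
#'
#' Two published figures are internally inconsistent with the conversion
#' factors and are carried verbatim for reference only: the C6/C8 product
#' potential of 210,000 Mg/a does not equal the favorable NFC pool times
#' the fermentation factor (2.7e6 x 0.093 = 251,100), and the extended NFC
#' fraction pool of 4.0e6 does not follow from the possible residues'
#' compositions.
#'
#' @return Nested named list: `adipic` (`favorable`/`extended` raw and
#'   fraction pools, `product_baseline`, `product_idealized`), `carboxylic`
#'   (same structure, products for favorable/extended tiers), `tca` (per
#'   stream raw pool, fraction pool, product), and `total_raw_extended`.
#' @export
reference_pools <- function() {
  list(
    adipic = list(
      favorable = list(raw_pool = 31.2e6, fraction_pool = 7.8e6),
      extended = list(raw_pool = 42.7e6, fraction_pool = 10.1e6),
      product_baseline = 665000, product_idealized = 2.5e6
    ),
    carboxylic = list(
      favorable = list(raw_pool = 6.9e6, fraction_pool = 2.7e6),
      extended = list(raw_pool = 16.6e6, fraction_pool = 4.0e6),
      product_favorable = 210000, product_extended = 368000
    ),
    tca = list(
      oil_waste = list(raw_pool = 156000, fraction_pool = 142000, product = 188000),
      glycerol = list(raw_pool = 277000, fraction_pool = 263000, product = 116000)
    ),
    total_raw_extended = 42.7e6 + 16.6e6 + 156000 + 277000,
    # total technical potential of all 77 residues in the national compilation
    monitor_total = 108.8e6
  )
}
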