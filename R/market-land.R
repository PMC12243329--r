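#' Break global production down to national demand
#'
#' National production figures for bulk chemicals are rarely public; the
#' assessment approximates national demand as the national share of global
#' gross domestic product applied to global production (for Germany,
#' ca. 3%).
#'
#' @param global_production Global annual production, Mg per year (> 0).
#' @param gdp_share National GDP share, in (0, 1\]; default 0.03.
#' @return National demand, Mg per year.
#' @export
#' @examples
#' national_demand(4.5e6) # adipic acid: 135,000 Mg/a
national_demand <- function(global_production, gdp_share = 0.03) {
  stop_if_not_number(global_production, "global_production", positive = TRUE)
  stop_if_not_number(gdp_share, "gdp_share", positive = TRUE)
  if (gdp_share > 1) abort("`gdp_share` must be in (0, 1].")
  global_production * gdp_share
}

#' Share of a fraction pool needed to meet a demand
#'
#' Inverts the conversion chain: meeting `demand` Mg of product requires
#' `demand / chain_factor(chain)` Mg of the target fraction, reported as a
#' share of the available fraction pool. Shares above 1 (demand exceeding
#' the pool) are reported unclamped with a warning.
#'
#' @param demand Product demand, Mg per year (>= 0).
#' @param chain A [process_chain()].
#' @param fraction_pool Available fraction pool, Mg per year (> 0).
#' @return Dimensionless share.
#' @export
#' @examples
#' ch <- default_process_chains()$adipic_from_lignin
#' required_fraction_share(135000, ch, 7.8e6) # ~0.20 of the lignin pool
required_fraction_share <- function(demand, chain, fraction_pool) {
  stop_if_not_number(demand, "demand", nonneg = TRUE)
  stop_if_not_number(fraction_pool, "fraction_pool", positive = TRUE)
  share <- (demand / chain_factor(chain)) / fraction_pool
  if (share > 1) warn(sprintf("Required fraction share %.3g exceeds 1: demand outstrips the pool.", share))
  share
}

#' Demand as a share of the biogenic product potential
#'
#' How much of the product potential from residues would have to be realized
#' to cover the national demand. Shares above 1 are reported unclamped with
#' a warning.
#'
#' @param demand Product demand, Mg per year (>= 0).
#' @param product_potential Biogenic product potential, Mg per year (> 0).
#' @return Dimensionless share.
#' @export
#' @examples
#' demand_coverage_share(54000, 210000) # ~0.257
demand_coverage_share <- function(demand, product_potential) {
  stop_if_not_number(demand, "demand", nonneg = TRUE)
  stop_if_not_number(product_potential, "product_potential", positive = TRUE)
  share <- demand / product_potential
  if (share > 1) warn(sprintf("Coverage share %.3g exceeds 1: demand outstrips the potential.", share))
  share
}

#' Define a land-use specification for a displaced crop
#'
#' Captures the areal yield of the crop (or biomass) the residue-based
#' production would displace, and the content factor (dry-matter share or
#' oil content) that converts the areal yield to the relevant feedstock
#' basis. The effective yield is their product.
#'
#' @param crop Crop or biomass name.
#' @param areal_yield Areal yield, Mg per hectare per year (> 0), on the
#'   stated (fresh or dry) basis.
#' @param content_factor Dimensionless content applied to the areal yield,
#'   in (0, 1\]; default 1.
#' @return A list of class `land_use_spec` with `crop`, `areal_yield`,
#'   `content_factor` and the derived `effective_yield`.
#' @export
land_use_spec <- function(crop, areal_yield, content_factor = 1) {
  stop_if_not_number(areal_yield, "areal_yield", positive = TRUE)
  stop_if_not_number(content_factor, "content_factor", positive = TRUE)
  if (content_factor > 1) abort("`content_factor` must be in (0, 1].")
  structure(list(crop = crop, areal_yield = areal_yield,
                 content_factor = content_factor,
                 effective_yield = areal_yield * content_factor),
            class = "land_use_spec")
}

#' Land area saved by residue-based production
#'
#' Producing `product_demand` Mg of product from residues instead of from a
#' dedicated crop saves the area that crop would occupy:
#' `product_demand / (chain_factor(chain) * feedstock_content *
#' effective_yield)` hectares, where `feedstock_content` is the relevant
#' fraction of the displaced biomass (e.g., an average lignin share of 0.25
#' for trunk wood) and the effective yield comes from the [land_use_spec()].
#' When the content is already folded into the spec's `content_factor`,
#' pass `feedstock_content = 1`.
#'
#' @param product_demand Product mass, Mg per year (>= 0).
#' @param chain A [process_chain()].
#' @param feedstock_content Relevant-fraction content of the displaced
#'   biomass, in (0, 1\].
#' @param land A [land_use_spec()].
#' @return Saved area in hectares.
#' @export
#' @examples
#' ch <- default_process_chains()$adipic_from_lignin
#' land_saving(650000, ch, 0.25, land_use_spec("trunk wood", 10)) # > 3e6 ha
land_saving <- function(product_demand, chain, feedstock_content, land) {
  stop_if_not_number(product_demand, "product_demand", nonneg = TRUE)
  stop_if_not_number(feedstock_content, "feedstock_content", positive = TRUE)
  stopifnot(inherits(land, "land_use_spec"))
  if (feedstock_content > 1) abort("`feedstock_content` must be in (0, 1].")
  denom <- chain_factor(chain) * feedstock_content * land$effective_yield
  if (denom <= 0) abort("Zero denominator in land saving.")
  product_demand / denom
}

#' Default market and land-use constants
#'
#' Global production volumes (adipic acid 4.5 Mio Mg/a; C6/C8 carboxylic
#' acids 1.8 Mio Mg/a market size; citric acid 2.0 Mio Mg/a), the default
#' national GDP share of 0.03, an explicit citric-acid national demand of
#' 68,000 Mg/a (the published figure, which differs from 3% of the global
#' market), and land-use specs: trunk wood at 10 Mg/ha/a; corn silage at
#' 40 Mg/ha/a fresh with a dry-matter share of 0.35; rapeseed at
#' 40 Mg/ha/a with an oil content of 0.446 (kept verbatim from the source
#' compilation although it is far above typical agronomic rapeseed yields —
#' treat the resulting areas as what this constant implies, not as field
#' expectations).
#'
#' @return A named list with elements `gdp_share`, `global_production`
#'   (named vector, Mg/a), `demand_override` (named vector, Mg/a) and
#'   `land` (named list of [land_use_spec()]).
#' @export
default_market_constants <- function() {
  list(
    gdp_share = 0.03,
    global_production = c(adipic_acid = 4.5e6, c6_c8_acids = 1.8e6,
                          citric_acid = 2.0e6),
    demand_override = c(citric_acid = 68000),
    land = list(
      trunk_wood = land_use_spec("trunk wood", 10),
      corn_silage = land_use_spec("corn silage", 40, content_factor = 0.35),
      rapeseed = land_use_spec("rapeseed", 40, content_factor = 0.446)
    )
  )
}
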