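#' Define a composition-threshold screening rule
#'
#' A process is fed by residues rich in one target fraction. A rule carries
#' two thresholds on the MEAN mass fraction: residues at or above (or
#' strictly above, for `comparison = "gt"`) the favorable threshold form the
#' favorable tier; residues meeting only the relaxed possible threshold form
#' the possible tier. Setting both thresholds equal collapses the possible
#' tier.
#'
#' @param fraction One of [residue_fractions()].
#' @param favorable Favorable threshold, mass fraction of DM in \[0, 1\].
#' @param possible Possible threshold, defaults to `favorable`; must not
#'   exceed it.
#' @param comparison `"geq"` (at or above, default) or `"gt"` (strictly
#'   above).
#' @return An object of class `screening_rule`.
#' @export
#' @examples
#' screening_rule("lignin", favorable = 0.23, possible = 0.20)
screening_rule <- function(fraction, favorable, possible = favorable,
                           comparison = c("geq", "gt")) {
  comparison <- match.arg(comparison)
  if (!fraction %in% residue_fractions()) {
    abort(sprintf("Unknown fraction `%s`; must be one of: %s", fraction,
                  paste(residue_fractions(), collapse = ", ")))
  }
  stop_if_not_number(favorable, "favorable", nonneg = TRUE)
  stop_if_not_number(possible, "possible", nonneg = TRUE)
  if (favorable > 1 || possible > favorable) {
    abort("Thresholds must satisfy 0 <= possible <= favorable <= 1.")
  }
  structure(list(fraction = fraction, favorable = favorable,
                 possible = possible, comparison = comparison),
            class = "screening_rule")
}

#' @export
print.screening_rule <- function(x, ...) {
  op <- if (x$comparison == "geq") ">=" else ">"
  cat(sprintf("<screening_rule> %s: favorable %s %.3g, possible %s %.3g (g/g DM)\n",
              x$fraction, op, x$favorable, op, x$possible))
  invisible(x)
}

#' Default screening rules for the three model processes
#'
#' Adipic-acid production wants lignin-rich feedstock (favorable at a mean
#' lignin fraction of at least 0.23 g/g DM, possible at 0.20); medium-chain
#' carboxylic-acid fermentation wants NFC-rich feedstock (favorable 0.20,
#' possible 0.16); microbial conversion of waste oils and glycerol to TCA
#' intermediates requires an oil/glycerol content strictly above 0.90, with
#' no relaxed tier.
#'
#' @return Named list of [screening_rule()] objects
#'   (`adipic_from_lignin`, `carboxylic_from_nfc`, `tca_from_oil`).
#' @export
default_screening_rules <- function() {
  list(
    adipic_from_lignin = screening_rule("lignin", favorable = 0.23, possible = 0.20),
    carboxylic_from_nfc = screening_rule("nfc", favorable = 0.20, possible = 0.16),
    tca_from_oil = screening_rule("fats_oils", favorable = 0.90, possible = 0.90,
                                  comparison = "gt")
  )
}

#' Screen a resource matrix into favorable and possible tiers
#'
#' Residues whose MEAN value of the rule's fraction meets the favorable
#' threshold go to the favorable tier; residues meeting only the possible
#' threshold go to the possible tier. Residues without a MEAN value for the
#' fraction are silently ineligible (reported via a message). Matrix order
#' is preserved within each tier; the tiers are disjoint by construction.
#'
#' @param matrix A [resource_matrix()].
#' @param rule A [screening_rule()].
#' @param quiet Suppress the message about ineligible residues.
#' @return An object of class `tiered_selection`: a list with character
#'   vectors `favorable` and `possible` of residue ids, plus the rule.
#' @export
screen_feedstocks <- function(matrix, rule, quiet = FALSE) {
  stopifnot(inherits(matrix, "resource_matrix"), inherits(rule, "screening_rule"))
  v <- matrix[[paste0(rule$fraction, "_mean")]]
  eligible <- !is.na(v)
  if (!quiet && any(!eligible)) {
    inform(sprintf("%d residue(s) without a mean %s value are ineligible for this rule.",
                   sum(!eligible), rule$fraction))
  }
  meets <- function(x, thr) if (rule$comparison == "geq") x >= thr else x > thr
  fav <- eligible & meets(v, rule$favorable)
  pos <- eligible & meets(v, rule$possible) & !fav
  structure(list(favorable = matrix$id[fav], possible = matrix$id[pos], rule = rule),
            class = "tiered_selection")
}

#' @export
print.tiered_selection <- function(x, ...) {
  cat(sprintf("<tiered_selection> %s: %d favorable, %d possible\n",
              x$rule$fraction, length(x$favorable), length(x$possible)))
  if (length(x$favorable)) cat("  favorable:", paste(x$favorable, collapse = ", "), "\n")
  if (length(x$possible)) cat("  possible: ", paste(x$possible, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate raw-material and fraction mass pools over a residue selection
#'
#' The raw pool is the sum of `technical_potential * usable_share` over the
#' selected residues; the fraction pool additionally weights each residue by
#' its MEAN value of the target fraction. Pools are additive over disjoint
#' id sets.
#'
#' @param matrix A [resource_matrix()].
#' @param ids Character vector of residue ids (may be empty).
#' @param fraction One of [residue_fractions()].
#' @return A list of class `mass_pools` with elements `raw_pool` and
#'   `fraction_pool`, both in Mg DM per year.
#' @export
pool_masses <- function(matrix, ids, fraction) {
  stopifnot(inherits(matrix, "resource_matrix"))
  if (!fraction %in% residue_fractions()) {
    abort(sprintf("Unknown fraction `%s`.", fraction))
  }
  missing_ids <- setdiff(ids, matrix$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("Unknown residue id(s): %s", paste(missing_ids, collapse = ", ")))
  }
  rows <- matrix[match(ids, matrix$id), , drop = FALSE]
  means <- rows[[paste0(fraction, "_mean")]]
  if (length(ids) > 0 && anyNA(means)) {
    abort(sprintf("Residue(s) without a mean %s value: %s", fraction,
                  paste(rows$id[is.na(means)], collapse = ", ")))
  }
  usable <- rows$technical_potential * rows$usable_share
  structure(list(raw_pool = sum(usable), fraction_pool = sum(usable * means)),
            class = "mass_pools")
}

#' @export
print.mass_pools <- function(x, ...) {
  cat(sprintf("<mass_pools> raw %s, fraction %s Mg DM/a\n",
              format(signif3(x$raw_pool), big.mark = ","),
              format(signif3(x$fraction_pool), big.mark = ",")))
  invisible(x)
}
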