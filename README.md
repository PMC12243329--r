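# residueflow

Material-flow assessment of biogenic residues as feedstocks for
biotechnological production.

## The problem

More than 100 million Mg of dry biogenic residues accrue every year in
Germany alone — straw, manure, logging residues, waste wood, industrial
by-products, municipal bio-waste. Whether such a stream can feed a given
bioprocess is decided by its biochemical composition: lignin-rich streams
suit routes to aromatic platform chemicals (e.g., adipic acid via
electrochemical and microbial conversion of lignin monomers), streams rich
in non-fibrous carbohydrates (NFC) suit anaerobic fermentation to
medium-chain (C6/C8) carboxylic acids, and nearly pure waste-oil or
glycerol streams suit yeast-based production of TCA-cycle intermediates
(citric acid, α-ketoglutarate). `residueflow` gives resource analysts and
bioprocess engineers a tested pipeline for this assessment:

* a **resource matrix** data structure: per residue a sector, an annual
  technical potential (Mg dry matter per year), MIN/MEAN/MAX mass
  fractions for cellulose, hemicellulose, lignin, NFC, protein, fats/oils
  and ash, and a five-level data-quality score computed from a
  configurable rubric (sources × analysis grade × recency);
* **screening** into favorable/possible tiers by composition thresholds,
  with raw and fraction mass pools `Σ pᵢuᵢ` and `Σ pᵢuᵢxᵢ`;
* **conversion chains**: a pool `m₀` pushed through steps with
  mass-per-mass factors `f_k` yields `m_P = m₀ · Π f_k`, a contiguous
  per-step ledger, side streams, co-substrate uptake (factors > 1), and
  the raw-material utilization ratio `η_RM = m_P / m_RM`;
* **market and land context**: GDP-share national demand, coverage and
  required-fraction shares, and land-use savings versus dedicated crops;
* a **seeded synthetic generator** with plantable ground truth (exact tier
  counts and pools) for end-to-end validation, and a packaged matrix of
  the 20 German residues feasible for the three model processes.

## Worked example: adipic acid from lignin-rich residues

```r
library(residueflow)

m <- german_residue_matrix()
sel <- screen_feedstocks(m, default_screening_rules()$adipic_from_lignin)
sel
#> <tiered_selection> lignin: 8 favorable, 2 possible
#>   favorable: bark, wood_processing, industrial_waste_wood, brewery_residues,
#>              logging_residues_deciduous, landscape_wood, waste_wood,
#>              logging_residues_coniferous
#>   possible:  green_waste, leaves

pool <- pool_masses(m, sel$favorable, "lignin")
pool
#> <mass_pools> raw 31,200,000, fraction 7,800,000 Mg DM/a

res <- run_chain(pool$fraction_pool,
                 default_process_chains("baseline")$adipic_from_lignin)
mass_ledger_report(res)
#>   step                         input   output    delta
#> 1 biomass decomposition      7800000 4602000  3198000
#> 2 lignin depolymerization    4602000 1610700  2991300
#> 3 electrochemical conversion 1610700 1095276   515424
#> 4 microbial conversion       1095276  668118.  427158.
#> 5 TOTAL                      7800000  668118. 7131882.

utilization_ratio(res$product, pool$raw_pool)
#> <utilization_ratio> eta_RM = 0.0214 Mg/Mg (668,000 / 31,200,000)
```

Read: of the 31.2 Mio Mg/a of favorable lignin-rich residues, the 7.8 Mio
Mg/a lignin fraction would yield about 668,000 Mg/a adipic acid under
state-of-the-art conversion factors — only 2.1% of the raw-material mass
ends up in the product, the rest leaves as side streams (which is why the
package also reports them; they remain feedstock for other process lines).
Meeting the estimated national demand of `national_demand(4.5e6) =
135,000` Mg/a would need about 20% of that lignin pool, or 7% under the
idealized factors. The whole multi-process assessment, including demand
coverage and land-use savings, runs as `run_assessment()` and writes
tables, per-step ledgers, Sankey-ready node-link JSON and a run log via
`write_assessment_report()`. A command-line wrapper is available through
`rf_cli()` (subcommands `assess`, `generate`, `score`, `validate`).

Note on the packaged matrix: per-residue potentials are reconstructed so
that the pooled tonnages match the published assessment exactly (the
public record prints pools, not rows); see `?german_residue_matrix`.

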