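---
title: "Assessing biogenic residues as bioprocess feedstocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing biogenic residues as bioprocess feedstocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residueflow)
```

## The assessment model

A circular bioeconomy must turn residues — straw, manure, logging residues,
industrial by-products, municipal bio-waste — into feedstocks for material
production without claiming additional arable land. Whether a residue is a
viable feedstock for a given bioprocess is decided almost entirely by its
biochemical composition: lignin-rich streams feed aromatic-platform routes,
streams rich in non-fibrous carbohydrates (NFC) feed anaerobic carboxylate
fermentation, and nearly pure oil or glycerol streams feed yeast-based
production of tricarboxylic-acid (TCA) cycle intermediates.

`residueflow` implements that assessment as a four-stage deterministic
pipeline:

1. **Resource matrix.** Each residue is a row: origin sector, annual
   technical potential (Mg dry matter per year — the mass available under
   current technical and non-technical constraints), a usable share, and a
   MIN/MEAN/MAX mass fraction (g per g DM) for each of the seven fractions
   cellulose, hemicellulose, lignin, NFC, protein, fats/oils and ash.
   Unknown values stay `NA`; they are never imputed.
2. **Screening.** A `screening_rule` puts residues whose MEAN value of the
   target fraction meets a strict threshold into a *favorable* tier and
   those meeting only a relaxed threshold into a *possible* tier. Mass
   pools are then accumulated: the raw pool
   $\sum_i p_i u_i$ and the fraction pool $\sum_i p_i u_i x_i$, with $p_i$
   the technical potential, $u_i$ the usable share and $x_i$ the mean
   fraction.
3. **Conversion chains.** A `process_chain` is an ordered list of steps,
   each with a dimensionless mass-per-mass conversion factor $f_k$. A pool
   $m_0$ pushed through the chain yields the product
   $m_P = m_0 \prod_k f_k$ and a contiguous per-step ledger (step $k$'s
   output is step $k{+}1$'s input). Positive step deltas are side streams;
   negative deltas (factors above 1, as in the oxidative conversion of oils
   to citric acid) book co-substrate uptake. The raw-material utilization
   ratio is $\eta_{RM} = m_P / m_{RM}$.
4. **Market and land context.** National demand is approximated as the
   national GDP share (default 3%) of global production. Coverage and
   required-fraction shares are plain quotients, reported unclamped — a
   share above 1 is meaningful (demand outstrips the resource) and only
   triggers a warning. Land savings divide the product mass by
   chain factor × feedstock content × areal yield of the displaced crop.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| potential cutoff | 250,000 (raw matrices) | Mg DM/a | restricts the assessment to quantitatively relevant residues; the packaged matrix is already post-cutoff, so the default run config uses 0 |
| lignin rule | favorable ≥ 0.23, possible ≥ 0.20 | g/g DM | reproduces the published tier membership: eight woody/brewery residues favorable, green waste and leaves (both at 0.20) possible |
| NFC rule | favorable ≥ 0.20, possible ≥ 0.16 | g/g DM | the published inclusion threshold is 0.16; the favorable boundary separates cattle manure and roadside stalks (0.16) into the possible tier |
| oil rule | > 0.90, no possible tier | g/g DM | yeast conversion needs nearly pure oil/glycerol; strict comparison per the stated "> 90%" requirement |
| lignin chain | 0.59, 0.35, 0.68, 0.61 | Mg/Mg | decomposition, depolymerization, electrochemical and microbial conversion; idealized scenario: 0.50/0.85/0.99 for the last three |
| NFC fermentation | 0.093 | Mg acid/Mg NFC | extrapolated from a whole-feedstock observation (1000 kg silage with 345 kg NFC giving 32 kg acids); see `nfc_yield_basis()` |
| oil/glycerol chains | 1.32 (CA), 1.03 (CA, wastewater), 0.44 (KGA) | Mg/Mg | single-step microbial conversions |
| GDP share | 0.03 | — | breaks global production down to the national level |
| land constants | wood 10; corn silage 40 × 0.35 DM; rapeseed 40 × 0.446 oil | Mg/ha/a | the rapeseed areal yield is kept verbatim from the source compilation although it is far above agronomic norms; treat derived areas as implied by that constant |

A deliberate modelling decision: the 0.59 decomposition factor is applied
to the **lignin fraction pool**, not to whole-residue mass. It is a lignin
recovery efficiency of the organosolv fractionation; applied this way the
favorable lignin pool of 7.8 Mio Mg/a yields 668,000 Mg/a adipic acid,
consistent (within the 3-significant-figure rounding of the pools) with
the published 665,000 Mg/a.

The idealized scenario replaces only the three factors with stated
prospected improvements; every other step keeps its baseline value. The
scenario mechanics therefore cannot silently change a process the
improvements do not concern.

## The data-quality score

Composition data come from heterogeneous literature. Each residue gets an
ordinal score 1 (good) … 5 (not reliable): the best level whose three
criteria — number of sources, analysis grade, recency — all hold. The
packaged rubric (`default_quality_rubric()`) uses level 1 = more than 2
sources, detailed analysis including measurement series, newest source
under 5 years old; level 2 = >1 source, detailed, <10 y; level 3 = >1,
method stated, <20 y; level 4 = ≥1, method stated, <30 y; level 5
otherwise. The exact grid is an interpretation of the stated tier
boundaries (the published grid itself is only available as a figure), so
the rubric is an argument, not a constant. Any replacement must relax
monotonically with the level; the test suite checks monotonicity of the
returned score in each criterion over the whole grid.

## The packaged German matrix

`german_residue_matrix()` ships the 20 residues feasible for the three
model processes, with their published relevant-fraction values and source
counts. Two caveats, both flagged in the function documentation:

* **Per-residue technical potentials are reconstructed.** The public
  record prints pooled tonnages only. The packaged potentials were chosen
  to reproduce the published pools *exactly* (favorable lignin
  31.2 Mio Mg/a raw and 7.8 Mio Mg/a lignin; extended 42.7/10.1; favorable
  NFC 6.9/2.7; oil waste 156,000/142,000; glycerol 277,000/263,000), so
  pooled results are faithful while individual rows are illustrative.
* **Two published figures do not close from the printed constants.** The
  C6/C8 product potential (210,000 Mg/a) differs from favorable NFC pool ×
  factor (2.7 Mio × 0.093 = 251,100), and the extended NFC fraction pool
  (4.0 Mio) does not follow from the possible residues' compositions. The
  engine always computes from factors; the printed potentials are kept in
  `reference_pools()` and used only where they are themselves the input
  (e.g., coverage shares of the printed potentials).

`reference_pools()` also carries the compilation-wide total potential
(108.8 Mio Mg/a) so that suitability shares can be expressed against the
full national residue base.

## The synthetic generator

`generate_matrix()` draws matrices that *structurally* resemble the real
one: sector weights, log-uniform potentials spanning the observed two
orders of magnitude, and compositions drawn on the simplex from
sector-specific Dirichlet archetypes (forestry lignin-heavy at ~0.25,
food-industry NFC-heavy at ~0.45) with a concentration parameter
controlling spread. MIN/MAX are the mean ∓ a uniform half-width clipped to
[0, 1]. Planted-truth constraints are satisfied by exact post-hoc
adjustment of a designated subset: their target fraction is redrawn at or
above the threshold (other fractions rescaled so the simplex bound holds),
their potentials are set so the fraction pool equals the target exactly,
and every other residue is clipped strictly below the threshold. The
ground-truth record then contains the exact memberships and pools, which
screening and pooling must recover bit-exactly — the package's end-to-end
parameter-recovery test.

What the generator does **not** emulate: correlations between potential
and composition, temporal trends, measurement error structure (MIN/MEAN/MAX
from real assay series are not symmetric), or the real compilation's
nomenclature. Passing the recovery tests therefore demonstrates the
pipeline's arithmetic and bookkeeping on realistic-shaped data, not the
validity of any particular literature value.

## Numerical choices and degenerate inputs

* All internal computation is unrounded; report tables round to 3
  significant figures (configurable), and machine-readable outputs keep
  full precision.
* Composition sums of present MEAN values warn above 1.05 and error above
  1.20 — heterogeneous assays need not close exactly, gross violations are
  data errors.
* The potential cutoff keeps the boundary value (`>=`), preserving the
  published count semantics, and is idempotent.
* Empty selections pool to (0, 0); `utilization_ratio()` refuses a zero
  raw pool rather than returning `NaN`; `run_chain(0, chain)` returns an
  all-zero ledger.
* Mass conservation (input = product + side streams) is asserted only for
  chains whose factors are all ≤ 1; factors above 1 are conserved jointly
  with the booked co-substrate uptake.
* Generation restores the caller's RNG state, so seeding the generator
  does not perturb surrounding code.

## Problem sizes

The test suite exercises matrices up to n = 1000 residues against
brute-force screening/pooling oracles and n = 1500 for the statistical
sector-share check; the full suite and the reproduction script each run in
well under a minute on a single CPU. These sizes comfortably bracket the
real problem (77 residues nationally; a few hundred at continental scale).

## Known limitations

* No pollutant/inhibitor assessment: feedstock suitability is judged on
  composition only.
* No allocation: a residue qualifying for several processes is counted in
  each process's pool; competition between processes is not modelled.
* No kinetics, titers, energy balances or costs — the chains are pure mass
  cascades.
* The CA national demand is carried as an explicit constant (68,000 Mg/a)
  because the published figure is not 3% of the published global market;
  derived quantities that inherit this inconsistency are not part of the
  reproduction set.
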