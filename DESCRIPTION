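Package: residueflow
Title: Material Flow Assessment of Biogenic Residues for Bioprocesses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the potential of biogenic residues (from
    agriculture, forestry, industry and municipal waste) as feedstocks for
    biotechnological production. Encodes a cross-sector resource matrix of
    residues with biochemical composition fractions (cellulose,
    hemicellulose, lignin, non-fibrous carbohydrates, protein, fats/oils,
    ash) and a five-level data-quality score; screens feedstocks by
    composition thresholds into favorable and possible tiers; pushes
    fraction mass pools through multi-stage conversion chains to estimate
    product potentials, side streams and raw-material utilization ratios;
    and relates product potentials to national demand and land-use savings.
    Includes a seeded synthetic-matrix generator with plantable ground
    truth for end-to-end validation, and a packaged matrix of German
    residues for the three model processes (adipic acid from lignin,
    medium-chain carboxylic acids from non-fibrous carbohydrates, and
    citric acid / alpha-ketoglutarate from waste oils and glycerol).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
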