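test_that("the packaged German matrix loads and validates", {
  m <- german_residue_matrix()
  expect_s3_class(m, "resource_matrix")
  expect_equal(nrow(m), 20L)
  expect_setequal(unique(m$sector), intersect(residue_sectors(), unique(m$sector)))
  # oil waste and glycerol carry the relevant oil/glycerol fractions
  expect_equal(m$fats_oils_mean[m$id == "oil_waste"], 0.91)
  expect_equal(m$fats_oils_mean[m$id == "glycerol_biodiesel"], 0.95)
  # the starch stream is the only one with a reduced usable share
  expect_equal(m$usable_share[m$id == "starch_residues"], 0.8)
  expect_equal(sum(m$usable_share < 1), 1L)
})

test_that("save/load round-trips a matrix field-for-field, preserving NA", {
  m <- german_residue_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_resource_matrix(m, path)
  m2 <- read_resource_matrix(path, reference_year = attr(m, "reference_year"))
  expect_equal(plain_df(m2), plain_df(m))
  # absent MAX values stay absent, never coerced to 0
  expect_true(anyNA(m$lignin_max))
  expect_identical(is.na(m2$lignin_max), is.na(m$lignin_max))
  # tab-delimited round-trip too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_resource_matrix(m, path2, delim = "\t")
  expect_equal(plain_df(read_resource_matrix(path2)), plain_df(m))
})

test_that("round-trip identity holds for generated matrices", {
  for (seed in c(3L, 17L)) {
    gen <- generate_matrix(generator_config(n_residues = 40, seed = seed))
    path <- withr::local_tempfile(fileext = ".csv")
    write_resource_matrix(gen$matrix, path)
    back <- read_resource_matrix(path)
    expect_equal(plain_df(back), plain_df(gen$matrix), tolerance = 1e-12)
  }
})

test_that("an empty file with header only yields an empty matrix", {
  m <- toy_matrix(list(id = "a", potential = 1e6, lignin = 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_resource_matrix(m[0, ], path)
  m0 <- read_resource_matrix(path)
  expect_equal(nrow(m0), 0L)
})

test_that("validation rejects out-of-range values with row diagnostics", {
  bad <- tibble::tibble(id = "x", name = "x", sector = "industry",
                        technical_potential = 1e6, lignin_mean = 1.3)
  expect_error(resource_matrix(bad), "lignin_mean outside")
  neg <- tibble::tibble(id = "x", name = "x", sector = "industry",
                        technical_potential = -5)
  expect_error(resource_matrix(neg), "technical_potential < 0")
  dup <- tibble::tibble(id = c("x", "x"), name = "x", sector = "industry",
                        technical_potential = 1e6)
  expect_error(resource_matrix(dup), "duplicated residue id")
  expect_error(resource_matrix(tibble::tibble(id = "x", name = "x",
                                              sector = "nowhere",
                                              technical_potential = 1)),
               "sector")
  unordered <- tibble::tibble(id = "x", name = "x", sector = "industry",
                              technical_potential = 1e6, lignin_min = 0.5,
                              lignin_mean = 0.3, lignin_max = 0.6)
  expect_error(resource_matrix(unordered), "not ordered")
})

test_that("composition sums warn above 1.05 and error above 1.20", {
  high <- tibble::tibble(id = "x", name = "x", sector = "industry",
                         technical_potential = 1e6, cellulose_mean = 0.6,
                         lignin_mean = 0.5)
  expect_warning(resource_matrix(high), "exceeds 1.05")
  worse <- tibble::tibble(id = "x", name = "x", sector = "industry",
                          technical_potential = 1e6, cellulose_mean = 0.7,
                          lignin_mean = 0.6)
  expect_error(resource_matrix(worse), "exceeds 1.20")
})

test_that("missing required columns and non-numeric fields are format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name,sector\na,b,industry", path)
  expect_error(read_resource_matrix(path), "technical_potential_Mg_DM_a")
  writeLines(c("id,name,sector,technical_potential_Mg_DM_a",
               "a,b,industry,lots"), path)
  expect_error(read_resource_matrix(path), "Parse error")
})

test_that("the potential cutoff keeps the boundary, preserves order, is idempotent", {
  m <- toy_matrix(list(id = "a", potential = 300000, lignin = 0.3),
                  list(id = "b", potential = 250000, lignin = 0.3),
                  list(id = "c", potential = 100000, lignin = 0.3))
  cut <- apply_potential_cutoff(m, 250000)
  expect_identical(cut$id, c("a", "b"))
  expect_identical(apply_potential_cutoff(m, 0)$id, m$id)
  expect_equal(plain_df(apply_potential_cutoff(cut, 250000)),
               plain_df(cut))
  expect_error(apply_potential_cutoff(m, -1), ">= 0")
  # retained mass is non-increasing in the cutoff
  cuts <- c(0, 1e5, 2.5e5, 5e5, 1e6)
  masses <- vapply(cuts, function(k) {
    sum(apply_potential_cutoff(m, k)$technical_potential)
  }, numeric(1))
  expect_true(all(diff(masses) <= 0))
})

test_that("a generator-planted cutoff split is recovered by the cutoff filter", {
  cfg <- generator_config(n_residues = 77, seed = 11,
                          cutoff_split = list(cutoff = 2.5e5, n_above = 35))
  gen <- generate_matrix(cfg)
  kept <- apply_potential_cutoff(gen$matrix, 2.5e5)
  expect_equal(nrow(kept), 35L)
  expect_setequal(kept$id, gen$truth$above_cutoff)
})

test_that("suitability shares sum to 1, masses to the total, order-invariant", {
  m <- toy_matrix(list(id = "a", potential = 59.7e6, lignin = 0.3),
                  list(id = "b", potential = 42.6e6, lignin = 0.1),
                  list(id = "c", potential = 4.1e6, lignin = 0.1),
                  list(id = "d", potential = 2.4e6, lignin = 0.1))
  asg <- c(a = "model_process", b = "principal_feasibility",
           c = "not_exploitable", d = "below_cutoff")
  s <- suitability_summary(m, asg)
  expect_equal(sum(s$share), 1, tolerance = 1e-9)
  expect_equal(sum(s$mass), sum(m$technical_potential))
  # shares match the published feasibility split within half a percentage point
  expect_equal(s$share[s$class == "model_process"], 0.548, tolerance = 0.005 / 0.548)
  expect_equal(s$share[s$class == "principal_feasibility"], 0.392,
               tolerance = 0.005 / 0.392)
  # order invariance
  m_rev <- resource_matrix(plain_df(m)[4:1, ])
  expect_equal(suitability_summary(m_rev, asg), s)
  # degenerate splits
  one <- suitability_summary(m, c(a = "model_process", b = "model_process",
                                  c = "model_process", d = "model_process"))
  expect_equal(one$share[one$class == "model_process"], 1)
  expect_error(suitability_summary(m, asg[-1]), "not assigned")
  expect_error(suitability_summary(m, c(asg[-1], a = "maybe")), "Unknown suitability")
})
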