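test_that("the default assessment reproduces the published summary table", {
  rep <- run_assessment()
  f <- rep$flows
  get <- function(p, t, s, col) f[[col]][f$process == p & f$tier == t & f$scenario == s]
  # adipic acid from lignin: baseline on the favorable pool, idealized on the extended
  expect_equal(get("adipic_from_lignin", "favorable", "baseline", "product"),
               665000, tolerance = 0.01)
  expect_equal(get("adipic_from_lignin", "extended", "idealized", "product"),
               2.5e6, tolerance = 0.01)
  expect_equal(get("adipic_from_lignin", "favorable", "baseline", "eta_rm"),
               0.021, tolerance = 0.02)
  # TCA intermediates
  expect_equal(get("ca_from_oil", "favorable", "baseline", "product"),
               188000, tolerance = 0.01)
  expect_equal(get("ca_from_oil", "favorable", "baseline", "eta_rm"),
               1.20, tolerance = 0.005)
  expect_equal(get("kga_from_glycerol", "favorable", "baseline", "product"),
               116000, tolerance = 0.01)
  expect_equal(get("kga_from_glycerol", "favorable", "baseline", "eta_rm"),
               0.42, tolerance = 0.005)
  # pools mirror the published tonnages
  p <- rep$pools
  gp <- function(proc, tier, col) p[[col]][p$process == proc & p$tier == tier]
  expect_equal(gp("adipic_from_lignin", "favorable", "raw_pool"), 31.2e6)
  expect_equal(gp("adipic_from_lignin", "favorable", "fraction_pool"), 7.8e6)
  expect_equal(gp("adipic_from_lignin", "extended", "raw_pool"), 42.7e6)
  expect_equal(gp("adipic_from_lignin", "extended", "fraction_pool"), 10.1e6)
  expect_equal(gp("carboxylic_from_nfc", "favorable", "raw_pool"), 6.9e6)
  expect_equal(gp("carboxylic_from_nfc", "favorable", "fraction_pool"), 2.7e6)
  expect_equal(gp("ca_from_oil", "favorable", "raw_pool"), 156000)
  expect_equal(gp("ca_from_oil", "favorable", "fraction_pool"), 142000,
               tolerance = 0.001)
  expect_equal(gp("kga_from_glycerol", "favorable", "raw_pool"), 277000)
  expect_equal(gp("kga_from_glycerol", "favorable", "fraction_pool"), 263000,
               tolerance = 0.001)
})

test_that("reported ratios are recomputable from the reported masses", {
  rep <- run_assessment()
  f <- dplyr::left_join(rep$flows, rep$pools[, c("process", "tier", "raw_pool")],
                        by = c("process", "tier"))
  ok <- f$raw_pool > 0
  expect_equal(f$eta_rm[ok], f$product[ok] / f$raw_pool[ok], tolerance = 1e-9)
  expect_equal(f$product, f$input_pool * f$chain_factor, tolerance = 1e-9)
  m <- rep$market
  has <- !is.na(m$coverage_share)
  expect_equal(m$coverage_share[has],
               m$national_demand[has] / m$product_potential[has],
               tolerance = 1e-9)
})

test_that("an empty matrix yields a zero-pool report without error", {
  m <- toy_matrix(list(id = "a", potential = 1e6, lignin = 0.3))
  cfg <- default_run_config()
  cfg$matrix <- m[0, ]
  expect_error(rep <- run_assessment(cfg), "Total technical potential")
  # with at least one (unselected) residue the report succeeds with zero pools
  cfg$matrix <- toy_matrix(list(id = "a", potential = 1e6, ash = 0.9))
  rep <- run_assessment(cfg)
  expect_true(all(rep$pools$raw_pool == 0))
  expect_true(all(rep$flows$product == 0))
})

test_that("assessing a planted synthetic matrix recovers the sidecar truth", {
  cfg <- default_run_config()
  cfg$generator <- generator_config(
    n_residues = 50, seed = 21,
    planted_truth = list(
      list(fraction = "lignin", threshold = 0.23, count = 5, pool = 3.3e6)))
  truth <- generate_matrix(cfg$generator)$truth$constraints$lignin
  rep <- run_assessment(cfg)
  p <- rep$pools
  # favorable tier of the lignin process equals the planted constraint
  expect_equal(p$fraction_pool[p$process == "adipic_from_lignin" &
                                 p$tier == "favorable"],
               truth$fraction_pool, tolerance = 1e-9)
  expect_equal(p$n_residues[p$process == "adipic_from_lignin" &
                              p$tier == "favorable"], 5L)
})

test_that("report files are written and re-runs are byte-identical", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  rep <- run_assessment()
  write_assessment_report(rep, dir1)
  write_assessment_report(run_assessment(), dir2)
  files <- c("summary_table.csv", "market_table.csv", "report.json", "run_log.txt")
  for (fl in files) {
    expect_true(file.exists(file.path(dir1, fl)))
    expect_identical(readLines(file.path(dir1, fl)),
                     readLines(file.path(dir2, fl)))
  }
  # node-link flow JSON present for every chain run
  expect_true(file.exists(file.path(dir1, "flow_adipic_from_lignin_favorable_baseline.json")))
  # the run log echoes the configured constants
  log <- readLines(file.path(dir1, "run_log.txt"))
  expect_true(any(grepl("gdp_share = 0.03", log)))
})

test_that("YAML config overrides merge with the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cutoff: 250000",
    "rules:",
    "  adipic_from_lignin:",
    "    fraction: lignin",
    "    favorable: 0.30",
    "    possible: 0.25",
    "market:",
    "  gdp_share: 0.05",
    "  land:",
    "    trunk_wood:",
    "      crop: trunk wood",
    "      areal_yield: 12"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$cutoff, 250000)
  expect_equal(cfg$rules$adipic_from_lignin$favorable, 0.30)
  expect_equal(cfg$rules$carboxylic_from_nfc$favorable, 0.20) # untouched default
  expect_equal(cfg$market$gdp_share, 0.05)
  expect_equal(cfg$market$land$trunk_wood$effective_yield, 12)
  # the tiny favorable tier makes demand outstrip the pool (warned, not clamped)
  rep <- suppressWarnings(run_assessment(cfg))
  # the stricter rule shrinks the favorable lignin tier to bark only
  p <- rep$pools
  expect_equal(p$n_residues[p$process == "adipic_from_lignin" &
                              p$tier == "favorable"], 1L)
})

test_that("the CLI subcommands run, validate and generate deterministically", {
  withr::local_dir(withr::local_tempdir())
  # assess on the packaged matrix
  expect_equal(suppressMessages(rf_cli(c("assess", "--out", "out1"))), 0L)
  expect_true(file.exists(file.path("out1", "summary_table.csv")))
  # generate twice with the same seed: byte-identical outputs
  expect_equal(suppressMessages(rf_cli(c("generate", "--seed", "7", "--n", "30",
                                         "--out", "g1"))), 0L)
  expect_equal(suppressMessages(rf_cli(c("generate", "--seed", "7", "--n", "30",
                                         "--out", "g2"))), 0L)
  expect_identical(readLines("g1.csv"), readLines("g2.csv"))
  expect_identical(readLines("g1_truth.json"), readLines("g2_truth.json"))
  # validate a good and a corrupt matrix
  expect_equal(suppressMessages(rf_cli(c("validate", "--matrix", "g1.csv"))), 0L)
  bad <- readLines("g1.csv")
  bad[2] <- sub("^([^,]*,[^,]*,)[^,]*", "\\1mars", bad[2])
  writeLines(bad, "bad.csv")
  expect_equal(suppressMessages(rf_cli(c("validate", "--matrix", "bad.csv"))), 1L)
  # score writes a quality table
  expect_equal(suppressMessages(rf_cli(c("score", "--matrix", "g1.csv",
                                         "--reference-year", "2024",
                                         "--out", "scores.csv"))), 0L)
  scores <- readr::read_csv("scores.csv", show_col_types = FALSE)
  expect_equal(nrow(scores), 30L)
  expect_true(all(scores$quality_score %in% 1:5))
  # usage errors exit 2
  expect_equal(suppressMessages(rf_cli(character(0))), 2L)
  expect_equal(suppressMessages(rf_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(rf_cli(c("assess", "--out"))), 2L)
})
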