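test_that("module knockouts starve or spare nitrogenase as the wiring dictates", {
  # sole ferredoxin source: knocking it zeroes symbiotic production
  solo <- make_symbiosis_toy(redundant_fdx = FALSE)
  rep1 <- module_knockout_report(solo$model, c(FDR1 = "Module A"),
                                 nfix_reaction_id = solo$ids$nitrogenase_id,
                                 cofactor_pools = solo$ids$cofactor_pools)
  wt <- rep1[rep1$module == "wild-type", ]
  ko <- rep1[rep1$module == "Module A", ]
  expect_equal(wt$symbiotic_production, solo$truth$optimum, tolerance = 1e-6)
  expect_equal(ko$symbiotic_production, 0, tolerance = 1e-9)
  expect_equal(ko$nitrogen_fixation, 0, tolerance = 1e-9)

  # redundant source: knockout leaves the optimum unchanged
  red <- make_symbiosis_toy(redundant_fdx = TRUE)
  rep2 <- module_knockout_report(red$model, red$ids$modules,
                                 nfix_reaction_id = red$ids$nitrogenase_id,
                                 cofactor_pools = red$ids$cofactor_pools)
  expect_equal(rep2$symbiotic_production,
               rep(red$truth$optimum, nrow(rep2)), tolerance = 1e-6)

  # no knockout ever beats wild type
  expect_true(all(rep2$symbiotic_production <=
                    rep2$symbiotic_production[rep2$module == "wild-type"] + 1e-6))
  expect_true(all(unlist(rep2[, 3:6]) >= -1e-9))
  expect_error(
    module_knockout_report(red$model, c(NOPE = "M"),
                           nfix_reaction_id = "NIT",
                           cofactor_pools = red$ids$cofactor_pools),
    "NOPE")
})

test_that("ferredoxin reactions balance their redox pair stoichiometrically", {
  sy <- make_symbiosis_toy()$model
  for (rid in c("FDR1", "FDR2", "NIT")) {
    st <- sy$reactions$stoichiometry[[match(rid, sy$reactions$id)]]
    expect_equal(unname(st["fdxrd"] + st["fdxox"]), 0, info = rid)
  }
})

test_that("the fixed-NH3 cap binds the wild type and boosting releases it", {
  sy <- make_symbiosis_toy()
  m <- sy$model
  capped <- set_bounds(m, "EX_NH3", upper = 0.001)
  wt <- fba(capped)
  expect_equal(unname(wt$fluxes["EX_NH3"]), 0.001, tolerance = 1e-9)
  expect_equal(wt$objective_value, 0.001 / 0.8, tolerance = 1e-7)

  scan <- overexpression_scan(m, c("FDR1", "NIT"), "EX_NH3", nfix_cap = 0.001)
  expect_true(all(scan$feasible))
  expect_true(all(scan$wild_type_fixed_nh3 == 0.001))
  # boosting a producer on the nitrogen-fixation path lifts export above the cap
  expect_true(all(scan$fixed_nh3_rate > 0.001))
})

test_that("a boost the network cannot carry reports zero (collapsed case)", {
  sy <- make_symbiosis_toy()
  scan <- overexpression_scan(sy$model, "FDR1", "EX_NH3", boost_factor = 50)
  expect_false(scan$feasible)
  expect_equal(scan$fixed_nh3_rate, 0)
  expect_equal(scan$symbiotic_production, 0)
  expect_error(overexpression_scan(sy$model, "NOPE", "EX_NH3"), "NOPE")
})

test_that("boosting a reaction disconnected from ferredoxin leaves fixed NH3 at wild type", {
  sy <- make_symbiosis_toy()$model
  # graft an independent nutrient path sharing nothing with nitrogen fixation
  mets <- rbind(sy$metabolites[, c("id", "name", "formula", "charge", "compartment")],
                data.frame(id = c("x_e", "x_c"), name = "x", formula = "",
                           charge = NA_integer_, compartment = c("e", "c")))
  mets$annotation <- I(rep(list(character()), nrow(mets)))
  add <- data.frame(id = c("EX_X", "T_X", "DM_X"), name = "x",
                    lower_bound = c(-1, 0, 0), upper_bound = 1000,
                    subsystem = "", class = c("exchange", NA, "demand"),
                    stringsAsFactors = FALSE)
  add$stoichiometry <- I(list(c(x_e = -1), c(x_e = -1, x_c = 1), c(x_c = -1)))
  add$gpr <- I(rep(list(NULL), 3))
  aug <- metabolic_model(sy$name, mets, rbind(sy$reactions, add),
                         genes = sy$genes, objective = sy$objective)
  scan <- overexpression_scan(aug, "DM_X", "EX_NH3")
  expect_true(scan$feasible)
  expect_equal(scan$fixed_nh3_rate, scan$wild_type_fixed_nh3, tolerance = 1e-5)
})

test_that("with the cap kept and boost factor 1 the scan reproduces wild type (MOMA identity)", {
  solo <- make_symbiosis_toy(redundant_fdx = FALSE)
  scan <- overexpression_scan(solo$model, "FDR1", "EX_NH3",
                              boost_factor = 1, release_cap = FALSE)
  expect_true(scan$feasible)
  expect_equal(scan$fixed_nh3_rate, scan$wild_type_fixed_nh3, tolerance = 1e-6)
  expect_equal(scan$symbiotic_production, scan$wild_type_symbiotic_production,
               tolerance = 1e-6)
})

test_that("target config YAML round-trips the module map", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "objective_id: SYM",
    "nitrogenase_id: NIT",
    "fixed_nh3_exchange_id: EX_NH3",
    "modules:",
    "  FDR1: Module A",
    "  FDR2: Module B"), path)
  cfg <- read_target_config(path)
  expect_equal(cfg$modules, c(FDR1 = "Module A", FDR2 = "Module B"))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("objective_id: SYM", bad)
  expect_error(read_target_config(bad), "missing keys")
})
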