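test_that("apply_media sets uptake bounds and can close unlisted exchanges", {
  ch <- make_chain_model(1, 10)$model
  m <- apply_media(ch, media_condition(c(EX_A = 5)), close_others = TRUE)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -5)
  # stoichiometry untouched
  expect_identical(m$reactions$stoichiometry, ch$reactions$stoichiometry)

  # unknown exchange ids are rejected by name
  expect_error(apply_media(ch, media_condition(c(EX_ZZ = 1))), "EX_ZZ")
  # negative uptake rates are rejected at construction
  expect_error(media_condition(c(EX_A = -2)), ">= 0")

  # the study's symbiotic medium applies succinate 1.38 / malate 1.44
  med <- symbiosis_media(c(succinate = "EX_succ", malate = "EX_mal"))
  expect_equal(unname(med$uptakes), c(1.38, 1.44))
})

test_that("blocked-reaction detection finds planted cuts and dead-end branches", {
  # severed chain: everything downstream of the cut is blocked
  ch <- make_chain_model(1, 10)$model
  cut <- set_bounds(ch, "R1", 0, 0)
  blocked <- find_blocked_reactions(cut, exclude_classes = "exchange")
  expect_setequal(blocked, c("T_A", "R1", "BIO"))

  # fully connected chain: nothing blocked
  expect_length(find_blocked_reactions(ch), 0)

  # dead-end branch fixture: exactly the planted branch, and the full
  # (unexcluded) report matches the brute-force vertex oracle
  de <- make_branched_model("dead_end")
  expect_identical(find_blocked_reactions(de$model), de$truth$blocked)
  expect_setequal(find_blocked_reactions(de$model, exclude_classes = character()),
                  oracle_blocked(de$model))
})

test_that("blocked detection is invariant to objective choice and media", {
  de <- make_branched_model("dead_end")$model
  starved <- apply_media(de, media_condition(c()), close_others = TRUE)
  expect_identical(find_blocked_reactions(starved), "RD")
  reobj <- de
  reobj$objective <- "T_A"
  expect_identical(find_blocked_reactions(reobj), "RD")
})

test_that("duplicate metabolites group by annotation and by formula+charge", {
  mets <- data.frame(
    id = c("succ1", "succ2", "succ3", "other", "empty1", "empty2"),
    name = "x", formula = c("C4H4O4", "C4H4O4", "", "C6H12O6", "", ""),
    charge = c(-2L, -2L, NA, 0L, NA, NA),
    compartment = "c", stringsAsFactors = FALSE)
  mets$annotation <- I(list(
    c(modelseed = "cpd00036"), character(), c(modelseed = "cpd00036"),
    c(modelseed = "cpd00027"), c(kegg = "C99991"), c(kegg = "C99992")))
  rxns <- data.frame(id = "r", name = "r", lower_bound = -1, upper_bound = 1,
                     subsystem = "", class = NA_character_)
  rxns$stoichiometry <- I(list(c(succ1 = -1, succ2 = 1)))
  rxns$gpr <- I(list(NULL))
  m <- metabolic_model("dups", mets, rxns, objective = "r")

  groups <- find_duplicate_metabolites(m)
  expect_length(groups, 1)
  # three aliases of succinate: two share formula+charge, annotation links the third
  expect_setequal(groups[[1]], c("succ1", "succ2", "succ3"))
  # empty-formula metabolites with distinct annotations never group
  expect_false(any(c("empty1", "empty2") %in% unlist(groups)))
})

test_that("duplicate grouping respects compartments", {
  mets <- data.frame(id = c("a_c", "a_e"), name = "a", formula = "CH4",
                     charge = 0L, compartment = c("c", "e"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = "t", name = "t", lower_bound = -1, upper_bound = 1,
                     subsystem = "", class = NA_character_)
  rxns$stoichiometry <- I(list(c(a_c = -1, a_e = 1)))
  rxns$gpr <- I(list(NULL))
  m <- metabolic_model("comp", mets, rxns, objective = "t")
  expect_length(find_duplicate_metabolites(m), 0)
})

test_that("dead-end metabolites are those only produced or only consumed internally", {
  de <- make_branched_model("dead_end")$model
  expect_identical(find_dead_end_metabolites(de), "D")
  ch <- make_chain_model(2, 5)$model
  expect_length(find_dead_end_metabolites(ch), 0)
})
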