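test_that("gene deletion recovers the planted essential sets on chain and isozyme toys", {
  ch <- make_chain_model(3, 4)
  screen <- single_gene_deletion(ch$model)
  expect_setequal(screen$element_id[screen$label == "essential"],
                  ch$truth$essential_genes)
  expect_true(all(screen$ratio[screen$label == "essential"] <= 0.05))

  iso <- make_isozyme_model()
  screen <- single_gene_deletion(iso$model)
  expect_setequal(screen$element_id[screen$label == "essential"],
                  iso$truth$essential_genes)
  expect_setequal(screen$element_id[screen$label == "neutral"],
                  iso$truth$neutral_genes)
  expect_equal(screen$ratio[screen$element_id == "g1"], 1, tolerance = 1e-9)
})

test_that("complex GPR deletion semantics propagate to growth", {
  # deleting one member of an AND complex kills the reaction and growth
  iso <- make_isozyme_model()$model
  s <- single_gene_deletion(iso, genes = "g4")
  expect_equal(s$ratio, 0, tolerance = 1e-9)
  expect_equal(s$label, "essential")
})

test_that("reaction deletion distinguishes essential, growth-affecting and neutral", {
  ch <- make_chain_model(1, 10)
  screen <- single_reaction_deletion(ch$model)
  expect_true(all(screen$label == "essential"))

  # one of two equivalent branches is dispensable
  eq <- make_branched_model("equivalent")
  screen <- single_reaction_deletion(eq$model, reactions = c("B1", "B2"))
  expect_true(all(screen$label == "neutral"))

  # a half-capacity partner gives ratio 0.5: growth-affecting, not essential
  hc <- make_branched_model("half_capacity")
  screen <- single_reaction_deletion(hc$model, reactions = "B2")
  expect_equal(screen$ratio, 0.5, tolerance = 1e-7)
  expect_equal(screen$label, "growth_affecting")
})

test_that("essential genes are a subset of growth-affecting genes", {
  hc <- make_branched_model("half_capacity")$model
  screen <- single_gene_deletion(hc)
  n_ess <- sum(screen$label == "essential")
  n_aff <- sum(screen$label != "neutral")
  expect_lte(n_ess, n_aff)
  expect_true(all(screen$ratio[screen$label == "essential"] <= 0.05))
  expect_true(all(screen$ratio >= 0))
})

test_that("genes absent from every GPR and blocked reactions are neutral", {
  ch <- make_chain_model(1, 10)$model
  ch$genes <- c(ch$genes, "bystander")
  screen <- single_gene_deletion(ch, genes = "bystander")
  expect_equal(screen$label, "neutral")

  de <- make_branched_model("dead_end")$model
  screen <- single_reaction_deletion(de, reactions = "RD")
  expect_equal(screen$label, "neutral")
})

test_that("gene-deletion outcome is invariant to GPR syntactic form", {
  build <- function(rule) {
    mets <- data.frame(id = c("a_e", "a_c", "b"), name = "x", formula = "",
                       charge = NA_integer_, compartment = c("e", "c", "c"),
                       stringsAsFactors = FALSE)
    rxns <- data.frame(id = c("EX_A", "T_A", "R1", "BIO"), name = "x",
                       lower_bound = c(-10, 0, 0, 0), upper_bound = 1000,
                       subsystem = "", class = NA_character_,
                       stringsAsFactors = FALSE)
    rxns$stoichiometry <- I(list(c(a_e = -1), c(a_e = -1, a_c = 1),
                                 c(a_c = -1, b = 1), c(b = -1)))
    rxns$gpr <- I(list(NULL, NULL, parse_gpr(rule), NULL))
    metabolic_model("syn", mets, rxns, genes = paste0("g", 1:3), objective = "BIO")
  }
  nested <- build("g1 and (g2 or g3)")
  dnf <- build("g1 and g2 or g1 and g3")
  s1 <- single_gene_deletion(nested)
  s2 <- single_gene_deletion(dnf)
  expect_equal(s1$ratio, s2$ratio, tolerance = 1e-9)
  expect_equal(s1$label, s2$label)
})

test_that("a non-growing wild type is rejected", {
  ch <- make_chain_model(1, 10)$model
  starved <- apply_media(ch, media_condition(c()), close_others = TRUE)
  expect_error(single_gene_deletion(starved), "zero")
})
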