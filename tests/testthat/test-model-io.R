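test_that("model construction validates invariants and infers classes", {
  ch <- make_chain_model(1, 10)$model
  expect_equal(nrow(ch$metabolites), 3)
  expect_equal(nrow(ch$reactions), 4)
  expect_setequal(ch$genes, c("gt", "g1"))
  expect_equal(ch$reactions$class[ch$reactions$id == "EX_A"], "exchange")
  expect_equal(ch$reactions$class[ch$reactions$id == "T_A"], "transport")
  expect_equal(ch$reactions$class[ch$reactions$id == "R1"], "enzymatic")
  expect_equal(ch$reactions$class[ch$reactions$id == "BIO"], "biomass")

  # missing objective is rejected
  mets <- data.frame(id = "a", name = "a", formula = "", charge = NA_integer_,
                     compartment = "c")
  rxns <- data.frame(id = "r", name = "r", lower_bound = 0, upper_bound = 1,
                     subsystem = "", class = NA_character_)
  rxns$stoichiometry <- I(list(c(a = -1)))
  rxns$gpr <- I(list(NULL))
  expect_error(metabolic_model("bad", mets, rxns, objective = "nope"),
               "objective")

  # GPR gene not registered: warning plus auto-registration
  rxns$gpr <- I(list(parse_gpr("ghost")))
  expect_warning(
    m <- metabolic_model("warned", mets, rxns, genes = character(), objective = "r"),
    "auto-registering")
  expect_true("ghost" %in% m$genes)
})

test_that("COBRA-JSON round trip preserves the model", {
  fix <- make_symbiosis_toy()
  path <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(fix$model, path)
  back <- read_cobra_json(path)

  expect_equal(back$reactions$id, fix$model$reactions$id)
  expect_equal(back$metabolites$id, fix$model$metabolites$id)
  expect_equal(back$reactions$lower_bound, fix$model$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, fix$model$reactions$upper_bound)
  expect_equal(back$objective, fix$model$objective)
  expect_setequal(back$genes, fix$model$genes)
  expect_equal(back$reactions$class, fix$model$reactions$class)
  for (i in seq_len(nrow(back$reactions))) {
    a <- back$reactions$stoichiometry[[i]]
    b <- fix$model$reactions$stoichiometry[[i]]
    expect_equal(a[sort(names(a))], b[sort(names(b))])
    # GPR truth tables survive the round trip
    genes <- gpr_genes(fix$model$reactions$gpr[[i]])
    if (length(genes)) {
      grid <- gene_state_grid(genes)
      for (k in seq_len(nrow(grid))) {
        deleted <- genes[!unlist(grid[k, , drop = FALSE])]
        expect_identical(evaluate_gpr(back$reactions$gpr[[i]], deleted),
                         evaluate_gpr(fix$model$reactions$gpr[[i]], deleted))
      }
    }
  }
  # and the round-tripped model optimises identically
  expect_equal(fba(back)$objective_value, fba(fix$model)$objective_value,
               tolerance = 1e-9)
})

test_that("SBML L3/FBC round trip preserves structure, bounds, GPRs and objective", {
  fix <- make_isozyme_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml_fbc(fix$model, path)
  back <- read_sbml_fbc(path)

  expect_equal(back$reactions$id, fix$model$reactions$id)
  expect_equal(back$metabolites$id, fix$model$metabolites$id)
  expect_equal(back$reactions$lower_bound, fix$model$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, fix$model$reactions$upper_bound)
  expect_equal(back$objective, "BIO")
  expect_setequal(back$genes, fix$model$genes)
  expect_equal(gpr_to_string(back$reactions$gpr[[3]]), "g1 or g2")
  expect_equal(gpr_to_string(back$reactions$gpr[[4]]), "g3 and g4")
  for (i in seq_len(nrow(back$reactions))) {
    a <- back$reactions$stoichiometry[[i]]
    b <- fix$model$reactions$stoichiometry[[i]]
    expect_equal(a[sort(names(a))], b[sort(names(b))])
  }
  expect_equal(fba(back)$objective_value, 10, tolerance = 1e-9)
})

test_that("load_model/write_model dispatch on dialect", {
  fix <- make_chain_model(1, 10)
  dir <- withr::local_tempdir()
  j <- file.path(dir, "m.json"); x <- file.path(dir, "m.xml")
  write_model(fix$model, j)
  write_model(fix$model, x)
  expect_equal(load_model(j)$reactions$id, fix$model$reactions$id)
  expect_equal(load_model(x, dialect = "sbml")$reactions$id, fix$model$reactions$id)
  expect_error(load_model(file.path(dir, "missing.json")), "not found")
})

test_that("media TSV and expression TSV readers handle headers and comments", {
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "media.tsv")
  writeLines(c("exchange_id\tuptake_rate", "# carbon", "EX_A\t5"), mpath)
  med <- read_media_tsv(mpath, label = "test")
  expect_equal(unname(med$uptakes["EX_A"]), 5)

  epath <- file.path(dir, "expr.tsv")
  writeLines(c("gene_id\trep1\trep2\trep3", "g1\t3\t4\t5", "g2\t0\t0\t0"), epath)
  pr <- read_expression_tsv(epath, condition = "logarithmic")
  expect_equal(unname(pr$abundance["g1"]), 4)  # replicate average
  expect_equal(unname(pr$abundance["g2"]), 0)
})
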