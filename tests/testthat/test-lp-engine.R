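test_that("FBA solves the chain benchmarks", {
  ch <- make_chain_model(1, 10)$model
  sol <- fba(ch)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_A"]), -10, tolerance = 1e-9)

  # all uptakes closed: nothing can grow
  closed <- apply_media(ch, media_condition(c()), close_others = TRUE)
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)

  # minimisation direction
  expect_equal(fba(ch, direction = "min")$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA objective equals the vertex-enumeration oracle on random networks", {
  for (seed in 1:12) {
    m <- make_random_network(seed)
    sol <- fba(m)
    ora <- oracle_fba(m)
    if (is.null(ora)) {
      expect_equal(sol$status, "infeasible", info = paste("seed", seed))
    } else {
      expect_equal(sol$status, "optimal", info = paste("seed", seed))
      expect_equal(sol$objective_value, ora$objective_value, tolerance = 1e-6,
                   info = paste("seed", seed))
    }
  }
})

test_that("optimal solutions satisfy steady state and bounds", {
  fixtures <- list(make_chain_model(3, 4)$model,
                   make_branched_model("equivalent")$model,
                   make_symbiosis_toy()$model)
  for (m in fixtures) {
    sol <- fba(m)
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-6))
    expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-6))
  }
})

test_that("tightening a bound never increases the FBA maximum", {
  for (seed in c(3, 5, 8)) {
    m <- make_random_network(seed)
    base <- fba(m)
    if (base$status != "optimal") next
    for (rid in m$reactions$id[1:3]) {
      i <- match(rid, m$reactions$id)
      m2 <- m
      m2$reactions$upper_bound[i] <- (m$reactions$lower_bound[i] +
                                        m$reactions$upper_bound[i]) / 2
      sol2 <- fba(m2)
      if (sol2$status == "optimal") {
        expect_lte(sol2$objective_value, base$objective_value + 1e-7)
      }
    }
  }
})

test_that("FVA brackets the FBA flux and pins unique optima", {
  ch <- make_chain_model(1, 10)$model
  rng <- fva(ch, fraction_of_optimum = 1)
  expect_true(all(abs(rng$min[rng$reaction != "EX_A"] - 10) < 1e-7))
  expect_true(all(abs(rng$max[rng$reaction != "EX_A"] - 10) < 1e-7))
  expect_equal(rng$min[rng$reaction == "EX_A"], -10, tolerance = 1e-7)

  # feasibility-only ranges
  rng0 <- fva(ch, fraction_of_optimum = 0, reactions = "EX_A")
  expect_equal(c(rng0$min, rng0$max), c(-10, 0), tolerance = 1e-7)

  # two equivalent branches at the optimum each span (0, total)
  eq <- make_branched_model("equivalent")$model
  rngb <- fva(eq, fraction_of_optimum = 1, reactions = c("B1", "B2"))
  expect_equal(rngb$min, c(0, 0), tolerance = 1e-7)
  expect_equal(rngb$max, c(10, 10), tolerance = 1e-7)

  # FVA(1) interval contains the FBA flux on every fixture
  for (m in list(eq, make_symbiosis_toy()$model)) {
    sol <- fba(m)
    rngm <- fva(m, fraction_of_optimum = 1)
    v <- sol$fluxes[rngm$reaction]
    expect_true(all(v >= rngm$min - 1e-6 & v <= rngm$max + 1e-6))
    expect_true(all(rngm$min <= rngm$max + 1e-9))
  }
})

test_that("production_rate sums gross production of a metabolite pool", {
  ch <- make_chain_model(1, 10)$model
  sol <- fba(ch)
  expect_equal(production_rate(ch, sol, "B"), 10, tolerance = 1e-7)
  expect_error(production_rate(ch, sol, "nope"), "unknown")

  # producer +8 and consumer -8 of a cofactor: gross production is 8
  mets <- data.frame(id = c("s", "atp", "orphan"),
                     name = c("s", "atp", "orphan"), formula = "",
                     charge = NA_integer_, compartment = "c")
  rxns <- data.frame(id = c("SRC", "MAKE", "USE"),
                     name = c("SRC", "MAKE", "USE"),
                     lower_bound = c(-8, 0, 0), upper_bound = c(1000, 8, 1000),
                     subsystem = "", class = c("exchange", NA, NA))
  rxns$stoichiometry <- I(list(c(s = -1), c(s = -1, atp = 1), c(atp = -1)))
  rxns$gpr <- I(rep(list(NULL), 3))
  toy <- metabolic_model("cofactor_toy", mets, rxns, objective = "USE")
  solt <- fba(toy)
  expect_equal(solt$objective_value, 8, tolerance = 1e-7)
  expect_equal(production_rate(toy, solt, "atp"), 8, tolerance = 1e-7)
  # a pool metabolite no reaction touches contributes nothing
  expect_equal(production_rate(toy, solt, "orphan"), 0, tolerance = 1e-12)
})
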