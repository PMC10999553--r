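test_that("reaction_expression aggregates AND as min and OR as sum", {
  pr <- expression_profile(c(g1 = 4, g2 = 10, g3 = 5))
  expect_equal(reaction_expression(parse_gpr("g1 and g2"), pr), 4)
  expect_equal(reaction_expression(parse_gpr("g1 or g2"), pr), 14)
  pr2 <- expression_profile(c(g1 = 9, g2 = 2, g3 = 5))
  expect_equal(reaction_expression(parse_gpr("g1 and (g2 or g3)"), pr2), 7)
  # alternative isozyme rule: max
  expect_equal(reaction_expression(parse_gpr("g1 or g2"), pr, or_rule = "max"), 10)
  # empty rule and unmeasured genes give the unconstrained sentinel
  expect_true(is.na(reaction_expression(parse_gpr(""), pr)))
  expect_true(is.na(reaction_expression(parse_gpr("g1 and gx"), pr)))
  # but a configured default can stand in for unmeasured genes
  expect_equal(reaction_expression(parse_gpr("g1 and gx"), pr, missing_value = 0), 0)
})

test_that("E-Flux leaves a uniformly expressed model unchanged and scales a planted limit", {
  ch <- make_chain_model(1, 10)$model
  base <- fba(ch)$objective_value

  uni <- make_expression_profile(ch, "uniform")
  expect_equal(fba(eflux_transform(ch, uni))$objective_value, base,
               tolerance = 1e-6)

  for (f in c(0, 0.25, 0.5, 1)) {
    pr <- make_expression_profile(ch, "single_limited", gene = "g1", fraction = f)
    obj <- fba(eflux_transform(ch, pr))$objective_value
    expect_equal(obj, f * base, tolerance = 1e-6,
                 info = paste("fraction", f))
  }
})

test_that("E-Flux never widens a bound and is invariant to profile scaling", {
  sy <- make_symbiosis_toy()$model
  pr <- expression_profile(c(gt = 50, gc = 80, gf1 = 20, gf2 = 10, gn = 40))
  t1 <- eflux_transform(sy, pr)

  clamped_lb <- pmin(fva(sy, 0)$min, 0)
  clamped_ub <- pmax(fva(sy, 0)$max, 0)
  expect_true(all(abs(t1$reactions$lower_bound) <= abs(clamped_lb) + 1e-9))
  expect_true(all(abs(t1$reactions$upper_bound) <= abs(clamped_ub) + 1e-9))

  pr10 <- expression_profile(pr$abundance * 10)
  t10 <- eflux_transform(sy, pr10)
  expect_equal(t1$reactions$lower_bound, t10$reactions$lower_bound, tolerance = 1e-9)
  expect_equal(t1$reactions$upper_bound, t10$reactions$upper_bound, tolerance = 1e-9)

  # objective ordering: transformed <= original
  expect_lte(fba(t1)$objective_value, fba(sy)$objective_value + 1e-9)
})

test_that("a zero-abundance gene closes its reaction", {
  ch <- make_chain_model(1, 10)$model
  pr <- expression_profile(c(gt = 10, g1 = 0))
  t <- eflux_transform(ch, pr)
  i <- match("R1", t$reactions$id)
  expect_equal(t$reactions$lower_bound[i], 0)
  expect_equal(t$reactions$upper_bound[i], 0)
  expect_equal(fba(t)$objective_value, 0, tolerance = 1e-9)
  # an all-zero profile leaves nothing to scale against
  expect_error(eflux_transform(ch, expression_profile(c(gt = 0, g1 = 0))), "zero")
})

test_that("homolog mapping keeps best bidirectional hits above the ratio threshold", {
  pr <- expression_profile(c(a = 7, b = 3, c = 9), condition = "W05")
  map <- homolog_map(data.frame(
    source_id = c("a", "b", "c", "c"),
    target_id = c("x", "y", "x", "z"),
    bbh_ratio = c(95, 85, 92, 96)), min_ratio = 90)
  out <- map_homologs(pr, map)
  # b -> y dropped (85 < 90); for x, a at 95 beats c at 92
  expect_equal(unname(out$abundance["x"]), 7)
  expect_equal(unname(out$abundance["z"]), 9)
  expect_false("y" %in% names(out$abundance))
  expect_true("b" %in% attr(out, "dropped_sources"))
  expect_equal(out$condition, "W05")
})

test_that("two sources over threshold resolve to the higher-ratio pair", {
  pr <- expression_profile(c(s1 = 4, s2 = 11))
  map <- homolog_map(data.frame(
    source_id = c("s1", "s2"), target_id = c("x", "x"),
    bbh_ratio = c(92, 96)), min_ratio = 90)
  out <- map_homologs(pr, map)
  expect_equal(unname(out$abundance["x"]), 11)
})
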