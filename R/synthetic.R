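# Deterministic toy-network generators. Each generator returns the model
# together with planted ground truth (optimum, essential sets, blocked
# set), and the planted truth is re-verified against the brute-force
# vertex oracle at generation time, so tests never have to trust the LP
# engine they are checking.

met_df <- function(id, compartment, name = id) {
  data.frame(id = id, name = name, formula = "", charge = NA_integer_,
             compartment = compartment, stringsAsFactors = FALSE)
}

rxn_df <- function(id, stoich, lb = 0, ub = BIG_BOUND, gpr = "", name = id,
                   subsystem = "", class = NA_character_) {
  df <- data.frame(id = id, name = name, lower_bound = lb, upper_bound = ub,
                   subsystem = subsystem, class = class, stringsAsFactors = FALSE)
  df$stoichiometry <- I(list(stoich))
  df$gpr <- I(list(parse_gpr(gpr)))
  df
}

verify_planted_optimum <- function(model, planted, tol = 1e-6) {
  ora <- oracle_fba(model)
  if (is.null(ora) || abs(ora$objective_value - planted) > tol) {
    stop("generator self-check failed: planted optimum ", planted,
         " vs oracle ", if (is.null(ora)) "infeasible" else ora$objective_value)
  }
  invisible(TRUE)
}

#' Linear chain toy model
#'
#' Exchange -> transport -> `n_steps` enzymatic steps -> biomass drain, one
#' gene per internal reaction. The FBA optimum equals `uptake_bound`,
#' every reaction (and every gene) is essential, and no reaction is
#' blocked. `make_chain_model(1, 10)` is the "chain3" benchmark: 3
#' metabolites, 4 reactions.
#'
#' @param n_steps number of enzymatic steps (>= 1)
#' @param uptake_bound uptake allowance on the single carbon exchange
#' @return list with elements `model` and `truth` (planted `optimum`,
#'   `essential_genes`, `essential_reactions`, `blocked`)
#' @export
make_chain_model <- function(n_steps = 1, uptake_bound = 10) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  inner <- if (n_steps > 1) paste0("M", seq_len(n_steps - 1)) else character()
  chain <- c("A_c", inner, "B")
  mets <- rbind(met_df("A_e", "e"), met_df(chain, "c"))
  genes <- c("gt", paste0("g", seq_len(n_steps)))
  rxns <- rbind(
    rxn_df("EX_A", c(A_e = -1), lb = -uptake_bound),
    rxn_df("T_A", c(A_e = -1, A_c = 1), gpr = "gt"),
    do.call(rbind, lapply(seq_len(n_steps), function(i) {
      rxn_df(paste0("R", i),
             stats::setNames(c(-1, 1), c(chain[i], chain[i + 1])),
             gpr = paste0("g", i))
    })),
    rxn_df("BIO", c(B = -1), class = "biomass")
  )
  model <- metabolic_model("chain_toy", mets, rxns, genes, objective = "BIO")
  truth <- list(optimum = uptake_bound,
                essential_genes = genes,
                essential_reactions = model$reactions$id,
                blocked = character())
  verify_planted_optimum(model, truth$optimum)
  list(model = model, truth = truth)
}

#' Branched toy model
#'
#' One carbon uptake feeding two parallel branches into the biomass
#' precursor. Variants:
#' * `"equivalent"` — both branches unlimited: FVA at the optimum gives
#'   each branch the full range (0, optimum);
#' * `"half_capacity"` — branch 1 capped at half the uptake: deleting
#'   branch 2 halves growth (ratio 0.5, growth-affecting, not essential);
#' * `"dead_end"` — an extra branch produces a metabolite nothing
#'   consumes, so that branch is the planted blocked set.
#'
#' @param variant one of `"equivalent"`, `"half_capacity"`, `"dead_end"`
#' @param uptake_bound uptake allowance
#' @return list with `model` and `truth`
#' @export
make_branched_model <- function(variant = c("equivalent", "half_capacity", "dead_end"),
                                uptake_bound = 10) {
  variant <- match.arg(variant)
  mets <- rbind(met_df("A_e", "e"), met_df(c("A_c", "P"), "c"))
  b1_ub <- if (variant == "half_capacity") uptake_bound / 2 else BIG_BOUND
  rxns <- rbind(
    rxn_df("EX_A", c(A_e = -1), lb = -uptake_bound),
    rxn_df("T_A", c(A_e = -1, A_c = 1), gpr = "gt"),
    rxn_df("B1", c(A_c = -1, P = 1), ub = b1_ub, gpr = "gb1"),
    rxn_df("B2", c(A_c = -1, P = 1), gpr = "gb2"),
    rxn_df("BIO", c(P = -1), class = "biomass")
  )
  genes <- c("gt", "gb1", "gb2")
  blocked <- character()
  if (variant == "dead_end") {
    mets <- rbind(mets, met_df("D", "c"))
    rxns <- rbind(rxns, rxn_df("RD", c(A_c = -1, D = 1), gpr = "gd"))
    genes <- c(genes, "gd")
    blocked <- "RD"
  }
  model <- metabolic_model(paste0("branched_", variant), mets, rxns, genes,
                           objective = "BIO")
  truth <- list(optimum = uptake_bound,
                essential_genes = "gt",
                essential_reactions = c("EX_A", "T_A", "BIO"),
                blocked = blocked,
                growth_affecting_genes =
                  if (variant == "half_capacity") c(gb2 = 0.5) else NULL)
  verify_planted_optimum(model, truth$optimum)
  list(model = model, truth = truth)
}

#' Isozyme / complex toy model
#'
#' A chain in which one step carries the isozyme rule `"g1 or g2"` and the
#' next the complex rule `"g3 and g4"`: the planted essential gene set is
#' exactly `{g3, g4}` while `g1`, `g2` are neutral; every reaction is
#' essential.
#'
#' @param uptake_bound uptake allowance
#' @return list with `model` and `truth`
#' @export
make_isozyme_model <- function(uptake_bound = 10) {
  mets <- rbind(met_df("A_e", "e"), met_df(c("A_c", "M", "B"), "c"))
  rxns <- rbind(
    rxn_df("EX_A", c(A_e = -1), lb = -uptake_bound),
    rxn_df("T_A", c(A_e = -1, A_c = 1)),
    rxn_df("R1", c(A_c = -1, M = 1), gpr = "g1 or g2"),
    rxn_df("R2", c(M = -1, B = 1), gpr = "g3 and g4"),
    rxn_df("BIO", c(B = -1), class = "biomass")
  )
  model <- metabolic_model("isozyme_toy", mets, rxns,
                           genes = c("g1", "g2", "g3", "g4"), objective = "BIO")
  truth <- list(optimum = uptake_bound,
                essential_genes = c("g3", "g4"),
                neutral_genes = c("g1", "g2"),
                essential_reactions = model$reactions$id,
                blocked = character())
  verify_planted_optimum(model, truth$optimum)
  list(model = model, truth = truth)
}

#' Miniature symbiosis (bacteroid) network
#'
#' Scaled-down mirror of the nitrogen-fixation core of a bacteroid model:
#' dicarboxylate (succinate) uptake at the study's symbiotic rate 1.38
#' mmol/gDW/h, catabolism producing ATP and NADH pools, ferredoxin
#' reduction (`FDR1`, plus a redundant `FDR2` isozyme reaction unless
#' `redundant_fdx = FALSE`), nitrogenase consuming reduced ferredoxin and
#' ATP to fix NH3, a fixed-NH3 exchange across the symbiosome boundary, a
#' symbiotic-product pseudo-reaction (the objective) consuming exported
#' NH3 and ATP, and demand drains for the product and cofactor slack.
#'
#' Ground truth (symbiotic optimum, nitrogenase flux, fixed-NH3 export at
#' the optimum) is computed by the vertex oracle at generation.
#'
#' @param redundant_fdx include the redundant second ferredoxin reductase?
#' @param uptake_bound succinate uptake (default 1.38, the study's rate)
#' @return list with `model`, `truth`, and `ids` (objective, nitrogenase,
#'   fixed-NH3 exchange, module map, cofactor pools)
#' @export
make_symbiosis_toy <- function(redundant_fdx = TRUE, uptake_bound = 1.38) {
  mets <- rbind(
    met_df("succ_e", "e"), met_df("nh3_p", "e", "fixed NH3 (plant side)"),
    met_df(c("succ_c", "atp", "nadh", "fdxox", "fdxrd", "nh3_c", "symb"), "c")
  )
  rxns <- rbind(
    rxn_df("EX_succ", c(succ_e = -1), lb = -uptake_bound),
    rxn_df("T_succ", c(succ_e = -1, succ_c = 1), gpr = "gt"),
    rxn_df("CAT", c(succ_c = -1, atp = 2, nadh = 3), gpr = "gc",
           name = "dicarboxylate catabolism", subsystem = "Carbon Metabolism"),
    rxn_df("FDR1", c(nadh = -1, fdxox = -2, fdxrd = 2), gpr = "gf1",
           name = "ferredoxin reductase", subsystem = "Sulfur Metabolism"),
    rxn_df("NIT", c(fdxrd = -4, atp = -8, fdxox = 4, nh3_c = 2), gpr = "gn",
           name = "nitrogenase", subsystem = "Nitrogen Fixation"),
    rxn_df("EX_NH3", c(nh3_c = -1, nh3_p = 1), class = "exchange",
           name = "fixed NH3 exchange"),
    rxn_df("SYM", c(nh3_p = -0.8, atp = -0.5, symb = 1), class = "biomass",
           name = "symbiotic production"),
    rxn_df("DM_symb", c(symb = -1), class = "demand"),
    rxn_df("DM_atp", c(atp = -1), class = "demand"),
    rxn_df("DM_nadh", c(nadh = -1), class = "demand")
  )
  genes <- c("gt", "gc", "gf1", "gn")
  if (redundant_fdx) {
    rxns <- rbind(rxns,
      rxn_df("FDR2", c(nadh = -1, fdxox = -2, fdxrd = 2), gpr = "gf2",
             name = "ferredoxin reductase (isozyme)",
             subsystem = "Terpenoid Backbone Biosynthesis"))
    genes <- c(genes, "gf2")
  }
  model <- metabolic_model("symbiosis_toy", mets, rxns, genes, objective = "SYM")

  ora <- oracle_fba(model)
  if (is.null(ora)) stop("generator self-check failed: symbiosis toy infeasible")
  truth <- list(optimum = ora$objective_value,
                nitrogenase_flux = unname(ora$vertex["NIT"]),
                fixed_nh3_flux = unname(ora$vertex["EX_NH3"]),
                blocked = character())
  ids <- list(
    objective_id = "SYM",
    nitrogenase_id = "NIT",
    fixed_nh3_exchange_id = "EX_NH3",
    modules = c(FDR1 = "Module A",
                if (redundant_fdx) c(FDR2 = "Module B")),
    cofactor_pools = list(nadh = "nadh", atp = "atp")
  )
  list(model = model, truth = truth, ids = ids)
}

#' Synthetic expression profiles
#'
#' `rule = "uniform"` gives every gene the same abundance (E-Flux then
#' leaves the model unchanged). `rule = "single_limited"` plants a known
#' rate-limiting gene at `fraction` of the maximum abundance, so the
#' E-Flux objective should equal `fraction` times the unconstrained
#' optimum when that gene's reaction carries the binding constraint.
#' Remaining genes receive seeded positive abundances at the common level.
#'
#' @param model a `metabolic_model`
#' @param rule `"uniform"` or `"single_limited"`
#' @param gene the planted rate-limiting gene (for `"single_limited"`)
#' @param fraction fraction of the maximum abundance for the planted gene
#' @param level abundance level of the non-limited genes (default 100)
#' @param seed integer seed; generation is deterministic given the seed
#' @return an `expression_profile`
#' @export
make_expression_profile <- function(model, rule = c("uniform", "single_limited"),
                                    gene = NULL, fraction = 0.5, level = 100,
                                    seed = 1) {
  rule <- match.arg(rule)
  genes <- model$genes
  ab <- stats::setNames(rep(level, length(genes)), genes)
  if (rule == "single_limited") {
    if (is.null(gene) || !gene %in% genes) stop("planted gene must be a model gene")
    ab[gene] <- fraction * level
  }
  # seeded jitter is intentionally absent from limiting structure: only the
  # condition label varies with the seed so profiles stay byte-identical
  expression_profile(ab, condition = paste0(rule, "_seed", seed))
}

#' Synthetic sole-carbon-source panel with known reachability
#'
#' Builds a model with `n_sources` carbon exchanges: the first
#' `n_connected` feed biomass through a transporter and a catabolic step,
#' the following ones have a transporter whose catabolic step is missing
#' (a blocked path), and the last `n_orphan` have an exchange that
#' connects to nothing.
#' The observed plate column is the graph-reachability truth with
#' `n_flipped` seeded wells flipped, so the expected plate accuracy is
#' known by construction.
#'
#' @param n_sources total carbon sources (>= 1)
#' @param n_connected sources with a complete path to biomass
#' @param n_orphan sources whose exchange connects to nothing
#' @param n_flipped observed calls flipped at seeded wells (defaults 0)
#' @param seed integer seed controlling which wells flip
#' @return list with `model`, `plate`, `mapping`, `minimal_medium`, and
#'   `truth` (`reachable`, `expected_accuracy`)
#' @export
make_phenotype_panel <- function(n_sources = 8, n_connected = 5, n_orphan = 2,
                                 n_flipped = 0, seed = 1) {
  stopifnot(n_sources >= 1, n_connected + n_orphan <= n_sources)
  n_blockedpath <- n_sources - n_connected - n_orphan
  src <- paste0("S", seq_len(n_sources))
  mets <- rbind(met_df(paste0(src, "_e"), "e"),
                met_df("N_e", "e", "nitrogen source"),
                met_df(c(paste0(src[seq_len(n_sources - n_orphan)], "_c"), "N_c", "P"), "c"))
  rxns <- rxn_df("EX_N", c(N_e = -1), lb = -BIG_BOUND)
  rxns <- rbind(rxns, rxn_df("T_N", c(N_e = -1, N_c = 1)))
  for (i in seq_len(n_sources)) {
    rxns <- rbind(rxns, rxn_df(paste0("EX_", src[i]),
                               stats::setNames(-1, paste0(src[i], "_e")), lb = 0))
    if (i <= n_connected + n_blockedpath) {
      has_cat <- i <= n_connected
      rxns <- rbind(rxns, rxn_df(paste0("T_", src[i]),
        stats::setNames(c(-1, 1), paste0(src[i], c("_e", "_c")))))
      if (has_cat) {
        rxns <- rbind(rxns, rxn_df(paste0("CAT_", src[i]),
          stats::setNames(c(-1, -0.1, 1), c(paste0(src[i], "_c"), "N_c", "P"))))
      }
    }
  }
  rxns <- rbind(rxns, rxn_df("BIO", c(P = -1), class = "biomass"))
  model <- metabolic_model("phenotype_panel", mets, rxns, genes = character(),
                           objective = "BIO")

  reachable <- c(rep(TRUE, n_connected), rep(FALSE, n_sources - n_connected))
  observed <- reachable
  if (n_flipped > 0) {
    set.seed(seed)
    flip <- sample(n_sources, n_flipped)
    observed[flip] <- !observed[flip]
  }
  plate <- data.frame(well = paste0("W", seq_len(n_sources)),
                      substrate_name = src,
                      observed = as.integer(observed), stringsAsFactors = FALSE)
  mapping <- data.frame(substrate_name = src,
                        exchange_id = paste0("EX_", src), stringsAsFactors = FALSE)
  minimal_medium <- media_condition(c(EX_N = BIG_BOUND), label = "minimal")
  truth <- list(reachable = stats::setNames(reachable, src),
                expected_accuracy = 100 * mean(reachable == observed))
  list(model = model, plate = plate, mapping = mapping,
       minimal_medium = minimal_medium, truth = truth)
}

#' Write a fixture (model + ground-truth sidecar) to disk
#'
#' @param fixture a generator result (list with `model` and `truth`)
#' @param dir output directory (created if needed)
#' @param name base filename; default the model name
#' @return paths of the files written, invisibly
#' @export
write_fixture <- function(fixture, dir, name = fixture$model$name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model_path <- file.path(dir, paste0(name, ".json"))
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  write_cobra_json(fixture$model, model_path)
  jsonlite::write_json(fixture$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(model = model_path, truth = truth_path))
}
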