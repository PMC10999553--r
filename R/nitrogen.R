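#' Ferredoxin-module knockout report
#'
#' For each reaction in the module map (reduced-ferredoxin producers, one
#' per metabolic module), the reaction is knocked out (`lb = ub = 0`), the
#' symbiotic objective is re-optimised by FBA, and four quantities are
#' reported at the mutant optimum: gross NADH/NADPH production, gross ATP
#' production (both via [production_rate()] over the supplied cofactor
#' pools), the symbiotic production flux (the objective reaction), and
#' the symbiotic nitrogen fixation flux (the nitrogenase reaction). The
#' wild type is reported as module label `"wild-type"`.
#'
#' @param model symbiotic condition `metabolic_model`
#' @param module_map named character: reaction id -> module label
#' @param objective_id symbiotic objective reaction id; default the model
#'   objective
#' @param nfix_reaction_id nitrogenase reaction id
#' @param cofactor_pools list with elements `nadh` and `atp`, each a
#'   character vector of metabolite ids pooled across compartments
#' @return data.frame: `module`, `knocked_reaction_id`,
#'   `nadh_nadph_production`, `atp_production`, `symbiotic_production`,
#'   `nitrogen_fixation`
#' @export
module_knockout_report <- function(model, module_map,
                                   objective_id = model$objective,
                                   nfix_reaction_id, cofactor_pools) {
  rxn_row(model, names(module_map))  # error naming unresolvable ids
  rxn_row(model, nfix_reaction_id)
  report_one <- function(m, module, knocked) {
    sol <- fba(m, objective_id)
    if (sol$status != "optimal") {
      return(data.frame(module = module, knocked_reaction_id = knocked,
                        nadh_nadph_production = 0, atp_production = 0,
                        symbiotic_production = 0, nitrogen_fixation = 0,
                        stringsAsFactors = FALSE))
    }
    data.frame(
      module = module, knocked_reaction_id = knocked,
      nadh_nadph_production = production_rate(m, sol, cofactor_pools$nadh),
      atp_production = production_rate(m, sol, cofactor_pools$atp),
      symbiotic_production = unname(sol$fluxes[objective_id]),
      nitrogen_fixation = unname(sol$fluxes[nfix_reaction_id]),
      stringsAsFactors = FALSE)
  }
  rows <- list(report_one(model, "wild-type", NA_character_))
  for (rid in names(module_map)) {
    rows <- c(rows, list(
      report_one(knockout_reactions(model, rid), module_map[[rid]], rid)))
  }
  do.call(rbind, rows)
}

#' MOMA overexpression scan for fixed-NH3 enhancement
#'
#' Emulates the target-finding procedure: the wild type is the symbiotic
#' model with the fixed-NH3 exchange capped at `nfix_cap` (0.001
#' mmol/gDW/h in the study) and its FBA solution is the MOMA reference.
#' For each candidate reaction, overexpression is imposed by raising the
#' candidate's lower bound to `boost_factor` times its wild-type FVA
#' maximum while the fixed-NH3 cap is released, and the perturbed flux
#' state is predicted by [moma()] against the wild-type reference. A
#' boost the network cannot carry makes the QP infeasible and is reported
#' as zero rates (the collapsed case).
#'
#' `overexpression_scan(..., boost_factor = 1, release_cap = FALSE)`
#' reproduces the wild-type fluxes exactly (MOMA identity).
#'
#' @param model symbiotic `metabolic_model` (uncapped)
#' @param candidates candidate reaction ids
#' @param nfix_exchange_id id of the fixed-NH3 exchange reaction
#' @param nfix_cap wild-type cap on fixed-NH3 export (default 0.001)
#' @param boost_factor multiple of the wild-type FVA maximum imposed as
#'   the candidate's lower bound (default 1)
#' @param release_cap release the fixed-NH3 cap during the boost
#'   (default `TRUE`)
#' @return data.frame: `reaction`, `fixed_nh3_rate`,
#'   `symbiotic_production`, `wild_type_fixed_nh3`,
#'   `wild_type_symbiotic_production`, `feasible`
#' @export
overexpression_scan <- function(model, candidates, nfix_exchange_id,
                                nfix_cap = 0.001, boost_factor = 1,
                                release_cap = TRUE) {
  rxn_row(model, candidates)
  i_nfix <- rxn_row(model, nfix_exchange_id)
  orig_ub <- model$reactions$upper_bound[i_nfix]

  wt_model <- set_bounds(model, nfix_exchange_id, upper = nfix_cap)
  wt <- fba(wt_model)
  if (wt$status != "optimal") stop("wild-type capped model is ", wt$status)
  wt_nfix <- unname(wt$fluxes[nfix_exchange_id])
  wt_symb <- unname(wt$fluxes[model$objective])

  # the attainable maximum is measured on the network the boost will act on:
  # with the cap released the candidate can reach its full network capacity
  scan_model <- if (release_cap) {
    set_bounds(wt_model, nfix_exchange_id, upper = orig_ub)
  } else {
    wt_model
  }
  ranges <- fva(scan_model, fraction_of_optimum = 0, reactions = candidates)
  vmax <- stats::setNames(ranges$max, ranges$reaction)

  rows <- lapply(candidates, function(rid) {
    target <- boost_factor * vmax[[rid]]
    m <- scan_model
    i <- rxn_row(m, rid)
    m$reactions$lower_bound[i] <- target
    if (m$reactions$upper_bound[i] < target) m$reactions$upper_bound[i] <- target
    sol <- moma(m, wt)
    if (sol$status != "optimal") {
      data.frame(reaction = rid, fixed_nh3_rate = 0, symbiotic_production = 0,
                 wild_type_fixed_nh3 = wt_nfix,
                 wild_type_symbiotic_production = wt_symb,
                 feasible = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(reaction = rid,
                 fixed_nh3_rate = unname(sol$fluxes[nfix_exchange_id]),
                 symbiotic_production = unname(sol$fluxes[model$objective]),
                 wild_type_fixed_nh3 = wt_nfix,
                 wild_type_symbiotic_production = wt_symb,
                 feasible = TRUE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Read a nitrogen-target analysis config
#'
#' YAML with keys `objective_id`, `nitrogenase_id`, `fixed_nh3_exchange_id`,
#' `modules` (mapping reaction id -> module label), and optional
#' `cofactor_pools` (`nadh`, `atp` metabolite id lists).
#'
#' @param path YAML file
#' @return named list
#' @export
read_target_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("objective_id", "nitrogenase_id", "fixed_nh3_exchange_id", "modules")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("target config missing keys: ", paste(miss, collapse = ", "))
  cfg$modules <- unlist(cfg$modules)
  cfg
}
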