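#' Flux balance analysis
#'
#' Solves the linear program max (or min) of the objective reaction's flux
#' subject to steady state `S v = 0` and the model's flux bounds. The
#' objective value is unique even when the optimal flux vector is
#' degenerate; the returned flux vector is one optimal basic solution.
#'
#' @param model a `metabolic_model`
#' @param objective reaction id to optimise; default the model objective
#' @param direction `"max"` (default) or `"min"`
#' @return a `flux_solution`: list with `status`
#'   (optimal/infeasible/unbounded), `objective_value`, and `fluxes` (named
#'   numeric over all reactions; absent for non-optimal status)
#' @examples
#' m <- make_chain_model(1, 10)$model
#' fba(m)$objective_value  # 10
#' @export
fba <- function(model, objective = model$objective, direction = c("max", "min")) {
  direction <- match.arg(direction)
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  if (!any(obj > 0)) stop("objective reaction '", objective, "' not in model")
  res <- solve_lp(obj, S, model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = direction == "max")
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = NULL), class = "flux_solution"))
  }
  structure(list(status = "optimal", objective_value = res$objective,
                 fluxes = stats::setNames(res$x, model$reactions$id)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") cat("  objective: ", signif(x$objective_value, 6), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' the network constraints and, when `fraction_of_optimum > 0`, to the
#' objective retaining at least that fraction of its FBA optimum.
#' `fraction_of_optimum = 0` gives the pure feasible flux ranges.
#'
#' @param model a `metabolic_model`
#' @param fraction_of_optimum number in `[0, 1]`
#' @param reactions reaction ids to scan; default all
#' @param objective objective reaction id; default the model objective
#' @return data.frame with columns `reaction`, `min`, `max`
#' @export
fva <- function(model, fraction_of_optimum = 1, reactions = model$reactions$id,
                objective = model$objective) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  S <- stoichiometric_matrix(model)
  lbv <- model$reactions$lower_bound
  ubv <- model$reactions$upper_bound
  ineq_A <- NULL; ineq_b <- NULL
  if (fraction_of_optimum > 0) {
    wt <- fba(model, objective)
    if (wt$status != "optimal") stop("FVA: model is ", wt$status)
    cobj <- as.numeric(model$reactions$id == objective)
    # c'v >= f * opt  as  -c'v <= -f * opt
    ineq_A <- matrix(-cobj, nrow = 1)
    ineq_b <- -fraction_of_optimum * wt$objective_value
  }
  n <- nrow(model$reactions)
  idx <- rxn_row(model, reactions)
  mn <- mx <- numeric(length(idx))
  for (k in seq_along(idx)) {
    e <- numeric(n); e[idx[k]] <- 1
    lo <- solve_lp(e, S, lbv, ubv, maximize = FALSE, ineq_A = ineq_A, ineq_b = ineq_b)
    hi <- solve_lp(e, S, lbv, ubv, maximize = TRUE, ineq_A = ineq_A, ineq_b = ineq_b)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem ", model$reactions$id[idx[k]], ": ", lo$status)
    }
    mn[k] <- lo$objective; mx[k] <- hi$objective
  }
  data.frame(reaction = reactions, min = mn, max = mx,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the flux distribution of the perturbed model closest (Euclidean
#' distance) to a reference flux distribution, as a strictly convex
#' quadratic program: minimise sum((v - v_ref)^2) subject to `S v = 0` and
#' the perturbed bounds. The solution is unique. The reference defaults to
#' the wild-type FBA solution in the calling workflows.
#'
#' @param model the perturbed `metabolic_model`
#' @param reference named numeric of reference fluxes (e.g.
#'   `fba(wild_type)$fluxes`) or a `flux_solution`
#' @return a `flux_solution` with an extra element `distance`
#'   (the Euclidean distance sum((v - v_ref)^2)^0.5 squared is in
#'   `distance_sq`); `objective_value` is the flux the solution carries
#'   through the model's objective reaction
#' @export
moma <- function(model, reference) {
  if (inherits(reference, "flux_solution")) reference <- reference$fluxes
  ref <- rep(0, nrow(model$reactions))
  names(ref) <- model$reactions$id
  common <- intersect(names(reference), names(ref))
  ref[common] <- reference[common]

  S <- stoichiometric_matrix(model)
  res <- solve_qp_bounded(ref, S, model$reactions$lower_bound,
                          model$reactions$upper_bound)
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible", objective_value = NA_real_,
                          fluxes = NULL, distance_sq = NA_real_),
                     class = "flux_solution"))
  }
  v <- stats::setNames(res$x, model$reactions$id)
  structure(list(status = "optimal",
                 objective_value = unname(v[model$objective]),
                 fluxes = v,
                 distance_sq = sum((v - ref)^2)),
            class = "flux_solution")
}

#' Gross production rate of a metabolite pool
#'
#' Production of a pool (e.g. NADH+NADPH across compartments, or all ATP
#' species) at a flux solution, defined as the sum over reactions of the
#' positive part of their net pool production:
#' `sum_r max(0, sum_{m in pool} S[m, r] * v_r)`.
#' The alternative `method = "demand"` instead sums the fluxes of
#' demand-class reactions draining pool members.
#'
#' @param model a `metabolic_model`
#' @param solution an optimal `flux_solution`
#' @param metabolite_ids pool member metabolite ids
#' @param method `"gross"` (default) or `"demand"`
#' @return production rate in mmol/gDW/h
#' @export
production_rate <- function(model, solution, metabolite_ids,
                            method = c("gross", "demand")) {
  method <- match.arg(method)
  if (solution$status != "optimal") stop("production_rate needs an optimal solution")
  met_row(model, metabolite_ids)  # errors on unknown ids
  if (method == "demand") {
    dm <- vapply(seq_len(nrow(model$reactions)), function(j) {
      st <- model$reactions$stoichiometry[[j]]
      model$reactions$class[j] == "demand" && any(names(st) %in% metabolite_ids)
    }, logical(1))
    return(sum(solution$fluxes[model$reactions$id[dm]]))
  }
  total <- 0
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    pool <- st[names(st) %in% metabolite_ids]
    if (!length(pool)) next
    prod_j <- sum(pool) * solution$fluxes[[model$reactions$id[j]]]
    if (prod_j > 0) total <- total + prod_j
  }
  total
}
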