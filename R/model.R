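#' Construct a metabolic model
#'
#' The central container: a stoichiometric network with flux bounds, GPR
#' rules and an objective reaction, in the COBRA convention (exchange flux
#' negative = uptake, positive = secretion; fluxes in mmol/gDW/h; biomass
#' molecular weight treated as 1 g/mmol so biomass flux is on a 1/h scale).
#'
#' @param name model name
#' @param metabolites data.frame with columns `id`, `name`, `formula`
#'   (Hill notation, may be ""), `charge` (integer, `NA` if unknown),
#'   `compartment`, and optionally a list column `annotation` of named
#'   character vectors (e.g. `c(modelseed = "cpd00036")`).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, optionally `class`, plus list columns
#'   `stoichiometry` (named numeric, metabolite id -> coefficient,
#'   negative = consumed) and `gpr` (objects from [parse_gpr()], or GPR
#'   strings which are parsed on construction).
#' @param genes character vector of gene ids; genes referenced by GPRs but
#'   not listed are auto-registered with a warning.
#' @param objective id of the objective (biomass or symbiotic) reaction.
#' @param compartments optional named character vector id -> name.
#' @return an object of class `metabolic_model`
#' @export
metabolic_model <- function(name, metabolites, reactions, genes = character(),
                            objective, compartments = NULL) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)

  if (is.null(metabolites$annotation)) {
    metabolites$annotation <- I(rep(list(character()), nrow(metabolites)))
  }
  if (is.null(metabolites$formula)) metabolites$formula <- ""
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id

  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$class)) reactions$class <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- I(rep(list(NULL), nrow(reactions)))

  # accept GPR strings for convenience
  reactions$gpr <- I(lapply(reactions$gpr, function(g) {
    if (is.character(g)) parse_gpr(g) else g
  }))

  model <- structure(
    list(name = name, metabolites = metabolites, reactions = reactions,
         genes = unique(genes), objective = objective,
         compartments = compartments),
    class = "metabolic_model"
  )
  model$reactions$class <- classify_reactions(model)
  validate_model(model)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a
#' metabolite, that every GPR leaf resolves to a registered gene
#' (unresolved genes are auto-registered with a warning, matching the
#' tolerant behaviour of COBRA readers), that bounds are ordered, that
#' stoichiometries are non-empty, and that the objective resolves.
#'
#' @param model a `metabolic_model`
#' @return the (possibly gene-augmented) model, invisibly usable
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids: ",
    paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids: ",
    paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))

  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[i]]
    if (length(st) == 0L) stop("reaction ", rxn_ids[i], " has empty stoichiometry")
    bad <- setdiff(names(st), met_ids)
    if (length(bad)) stop("reaction ", rxn_ids[i],
                          " references unknown metabolites: ", paste(bad, collapse = ", "))
  }
  if (any(model$reactions$lower_bound > model$reactions$upper_bound + 1e-12)) {
    off <- rxn_ids[model$reactions$lower_bound > model$reactions$upper_bound + 1e-12]
    stop("lower_bound > upper_bound for: ", paste(off, collapse = ", "))
  }

  gpr_refs <- unique(unlist(lapply(model$reactions$gpr, gpr_genes), use.names = FALSE))
  unresolved <- setdiff(gpr_refs, model$genes)
  if (length(unresolved)) {
    warning("auto-registering ", length(unresolved),
            " gene(s) referenced by GPRs but not listed: ",
            paste(utils::head(unresolved, 5), collapse = ", "),
            if (length(unresolved) > 5) ", ..." else "")
    model$genes <- c(model$genes, unresolved)
  }

  if (is.null(model$objective) || !model$objective %in% rxn_ids) {
    stop("objective reaction '", model$objective, "' not found in model")
  }
  model
}

# reaction_class inference, priority: explicit annotation > id prefix > structure
classify_reactions <- function(model) {
  rxns <- model$reactions
  comp_of <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  out <- character(nrow(rxns))
  for (i in seq_len(nrow(rxns))) {
    cls <- rxns$class[i]
    if (!is.na(cls) && nzchar(cls)) { out[i] <- cls; next }
    id <- rxns$id[i]
    st <- rxns$stoichiometry[[i]]
    if (grepl("^EX_", id)) { out[i] <- "exchange"; next }
    if (grepl("^DM_", id)) { out[i] <- "demand"; next }
    if (grepl("^SK_", id)) { out[i] <- "sink"; next }
    if (identical(id, model$objective) ||
        grepl("biomass|symbio", id, ignore.case = TRUE)) { out[i] <- "biomass"; next }
    if (length(st) == 1L) {
      # single-metabolite boundary reaction
      if (rxns$lower_bound[i] < 0 && rxns$upper_bound[i] > 0) out[i] <- "exchange"
      else if (rxns$lower_bound[i] >= 0) out[i] <- "demand"
      else out[i] <- "sink"
      next
    }
    base <- sub("_[a-z0-9]$", "", names(st))
    comps <- comp_of[names(st)]
    if (length(unique(comps)) > 1L && anyDuplicated(base)) { out[i] <- "transport"; next }
    if (gpr_is_empty(rxns$gpr[[i]]) && grepl("spontaneous", rxns$name[i], ignore.case = TRUE)) {
      out[i] <- "spontaneous"; next
    }
    out[i] <- "enzymatic"
  }
  out
}

#' Stoichiometric matrix of a model
#' @param model a `metabolic_model`
#' @return numeric matrix, metabolites x reactions, dimnames set
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Reaction ids of a given class
#' @param model a `metabolic_model`
#' @param class reaction classes to select, e.g. `"exchange"`
#' @return character vector of reaction ids
#' @export
reactions_of_class <- function(model, class) {
  model$reactions$id[model$reactions$class %in% class]
}

rxn_row <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

met_row <- function(model, id) {
  i <- match(id, model$metabolites$id)
  if (anyNA(i)) stop("unknown metabolite id(s): ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Set flux bounds on one or more reactions
#' @param model a `metabolic_model`
#' @param ids reaction ids
#' @param lower,upper new bounds (recycled); `NULL` leaves a side unchanged
#' @return the modified model
#' @export
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  i <- rxn_row(model, ids)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- rep_len(lower, length(i))
  if (!is.null(upper)) model$reactions$upper_bound[i] <- rep_len(upper, length(i))
  model
}

#' Knock out reactions (fix flux to zero)
#' @param model a `metabolic_model`
#' @param ids reaction ids to disable
#' @return the modified model
#' @export
knockout_reactions <- function(model, ids) set_bounds(model, ids, 0, 0)

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$name, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   genes: ", length(x$genes), "\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  tab <- table(x$reactions$class)
  cat("  classes:     ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  invisible(x)
}
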