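#' Read a metabolic model from COBRA-JSON
#'
#' Understands the cobrapy JSON schema: top-level `metabolites`,
#' `reactions` (with `metabolites` stoichiometry maps, `lower_bound`,
#' `upper_bound`, `gene_reaction_rule`, `objective_coefficient`,
#' `subsystem`), `genes`, and optional `compartments`. The objective is
#' the reaction with a nonzero `objective_coefficient`; a model without
#' one is rejected. Reaction classes are taken from an explicit
#' `notes$reaction_class` when present, otherwise inferred from id
#' prefixes (`EX_`/`DM_`/`SK_`) and boundary structure.
#'
#' @param path path to a `.json` model file
#' @return a `metabolic_model`
#' @export
read_cobra_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("not a COBRA-JSON model (missing metabolites/reactions): ", path)
  }

  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = m$name %||% m$id,
               formula = m$formula %||% "",
               charge = as.integer(m$charge %||% NA_integer_),
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  mets$annotation <- I(lapply(doc$metabolites, function(m) {
    ann <- m$annotation
    if (is.null(ann)) return(character())
    unlist(lapply(ann, function(v) paste(unlist(v), collapse = ";")))
  }))

  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id,
               name = r$name %||% r$id,
               lower_bound = as.numeric(r$lower_bound %||% -BIG_BOUND),
               upper_bound = as.numeric(r$upper_bound %||% BIG_BOUND),
               subsystem = r$subsystem %||% "",
               class = (r$notes$reaction_class %||% NA_character_),
               stringsAsFactors = FALSE)
  }))
  rxns$stoichiometry <- I(lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) numeric() else st
  }))
  rxns$gpr <- I(lapply(doc$reactions, function(r) {
    parse_gpr(r$gene_reaction_rule %||% "")
  }))

  genes <- vapply(doc$genes, function(g) g$id, character(1))

  obj_coef <- vapply(doc$reactions, function(r) as.numeric(r$objective_coefficient %||% 0), numeric(1))
  if (!any(obj_coef != 0)) stop("model has no objective reaction (no nonzero objective_coefficient)")
  objective <- rxns$id[which(obj_coef != 0)[1]]

  comp <- if (!is.null(doc$compartments)) unlist(doc$compartments) else NULL
  metabolic_model(name = doc$id %||% basename(path),
                  metabolites = mets, reactions = rxns, genes = genes,
                  objective = objective, compartments = comp)
}

#' Write a metabolic model to COBRA-JSON
#'
#' Inverse of [read_cobra_json()]: the round trip preserves ids, names,
#' bounds, stoichiometry, GPR truth tables, the objective, annotations and
#' inferred reaction classes (stored under `notes$reaction_class`).
#'
#' @param model a `metabolic_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cobra_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                formula = m$formula)
    if (!is.na(m$charge)) out$charge <- m$charge
    ann <- model$metabolites$annotation[[i]]
    if (length(ann)) out$annotation <- as.list(ann)
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    list(id = r$id, name = r$name,
         metabolites = as.list(model$reactions$stoichiometry[[i]]),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = gpr_to_string(model$reactions$gpr[[i]]),
         subsystem = r$subsystem,
         objective_coefficient = as.numeric(r$id == model$objective),
         notes = list(reaction_class = r$class))
  })
  genes <- lapply(model$genes, function(g) list(id = g, name = g))
  doc <- list(id = model$name, metabolites = mets, reactions = rxns, genes = genes)
  if (!is.null(model$compartments)) doc$compartments <- as.list(model$compartments)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model in either supported dialect
#'
#' @param path model file
#' @param dialect `"cobra-json"` or `"sbml"`; default guessed from the
#'   file extension
#' @return a `metabolic_model`
#' @export
load_model <- function(path, dialect = c("auto", "cobra-json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "cobra-json"
  }
  switch(dialect,
         "cobra-json" = read_cobra_json(path),
         "sbml" = read_sbml_fbc(path))
}

#' Write a model in either supported dialect
#' @param model a `metabolic_model`
#' @param path output file; dialect guessed from extension unless given
#' @param dialect `"cobra-json"` or `"sbml"`
#' @return `path`, invisibly
#' @export
write_model <- function(model, path, dialect = c("auto", "cobra-json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "cobra-json"
  }
  switch(dialect,
         "cobra-json" = write_cobra_json(model, path),
         "sbml" = write_sbml_fbc(model, path))
}

#' Export a flux solution as TSV
#' @param solution a `flux_solution`
#' @param path output path (columns reaction_id, flux)
#' @return `path`, invisibly
#' @export
write_flux_tsv <- function(solution, path) {
  df <- data.frame(reaction_id = names(solution$fluxes),
                   flux = unname(solution$fluxes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
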