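# SBML Level 3 Version 1 + FBC v2 subset: species with charge/formula,
# reactions with parameter-backed flux bounds, gene product associations,
# and an active maximisation objective. Ids are written with the COBRA
# prefixes (R_/M_/G_) and stripped again on read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", id))

#' Read a metabolic model from SBML Level 3 with FBC
#'
#' Covers the subset written by [write_sbml_fbc()] and by COBRA
#' exporters: species (`fbc:charge`, `fbc:chemicalFormula`), flux bounds
#' referenced through parameters, `fbc:geneProductAssociation` trees, gene
#' products, and the active FBC objective. COBRA-style `R_`/`M_`/`G_` id
#' prefixes are stripped.
#'
#' @param path path to an `.xml`/`.sbml` file
#' @return a `metabolic_model`
#' @export
read_sbml_fbc <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing")) stop("not an SBML L3 document: ", path)

  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  fattr <- function(node, name) {
    a <- xml2::xml_attrs(node)
    for (key in c(paste0("fbc:", name), name)) {
      if (key %in% names(a)) return(unname(a[[key]]))
    }
    NULL
  }

  sp <- xml2::xml_find_all(mnode, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp, function(x) {
    data.frame(id = strip(xml2::xml_attr(x, "id"), "M_"),
               name = xml2::xml_attr(x, "name") %||% "",
               formula = fattr(x, "chemicalFormula") %||% "",
               charge = as.integer(fattr(x, "charge") %||% NA_integer_),
               compartment = xml2::xml_attr(x, "compartment"),
               stringsAsFactors = FALSE)
  }))
  mets$annotation <- I(rep(list(character()), nrow(mets)))

  pars <- xml2::xml_find_all(mnode, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    vapply(gps, function(x) fattr(x, "label") %||% strip(fattr(x, "id"), "G_"), character(1)),
    vapply(gps, function(x) fattr(x, "id"), character(1)))

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- fattr(node, "geneProduct")
      return(list(op = "gene", gene = unname(gp_label[ref] %||% strip(ref, "G_"))))
    }
    kids <- xml2::xml_children(node)
    gpr_node(if (nm == "and") "and" else "or", lapply(kids, parse_assoc))
  }

  notes_field <- function(node, field) {
    ps <- xml2::xml_find_all(node, ".//s:notes//*[local-name()='p']", ns)
    for (p in ps) {
      txt <- xml2::xml_text(p)
      m <- regmatches(txt, regexec(paste0("^\\s*", field, ":\\s*(.*)$"), txt))[[1]]
      if (length(m) == 2) return(trimws(m[2]))
    }
    NA_character_
  }

  rn <- xml2::xml_find_all(mnode, ".//s:listOfReactions/s:reaction", ns)
  rxns <- do.call(rbind, lapply(rn, function(x) {
    lbp <- fattr(x, "lowerFluxBound"); ubp <- fattr(x, "upperFluxBound")
    data.frame(id = strip(xml2::xml_attr(x, "id"), "R_"),
               name = xml2::xml_attr(x, "name") %||% "",
               lower_bound = if (!is.null(lbp)) unname(parval[lbp]) else -BIG_BOUND,
               upper_bound = if (!is.null(ubp)) unname(parval[ubp]) else BIG_BOUND,
               subsystem = notes_field(x, "subsystem") %||% "",
               class = notes_field(x, "reaction_class"),
               stringsAsFactors = FALSE)
  }))
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  rxns$stoichiometry <- I(lapply(rn, function(x) {
    re <- xml2::xml_find_all(x, "./s:listOfReactants/s:speciesReference", ns)
    pr <- xml2::xml_find_all(x, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(re, "stoichiometry")),
                      strip(xml2::xml_attr(re, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(pr, "stoichiometry")),
                      strip(xml2::xml_attr(pr, "species"), "M_")))
    # merge duplicate species appearing on both sides
    tapply_names <- unique(names(st))
    stats::setNames(vapply(tapply_names, function(m) sum(st[names(st) == m]),
                           numeric(1)), tapply_names)
  }))
  rxns$gpr <- I(lapply(rn, function(x) {
    assoc <- xml2::xml_find_first(x, "./fbc:geneProductAssociation", ns)
    if (inherits(assoc, "xml_missing")) return(parse_gpr(""))
    kids <- xml2::xml_children(assoc)
    if (!length(kids)) return(parse_gpr(""))
    structure(parse_assoc(kids[[1]]), class = "gpr", empty = FALSE)
  }))

  fobj <- xml2::xml_find_first(
    mnode, ".//fbc:listOfObjectives/fbc:objective//fbc:fluxObjective", ns)
  if (inherits(fobj, "xml_missing")) stop("SBML model has no FBC objective")
  objective <- strip(fattr(fobj, "reaction"), "R_")

  cn <- xml2::xml_find_all(mnode, ".//s:listOfCompartments/s:compartment", ns)
  comp <- stats::setNames(xml2::xml_attr(cn, "name") %||% xml2::xml_attr(cn, "id"),
                          xml2::xml_attr(cn, "id"))

  metabolic_model(name = xml2::xml_attr(mnode, "id") %||% basename(path),
                  metabolites = mets, reactions = rxns,
                  genes = unname(gp_label), objective = objective,
                  compartments = comp)
}

#' Write a metabolic model to SBML Level 3 with FBC
#'
#' @param model a `metabolic_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sbml_fbc <- function(model, path) {
  root <- xml2::xml_new_root("sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                             level = "3", version = "1", "fbc:required" = "false")
  mn <- xml2::xml_add_child(root, "model", id = sbml_id("", model$name),
                            "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (cmp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cmp, constant = "true")
  }

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    node <- xml2::xml_add_child(ls, "species", id = sbml_id("M_", m$id),
                                name = m$name, compartment = m$compartment,
                                hasOnlySubstanceUnits = "false",
                                boundaryCondition = "false", constant = "false")
    if (nzchar(m$formula)) xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(node, "fbc:charge", as.character(m$charge))
  }

  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    xml2::xml_add_child(lp, "parameter", id = paste0(sbml_id("R_", r$id), "_lb"),
                        value = format(r$lower_bound, digits = 17), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(sbml_id("R_", r$id), "_ub"),
                        value = format(r$upper_bound, digits = 17), constant = "true")
  }

  lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = sbml_id("R_", model$objective),
                      "fbc:coefficient" = "1")

  write_assoc <- function(parent, node) {
    if (node$op == "gene") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                         "fbc:geneProduct" = sbml_id("G_", node$gene))
    } else {
      sub <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
      for (a in node$args) write_assoc(sub, a)
    }
  }

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rid <- sbml_id("R_", r$id)
    node <- xml2::xml_add_child(lr, "reaction", id = rid, name = r$name,
                                reversible = tolower(as.character(r$lower_bound < 0)),
                                fast = "false",
                                "fbc:lowerFluxBound" = paste0(rid, "_lb"),
                                "fbc:upperFluxBound" = paste0(rid, "_ub"))
    notes <- xml2::xml_add_child(node, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("subsystem: ", r$subsystem))
    xml2::xml_add_child(body, "p", paste0("reaction_class: ", r$class))
    st <- model$reactions$stoichiometry[[i]]
    re <- st[st < 0]; pr <- st[st > 0]
    if (length(re)) {
      lre <- xml2::xml_add_child(node, "listOfReactants")
      for (m in names(re)) {
        xml2::xml_add_child(lre, "speciesReference", species = sbml_id("M_", m),
                            stoichiometry = format(-re[[m]], digits = 17),
                            constant = "true")
      }
    }
    if (length(pr)) {
      lpr <- xml2::xml_add_child(node, "listOfProducts")
      for (m in names(pr)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sbml_id("M_", m),
                            stoichiometry = format(pr[[m]], digits = 17),
                            constant = "true")
      }
    }
    g <- model$reactions$gpr[[i]]
    if (!gpr_is_empty(g)) {
      assoc <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      write_assoc(assoc, g)
    }
  }

  lgp <- xml2::xml_add_child(mn, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(lgp, "fbc:geneProduct", "fbc:id" = sbml_id("G_", g),
                        "fbc:label" = g)
  }

  xml2::write_xml(root, path)
  invisible(path)
}
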