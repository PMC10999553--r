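#' Find blocked reactions
#'
#' A reaction is blocked when it cannot carry nonzero flux in any feasible
#' steady state. Detection opens every exchange reaction to the default
#' bounds (so the result is independent of the medium and of the objective)
#' and runs FVA at `fraction_of_optimum = 0`; a reaction is blocked when
#' both its minimum and maximum are within `tolerance` of 0. By
#' convention, exchange and transport reactions are excluded from the
#' report (they mirror the model's boundary, not internal gaps); pass
#' `exclude_classes = character()` to report everything.
#'
#' @param model a `metabolic_model`
#' @param exclude_classes reaction classes removed from the report
#' @param tolerance absolute flux below which a range counts as zero;
#'   default 1e-9, below the LP feasibility tolerance
#' @param open_exchanges open all exchange bounds to the default span
#'   before testing (default `TRUE`)
#' @return character vector of blocked reaction ids
#' @export
find_blocked_reactions <- function(model,
                                   exclude_classes = c("exchange", "transport"),
                                   tolerance = 1e-9,
                                   open_exchanges = TRUE) {
  if (open_exchanges) {
    ex <- reactions_of_class(model, "exchange")
    if (length(ex)) model <- set_bounds(model, ex, lower = -BIG_BOUND, upper = BIG_BOUND)
  }
  ranges <- fva(model, fraction_of_optimum = 0)
  blocked <- ranges$reaction[abs(ranges$min) <= tolerance & abs(ranges$max) <= tolerance]
  keep <- !model$reactions$class[rxn_row(model, blocked)] %in% exclude_classes
  blocked[keep]
}

#' Find duplicate metabolites
#'
#' Flags metabolites that are likely aliases of the same compound:
#' members of a group share a compartment and either an identical
#' non-empty formula+charge pair or a shared external annotation (e.g. the
#' same KEGG or ModelSEED id). Empty formulas never match on formula.
#'
#' @param model a `metabolic_model`
#' @return list of character vectors, each a group of >= 2 metabolite ids;
#'   empty list when no duplicates are found
#' @export
find_duplicate_metabolites <- function(model) {
  mets <- model$metabolites
  n <- nrow(mets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }

  key_groups <- list()
  add_key <- function(key, i) {
    if (is.null(key_groups[[key]])) key_groups[[key]] <<- i
    else {
      union_(key_groups[[key]], i)
    }
  }
  for (i in seq_len(n)) {
    comp <- mets$compartment[i]
    f <- mets$formula[i]
    if (!is.na(f) && nzchar(f)) {
      add_key(paste0("F|", comp, "|", f, "|", mets$charge[i]), i)
    }
    ann <- mets$annotation[[i]]
    if (length(ann)) {
      for (k in seq_along(ann)) {
        add_key(paste0("A|", comp, "|", names(ann)[k], "|", ann[[k]]), i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(mets$id, roots)
  unname(groups[lengths(groups) > 1])
}

#' Find dead-end metabolites
#'
#' Metabolites that can only ever be produced or only ever consumed,
#' taking reaction reversibility into account. Boundary reactions count:
#' a demand or sink reaction is exactly what resolves a dead end, so a
#' metabolite drained by one is not reported. Dead ends are the
#' structural cause of most blocked reactions and the first place to look
#' when gap-filling.
#'
#' @param model a `metabolic_model`
#' @return character vector of dead-end metabolite ids
#' @export
find_dead_end_metabolites <- function(model) {
  can_produce <- can_consume <- stats::setNames(logical(nrow(model$metabolites)),
                                                model$metabolites$id)
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    fwd <- model$reactions$upper_bound[j] > 1e-12
    rev <- model$reactions$lower_bound[j] < -1e-12
    for (m in names(st)) {
      s <- st[[m]]
      if ((s > 0 && fwd) || (s < 0 && rev)) can_produce[m] <- TRUE
      if ((s < 0 && fwd) || (s > 0 && rev)) can_consume[m] <- TRUE
    }
  }
  touched <- can_produce | can_consume
  names(touched)[touched & (can_produce != can_consume)]
}
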