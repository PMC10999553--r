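#' Build an expression profile
#'
#' A profile maps gene ids to protein abundance (mean peptide counts,
#' dimensionless, >= 0). Genes not present in a model are retained and can
#' be flagged via [map_homologs()] / downstream joins.
#'
#' @param abundance named numeric, gene id -> abundance (>= 0)
#' @param condition condition label, e.g. `"logarithmic"` or `"W05"`
#' @return an `expression_profile`
#' @export
expression_profile <- function(abundance, condition = "unspecified") {
  abundance <- unlist(abundance)
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  structure(list(abundance = abundance, condition = condition),
            class = "expression_profile")
}

#' Read an expression profile from TSV
#'
#' Columns: `gene_id`, then one or more numeric abundance/replicate
#' columns, which are averaged (the study averaged the peptide counts of
#' three replicate experiments).
#'
#' @param path TSV path with header; `#` comments allowed
#' @param condition condition label
#' @return an `expression_profile`
#' @export
read_expression_tsv <- function(path, condition = "unspecified") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs gene_id plus >= 1 abundance column")
  vals <- rowMeans(as.matrix(df[, -1, drop = FALSE]), na.rm = TRUE)
  expression_profile(stats::setNames(vals, df[[1]]), condition = condition)
}

#' Reaction-level expression from a GPR rule
#'
#' Aggregates gene abundances through the GPR: `and` nodes (complexes)
#' take the minimum of their children, `or` nodes (isozymes) the sum
#' (`or_rule = "max"` selects the maximum instead). A missing gene
#' contributes `missing_value`; with the default `NA` the whole reaction
#' becomes unconstrained (peptide non-detection is not evidence of
#' absence). The empty rule returns `NA` (unconstrained sentinel).
#'
#' @param gpr a `gpr` object
#' @param profile an `expression_profile`
#' @param or_rule `"sum"` (default) or `"max"`
#' @param missing_value abundance assumed for unmeasured genes; default
#'   `NA` = treat the reaction as unconstrained
#' @return abundance, or `NA` for unconstrained
#' @export
reaction_expression <- function(gpr, profile, or_rule = c("sum", "max"),
                                missing_value = NA_real_) {
  or_rule <- match.arg(or_rule)
  if (gpr_is_empty(gpr)) return(NA_real_)
  ab <- profile$abundance
  agg <- function(node) {
    if (node$op == "gene") {
      return(if (node$gene %in% names(ab)) ab[[node$gene]] else missing_value)
    }
    vals <- vapply(node$args, agg, numeric(1))
    if (anyNA(vals)) return(NA_real_)
    if (node$op == "and") min(vals)
    else if (or_rule == "sum") sum(vals) else max(vals)
  }
  agg(gpr)
}

#' E-Flux: condition-specific model from protein abundance
#'
#' The E-Flux procedure implemented here follows three steps:
#' 1. apply the media and compute each reaction's attainable flux range by
#'    FVA at `fraction_of_optimum = 0`;
#' 2. clamp the ranges so zero stays attainable (positive minima and
#'    negative maxima are set to 0), so that down-scaling can never make
#'    the model infeasible;
#' 3. for every reaction with a finite expression `e` (via
#'    [reaction_expression()]), scale both clamped bounds by `e / e_max`,
#'    where `e_max` is the maximum reaction-level expression in the model.
#'    Reactions with the unconstrained sentinel keep their clamped bounds.
#'
#' Scaling the whole profile by a constant leaves the result unchanged,
#' and no bound is ever widened. With `clamp = "bounds"` the clamping acts
#' on the original model bounds instead of FVA ranges (the alternative
#' reading of the preprocessing step).
#'
#' @param model a `metabolic_model`
#' @param profile an `expression_profile`
#' @param media optional `media_condition` applied first
#' @param or_rule,missing_value passed to [reaction_expression()]
#' @param clamp `"fva"` (default) or `"bounds"`
#' @return the condition-specific `metabolic_model`
#' @export
eflux_transform <- function(model, profile, media = NULL,
                            or_rule = c("sum", "max"),
                            missing_value = NA_real_,
                            clamp = c("fva", "bounds")) {
  or_rule <- match.arg(or_rule)
  clamp <- match.arg(clamp)
  if (!is.null(media)) model <- apply_media(model, media, close_others = FALSE)

  if (clamp == "fva") {
    ranges <- fva(model, fraction_of_optimum = 0)
    lb <- ranges$min; ub <- ranges$max
  } else {
    lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  }
  lb <- pmin(lb, 0)  # 0 always attainable after clamping
  ub <- pmax(ub, 0)

  expr <- vapply(model$reactions$gpr, reaction_expression, numeric(1),
                 profile = profile, or_rule = or_rule,
                 missing_value = missing_value)
  finite <- is.finite(expr)
  if (!any(finite)) stop("no reaction has finite expression; cannot scale")
  e_max <- max(expr[finite])
  if (e_max <= 0) stop("all reaction expressions are zero; no scale for E-Flux")

  scale <- ifelse(finite, expr / e_max, 1)
  model$reactions$lower_bound <- lb * scale
  model$reactions$upper_bound <- ub * scale
  model
}

#' Read a homolog map from TSV
#'
#' Columns: `source_id`, `target_id`, `bbh_ratio` (percent). Used to
#' carry expression measured in one strain onto the genes of another via
#' best bidirectional hits (BBH).
#'
#' @param path TSV path with header; `#` comments allowed
#' @param min_ratio minimum BBH ratio retained (default 90, the study
#'   threshold)
#' @return a `homolog_map` (data.frame with the threshold as attribute)
#' @export
read_homolog_tsv <- function(path, min_ratio = 90) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  homolog_map(df, min_ratio = min_ratio)
}

#' Construct a homolog map
#' @param pairs data.frame with columns `source_id`, `target_id`,
#'   `bbh_ratio`
#' @param min_ratio minimum BBH ratio retained
#' @return a `homolog_map`
#' @export
homolog_map <- function(pairs, min_ratio = 90) {
  need <- c("source_id", "target_id", "bbh_ratio")
  if (!all(need %in% names(pairs))) {
    stop("homolog map needs columns: ", paste(need, collapse = ", "))
  }
  structure(pairs[, need], class = c("homolog_map", "data.frame"),
            min_ratio = min_ratio)
}

#' Map an expression profile onto another strain's genes via homologs
#'
#' Keeps only pairs at or above the BBH ratio threshold; when several
#' retained sources map to one target, the highest-ratio pair wins (the
#' best matching outcome of the bidirectional comparison). Sources with no
#' retained hit are dropped and counted in the `dropped_sources`
#' attribute of the result.
#'
#' @param profile an `expression_profile` keyed by source-strain genes
#' @param map a `homolog_map`
#' @return an `expression_profile` keyed by target-strain genes
#' @export
map_homologs <- function(profile, map) {
  stopifnot(inherits(map, "homolog_map"))
  thr <- attr(map, "min_ratio")
  keep <- map[map$bbh_ratio >= thr & map$source_id %in% names(profile$abundance), ]
  keep <- keep[order(-keep$bbh_ratio), ]
  best <- keep[!duplicated(keep$target_id), ]
  out <- expression_profile(
    stats::setNames(profile$abundance[best$source_id], best$target_id),
    condition = profile$condition)
  attr(out, "dropped_sources") <-
    setdiff(names(profile$abundance), keep$source_id)
  out
}
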