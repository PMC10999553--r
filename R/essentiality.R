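#' Single-gene deletion screen
#'
#' For each gene, every reaction whose GPR rule evaluates to `FALSE` under
#' the deletion is constrained to zero flux, the model objective is
#' re-optimised by FBA, and the mutant/wild-type growth ratio classifies
#' the gene: `essential` when ratio <= `threshold` (study cutoff 0.05),
#' `growth_affecting` when ratio < 1 (by more than numerical tolerance)
#' but above the essentiality cutoff, otherwise `neutral`. Genes absent
#' from every GPR are neutral by construction; reactions without gene
#' association are never disabled.
#'
#' In the published usage essential genes are a subset of the
#' growth-affecting set, so the growth-affecting count is
#' `sum(label != "neutral")`.
#'
#' @param model a condition-specific `metabolic_model` (media applied,
#'   objective set)
#' @param genes genes to screen; default all model genes
#' @param threshold mutant/wild-type ratio at or below which a gene is
#'   essential (default 0.05)
#' @return data.frame: `element_id`, `wild_type_growth`, `mutant_growth`,
#'   `ratio`, `label`
#' @export
single_gene_deletion <- function(model, genes = model$genes, threshold = 0.05) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type growth is ", if (wt$status == "optimal") "zero" else wt$status,
         "; deletion ratios undefined")
  }
  gpr_list <- model$reactions$gpr
  gene_hits <- lapply(gpr_list, gpr_genes)

  mutant <- vapply(genes, function(g) {
    touches <- vapply(gene_hits, function(gs) g %in% gs, logical(1))
    if (!any(touches)) return(wt$objective_value)
    off <- which(touches)[!vapply(which(touches), function(j) {
      evaluate_gpr(gpr_list[[j]], deleted = g)
    }, logical(1))]
    if (!length(off)) return(wt$objective_value)
    m2 <- knockout_reactions(model, model$reactions$id[off])
    sol <- fba(m2)
    if (sol$status != "optimal") 0 else max(0, sol$objective_value)
  }, numeric(1))

  essentiality_table(genes, wt$objective_value, mutant, threshold)
}

#' Single-reaction deletion screen
#'
#' As [single_gene_deletion()], but each reaction is individually
#' constrained to `lb = ub = 0`. A blocked reaction is always neutral.
#'
#' @inheritParams single_gene_deletion
#' @param reactions reaction ids to screen; default all
#' @return data.frame as in [single_gene_deletion()]
#' @export
single_reaction_deletion <- function(model, reactions = model$reactions$id,
                                     threshold = 0.05) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type growth is ", if (wt$status == "optimal") "zero" else wt$status,
         "; deletion ratios undefined")
  }
  mutant <- vapply(reactions, function(r) {
    sol <- fba(knockout_reactions(model, r))
    if (sol$status != "optimal") 0 else max(0, sol$objective_value)
  }, numeric(1))
  essentiality_table(reactions, wt$objective_value, mutant, threshold)
}

essentiality_table <- function(ids, wt, mutant, threshold, tol = 1e-6) {
  ratio <- mutant / wt
  label <- ifelse(ratio <= threshold, "essential",
                  ifelse(ratio < 1 - tol, "growth_affecting", "neutral"))
  data.frame(element_id = ids, wild_type_growth = wt, mutant_growth = mutant,
             ratio = ratio, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a deletion screen as TSV
#' @param screen result of [single_gene_deletion()] or
#'   [single_reaction_deletion()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
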