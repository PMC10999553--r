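#!/usr/bin/env Rscript
# FBA and FVA on the benchmark networks, plus the cofactor/production
# summary of the symbiosis toy under its dicarboxylate medium (the same
# quantities the genome-scale study tabulates: NADH/NADPH production, ATP
# production, symbiotic production, and the carbon uptake rates).
suppressPackageStartupMessages(library(rhizoflux))
dir.create("results", showWarnings = FALSE)

ch <- make_chain_model(1, 10)$model
sol <- fba(ch)
cat("chain FBA optimum:", sol$objective_value, "(uptake-limited)\n")
write_flux_tsv(sol, "results/chain_fba_fluxes.tsv")

rng <- fva(ch, fraction_of_optimum = 1)
utils::write.table(rng, "results/chain_fva.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("chain FVA at the optimum pins every reaction: range width",
    max(rng$max - rng$min), "\n")

sy <- make_symbiosis_toy()
ssol <- fba(sy$model)
summary <- data.frame(
  model = sy$model$name,
  nadh_nadph_production = production_rate(sy$model, ssol, sy$ids$cofactor_pools$nadh),
  atp_production = production_rate(sy$model, ssol, sy$ids$cofactor_pools$atp),
  symbiotic_production = ssol$objective_value,
  succinate_uptake = -unname(ssol$fluxes["EX_succ"]),
  nitrogen_fixation = unname(ssol$fluxes[sy$ids$nitrogenase_id]))
utils::write.table(summary, "results/symbiosis_flux_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf(paste0("symbiosis toy: symbiotic production %.4f, N-fixation %.4f,",
                   " ATP %.2f, NADH %.2f at succinate uptake %.2f\n"),
            summary$symbiotic_production, summary$nitrogen_fixation,
            summary$atp_production, summary$nadh_nadph_production,
            summary$succinate_uptake))
write_flux_tsv(ssol, "results/symbiosis_fba_fluxes.tsv")
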