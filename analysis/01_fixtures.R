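#!/usr/bin/env Rscript
# Build the synthetic benchmark networks the downstream analyses run on,
# re-verify their planted ground truth against the brute-force vertex
# oracle, and write them (with truth sidecars) under results/fixtures/.
suppressPackageStartupMessages(library(rhizoflux))

out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fixtures <- list(
  chain3 = make_chain_model(1, 10),
  chain5 = make_chain_model(5, 2.5),
  branched = make_branched_model("equivalent"),
  branched_dead_end = make_branched_model("dead_end"),
  isozyme = make_isozyme_model(),
  symbiosis = make_symbiosis_toy()
)

for (name in names(fixtures)) {
  fix <- fixtures[[name]]
  ora <- oracle_fba(fix$model)
  stopifnot(abs(ora$objective_value - fix$truth$optimum) < 1e-6)
  write_fixture(fix, out, name = name)
  cat(sprintf("%-18s %2d reactions, oracle optimum %.4f\n",
              name, nrow(fix$model$reactions), ora$objective_value))
}

# SBML export of the symbiosis toy, for tools that speak FBC
write_sbml_fbc(fixtures$symbiosis$model, file.path(out, "symbiosis.xml"))
cat("fixtures written to", out, "\n")
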