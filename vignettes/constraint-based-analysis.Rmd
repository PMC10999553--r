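---
title: "Constraint-based analysis of rhizobial metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of rhizobial metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoflux)
```

## The modelling framework

A genome-scale metabolic model (GSMM) represents an organism's metabolism
as a stoichiometric matrix $S$ (metabolites $\times$ reactions) with flux
bounds $l \le v \le u$ on every reaction (mmol/gDW/h) and boolean
gene-protein-reaction (GPR) rules linking genes to reactions (`and` =
enzyme complex, `or` = isozymes). At steady state, flux balance analysis
(FBA) solves the linear program

$$\max\; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

where $c$ selects an objective pseudo-reaction. For a rhizobium two
objectives matter: a *biomass* equation for the free-living cell and a
*symbiotic-product* equation for the bacteroid, whose defining output is
fixed ammonia delivered to the host plant. The biomass molecular weight is
treated as 1 g/mmol, so biomass flux is on a 1/h-equivalent scale and is
not rescaled. Exchange fluxes follow the COBRA sign convention: negative =
uptake, positive = secretion. Media are therefore stated as positive
uptake rates and applied as negative lower bounds; the free-living
condition uses malate 1.44, succinate 1.38, oxygen 1.26, glutamate 2 and
inositol 0.01 mmol/gDW/h, and the symbiotic condition succinate 1.38 and
malate 1.44 mmol/gDW/h.

Flux variability analysis (FVA) reports, per reaction, the minimum and
maximum flux compatible with the constraints and (optionally) with
retaining a fraction of the FBA optimum. Because FBA optima are typically
degenerate, all conclusions about individual fluxes in this package go
through FVA ranges or objective values, never a single arbitrary optimal
vertex.

## The linear and quadratic solvers

FBA and FVA run on a dense bounded-variable two-phase primal simplex
implemented in the package (Bland's rule for anti-cycling, feasibility
tolerance $10^{-9}$). A hand-written solver was chosen after the available
general-purpose routines proved unreliable on precisely the degenerate,
box-constrained problems metabolic networks generate; correctness is
enforced two independent ways in the test suite: every fixture's optimum
is compared against a brute-force vertex-enumeration oracle
(`oracle_fba()`, exhaustive and solver-free), and an exported model is
re-optimised by the Python COBRA stack in an interoperability test.
Unbounded directions cannot arise in practice because every unbounded
reaction is clipped to the conventional $\pm 1000$ mmol/gDW/h span.

Minimization of metabolic adjustment (MOMA) predicts the flux state of a
perturbed network as the point of its feasible set closest (Euclidean) to
a reference flux distribution — a strictly convex quadratic program with a
unique solution, solved with `quadprog`. The reference defaults to the
wild-type FBA solution; since that reference may itself be degenerate,
small discrepancies between equally optimal references are an acknowledged
source of variation in MOMA outputs.

## Model I/O and quality control

Models round-trip through COBRA-JSON and through an SBML Level 3 FBC
subset (species with charge/formula, parameter-backed bounds, gene-product
associations, an active objective). Reaction classes
(enzymatic/transport/exchange/demand/sink/biomass/spontaneous) are taken
from explicit annotation when present, then from id prefixes
(`EX_`/`DM_`/`SK_`), then inferred from boundary structure — deposited
models vary widely in annotation completeness, so inference is layered
rather than trusted to any single convention.

Three gap diagnostics are provided. *Blocked reactions* are detected by
FVA at fraction 0 with all exchanges opened, so the result is independent
of medium and objective (verified as a property test); the report excludes
exchange and transport reactions by convention, and the zero tolerance is
$10^{-9}$, below the solver's feasibility tolerance. *Duplicate
metabolites* are grouped within a compartment by identical non-empty
formula+charge or by a shared external database annotation, via
union-find, so transitive aliases collapse into one group. *Dead-end
metabolites* are those that can only ever be produced or only consumed,
counting boundary reactions — a demand reaction is exactly what resolves a
dead end, so a metabolite drained by one is not reported.

## Deletion screens and E-Flux

Gene deletion constrains to zero every reaction whose GPR evaluates false
under the deletion and re-runs FBA. A gene or reaction is *essential* when
the mutant/wild-type growth ratio is at or below 0.05 (the study cutoff,
configurable), *growth-affecting* when the ratio falls below 1 by more
than $10^{-6}$ (no published cutoff exists for this class; the tolerance
is purely numerical), and *neutral* otherwise; essential elements are a
subset of growth-affecting ones, matching the published counting. Screens
are run against the condition-specific model (free-living medium with the
biomass objective, or symbiotic uptakes with the symbiotic objective). The
free-living screen uses the unconstrained (not E-Flux-scaled) model by
default, which is the more reproducible reading of the published setup.

E-Flux builds a condition-specific model from protein abundance (mean
peptide counts). Reaction-level expression aggregates the GPR with
`and` $\to$ min and `or` $\to$ sum — the standard E-Flux convention; the
aggregation is configurable (`or_rule = "max"`) because published
descriptions often omit the rule and results are sensitive to it. The
preprocessing first computes attainable flux ranges by FVA at fraction 0,
clamps them so zero remains attainable (positive minima and negative
maxima set to 0), then scales both clamped bounds by $e/e_{\max}$, where
$e_{\max}$ is the maximum *reaction-level* expression (bounds are
per-reaction, so a reaction-level normaliser is the consistent choice).
Clamping original bounds instead of FVA ranges is available as
`clamp = "bounds"`, since the published preprocessing sentence admits both
readings; the FVA reading is the default because it guarantees the scaled
model stays feasible. A gene without a measurement contributes the
unconstrained sentinel rather than zero — peptide non-detection is not
evidence of absence, and zeroing unmeasured genes would silence most of a
genome-scale network. Expression measured in a sister strain is carried
over by best-bidirectional-hit homolog mapping with a 90% minimum ratio,
keeping the highest-ratio pair per target gene.

## Phenotype prediction

A sole-carbon-source test closes uptake through every exchange except the
tested one (non-carbon nutrients of a minimal medium stay open) and calls
growth when the biomass optimum exceeds $10^{-6}$ — above LP tolerance,
below any biological growth rate. Plate accuracy is (TP+TN)/tested;
substrates that cannot be mapped to any exchange reaction count as
mismatches, because a model that cannot represent a substrate cannot be
scored consistent with the experiment on it. The exact composition of the
minimal medium is configurable: published minimal media are rarely
itemised, and accuracy figures depend on which non-carbon nutrients are
open.

## Nitrogen-fixation modules and MOMA targets

Nitrogenase (EC 1.18.6.1) consumes reduced ferredoxin, so the reactions
able to produce reduced ferredoxin organise the nitrogen-fixation core
into modules. `module_knockout_report()` disables each module's producer
in turn and tabulates gross NADH/NADPH production, gross ATP production
(both as the sum of positive pool production over reactions — Tables of
this kind print single pooled numbers without defining them, so the gross
definition is documented prominently and a demand-reaction alternative is
selectable), the symbiotic production flux and the nitrogenase flux.

The overexpression scan emulates target finding: the wild type is the
symbiotic model with its fixed-NH3 exchange capped at 0.001 mmol/gDW/h and
its FBA solution is the MOMA reference. Each candidate's lower bound is
raised to `boost_factor` times its attainable FVA maximum measured on the
cap-released network — the cap must be released before measuring
attainability, otherwise the cap itself bounds the boost — and the
perturbed state is solved by MOMA. A boost the network cannot carry makes
the QP infeasible and is reported as zero rates (the "collapsed" case).
This operationalisation of "increasing" a reaction is the main
interpretive freedom in the procedure and is therefore fully configurable
(`boost_factor`, `release_cap`).

## Synthetic study networks

All tests and the acceptance script run on deterministic toy networks with
planted, oracle-verified ground truth:

* `make_chain_model(n, u)` — exchange → transport → n enzymatic steps →
  biomass; optimum = u, every gene essential, nothing blocked.
* `make_branched_model(variant)` — two parallel branches; variants plant
  an equivalent pair (FVA symmetry), a half-capacity branch (ratio-0.5
  deletion), or a dead-end branch (planted blocked set).
* `make_isozyme_model()` — one step under `"g1 or g2"`, the next under
  `"g3 and g4"`; planted essential set exactly `{g3, g4}`.
* `make_symbiosis_toy()` — succinate uptake at the symbiotic rate 1.38
  mmol/gDW/h, catabolism to ATP/NADH pools, ferredoxin reduction with an
  optional redundant isozyme reaction, nitrogenase, a fixed-NH3 exchange
  across the symbiosome boundary, and a symbiotic-product objective that
  consumes exported NH3 — so capping the NH3 exchange caps symbiotic
  production, mirroring the wiring the genome-scale analysis relies on.
  Its optimum has the closed form $2.76 \times 2.5 / 9.25 \approx 0.7459$
  (ATP supply over nitrogenase + product costs), asserted against the
  vertex oracle at generation time.

Ground truth is re-verified by brute force (vertex enumeration, truth
tables, reachability) every time a generator runs, and fixtures written to
disk carry a truth sidecar JSON so tests never have to trust the engine
under test. Problem sizes stay below ~14 reactions because the vertex
oracle is exponential; this is a deliberate choice to keep every planted
value independently checkable.

What the toys do *not* emulate: genome-scale size and degeneracy, realistic
peptide-count distributions, charge/mass imbalance, multi-compartment
transport chains. Passing on the toys therefore demonstrates algorithmic
correctness of every pipeline stage, not numerical agreement with any
particular deposited genome-scale model; the test suite's
genome-scale reproduction blocks run the same code paths against the
deposited model of *S. fredii* CCBAU45436 whenever a copy is placed under
`inst/extdata/`.

## Worked example

```{r example}
sy <- make_symbiosis_toy()
sol <- fba(sy$model)
sol$objective_value                       # symbiotic production, mmol/gDW/h

scan <- overexpression_scan(sy$model, c("FDR1", "NIT"),
                            nfix_exchange_id = "EX_NH3", nfix_cap = 0.001)
scan[, c("reaction", "fixed_nh3_rate", "wild_type_fixed_nh3")]
```

Boosting a ferredoxin producer lifts fixed-NH3 export from the capped
0.001 to the network's carbon-limited capacity of about 0.597 mmol/gDW/h.

## Known limitations

* The simplex is dense and exact-pivot; it is built for models up to a
  few thousand reactions, not for repeated genome-scale FVA in tight
  loops.
* MOMA reference degeneracy: different optimal wild-type vertices can
  shift scan outputs; fixing the reference (or passing one explicitly) is
  the reproducible path.
* Gross cofactor production is one of several defensible definitions of a
  "production rate"; comparisons against published pooled numbers should
  state the definition used.
* The SBML reader covers the FBC subset the package writes plus common
  COBRA exports; exotic SBML (initial assignments, species references by
  id) is out of scope.
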