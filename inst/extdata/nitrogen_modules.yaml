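# Nitrogen-fixation target configuration for the deposited iAQY970 model
# of Sinorhizobium fredii CCBAU45436. The module map lists the reduced-
# ferredoxin-producing reactions by ModelSEED id with their metabolic
# module. The carbon monoxide dehydrogenase reaction (Module 3, Carbon
# Metabolism) has no published ModelSEED id; identify it in the model and
# add it here before running the module-knockout reproduction. The
# objective/nitrogenase/exchange ids below likewise follow the deposited
# model's naming and should be checked against the downloaded file.
objective_id: SYM               # symbiotic-product objective reaction
nitrogenase_id: rxn06874        # nitrogenase, EC 1.18.6.1
fixed_nh3_exchange_id: EX_nh3   # fixed-NH3 exchange (capped at 0.001 in scans)
modules:
  rxn05937: Module 1            # ferredoxin-NADP+ reductase, EC 1.18.1.2
  rxn04113: Module 2            # xanthine dehydrogenase, EC 1.17.1.4
  rxn05902: Module 4            # sulfite reductase, EC 1.8.7.1
cofactor_pools:
  nadh:                         # NADH + NADPH, pooled across compartments
    - cpd00004
    - cpd00005
  atp:
    - cpd00002
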