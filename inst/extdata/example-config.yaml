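# Example run configuration for run_pipeline() / read_run_config().
seed: 7
outdir: ordival_run
stages: [simulate, filter, modelfree, fit, correlate]
trial_seed: 0
cohort:
  n_agents: 50
  cross_domain_rho: 0.4
  cross_phase_rho: 0.5
  aberrant_fractions:
    catch_failer: 0.05
    never_uncertain: 0.03
    duplicate_id: 0.02
model:
  variant: ordinal
grid:
  step: 0.5
cv:
  k: 5
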