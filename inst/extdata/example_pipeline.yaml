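# Example pipeline configuration: simulate a scripted turnover scenario and
# run every analysis stage. See ?run_pipeline and ?scenario_config.
simulate: true
scenario:
  n_individuals: 120
  n_groups: 8
  mortality_fraction: 0.18
  disappearance_fraction: 0.22
  response_effect_low_social: 8
  response_effect_high_social: 2.5
  seed: 1
communities:
  objective: map
  restarts: 10
models:
  responses: [d_degree, d_strength]
  variants: [interaction]
permutation_test: false
seed: 1
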