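# turnovernet

Social network analysis of catastrophic turnover events in group-living
animals, from raw RFID visit logs to fitted behavioural-response models.

## The problem

When a population monitored through nest-box (or roost/burrow) transponder
antennae suddenly loses a large fraction of its members — predation, disease,
a natural disaster — the survivors' social world changes twice over: directly,
because partners are gone, and indirectly, because survivors rewire their
remaining associations. `turnovernet` implements the complete analysis chain
for quantifying both effects from timed co-occupancy data, for behavioural
ecologists working with automatically logged association data.

The core quantities:

* **Association weight** between two individuals in a time window: the
  duration-based simple ratio index
  `w_ij = x_ij / (t_i + t_j − x_ij)`, where `x_ij` is the time the pair
  spent in the same box together and `t_i`, `t_j` are each individual's
  total in-box times. `w_ij ∈ [0, 1]`.
* **Centrality change**: degree `k_i`, strength `s_i = Σ_j w_ij` (the
  sociality measure) and betweenness (shortest paths under distance
  `d_ij = 1/w_ij`), each differenced against the last pre-event window in a
  survivor-restricted network stack.
* **Loss proportion** `ℓ_i = Σ_{j missing} w_ij / Σ_j w_ij`: the share of
  pre-event association strength a survivor lost.
* **Null model**: synchronized node-identity swaps — one chain of random
  transpositions (1000 burn-in, then one randomized labelling every 10
  swaps, 1000 labellings = 11 000 swaps) applied identically to every
  window, preserving all structure while shuffling who sits where; add-one
  two-sided empirical p-values per model coefficient.
* **Dynamic communities**: per-window Infomap (or Louvain) partitions linked
  across windows by strict reciprocal majority, with persistent identities,
  movement events (count, mover range, cross-section flag) and alluvial
  flow tables.
* **Response models**: location–scale hierarchical regression — mean model
  `Δmetric ~ timestep × sociality × loss` with individual random intercepts
  and a log-linear model for the residual spread in `sociality × loss` —
  fitted by exact profiled maximum likelihood, fast enough for a thousand
  permutation refits.

A fully parameterized generator of synthetic nest-box visit streams (group
structure, heterogeneous sociality, a scripted catastrophe, tunable
post-event behavioural responses) makes the entire pipeline testable without
field data.

## A worked example

Simulate a barn population of 120 tagged adults in 8 social groups, lose
~40% of them to a scripted predation event, and run the whole analysis:

```r
library(turnovernet)

cfg <- scenario_config(n_individuals = 120, n_groups = 8, seed = 1,
                       response_effect_low_social = 8,
                       response_effect_high_social = 2.5)
report <- run_pipeline(cfg)
report$summary
```

```
 window phase nodes edges edge_density survivor_edge_density modularity groups_3plus
      1   pre   117   495       0.0729                0.0810      0.602           10
      2   pre   120   522       0.0731                0.0776      0.651           12
      3  post    72   163       0.0638                0.0648      0.721           10
      4  post    71   129       0.0519                0.0537      0.711           11
      5  post    71    90       0.0362                0.0379      0.745           12
      6  post    71    66       0.0266                0.0281      0.778           10
```

Pre-event, the planted structure gives an edge density of about 0.07,
modularity around 0.6 and 10-12 social groups of three or more members. At
the event the node count drops from 120 to 72; over the post-event windows
the scripted insularity response ramps up, so edges thin out and modularity
climbs while the number of groups barely changes. The behavioural responses
themselves live in the fitted degree-change model
(`report$model_fits$d_degree.interaction`): evaluating the loss slope from
its coefficients at one standard deviation below and above mean sociality
gives, for window 5, +0.29 versus -0.37 and, for window 6, +0.67 versus
-1.81 — weakly social survivors that lost many partners accumulate new weak
ties while highly social ones shed partners, and the contrast widens over
time. The same fit on a null scenario (both response effects 0) shows
interaction coefficients near zero.

Dynamic-community tracking reports the movements behind these numbers:

```r
report$movements$n_events        # 202 movement events across the five window pairs
report$movements$n_cross_section # 81 of them between barn sections
report$movements$mover_range     # events involve 1 to 7 individuals
```

(The strict reciprocal-majority rule hands a fresh identity to any
community without an unambiguous predecessor, and every member of a
relabelled community counts as a mover — so a strongly perturbed scenario
like this one churns out far more movement events than a stable
population would.)

For significance against random association, add the permutation test:

```r
scen   <- simulate_scenario(cfg)
stacks <- make_stacks(scen$events, scen$schedule, scen$roster)
chain  <- generate_swap_chain(stack_nodes(stacks$survivor), seed = 2)  # 11 000 swaps
pt <- permutation_effect_test(stacks$survivor, scen$attributes, chain,
                              response = "d_degree")
subset(pt$pvalues, term == "sociality_std:loss_std")
```

Every stage is also exposed on its own (`build_network()`,
`node_metrics()`, `delta_from_baseline()`, `detect_communities()`,
`link_windows()`, `movement_events()`, `fit_location_scale()`, ...) and the
pipeline reads real event logs from CSV (`individual_id, box_id, section,
entry, exit` in epoch seconds) instead of simulating — see
`?run_pipeline` and the vignette `vignettes/turnover-analysis.Rmd` for the
model details, assumptions and design decisions.

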