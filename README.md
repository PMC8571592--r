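# arbormk

Inference of mammalian substrate-preference evolution (arboreal /
semi-arboreal / nonarboreal) on time-calibrated phylogenies, centered on
the Cretaceous-Paleogene (K-Pg) boundary at ca. 66.02 Ma.

## What it does, for whom

For comparative biologists asking how a three-state ecological character
evolved across a mass-extinction horizon, the package implements the full
inference chain as reusable, tested functions:

* **Structured Mk models** on the state space {arboreal (A),
  semi-arboreal (S), nonarboreal (N)}: a two-rate model (transitions
  touching S share one rate, direct A↔N another), the ordered four-rate
  model (A↔S and S↔N with separate forward/reverse rates, direct A↔N
  structurally forbidden), the six-rate ARD model, and hidden-rate-class
  expansions of these (k = 11, 13, 19) with a shared symmetric
  class-switch rate. Likelihoods by Felsenstein pruning over the expanded
  (state × class) space; maximum-likelihood fitting on log-rates with
  restarts; model choice by AIC (`model_selection_table`).
* **Ancestral state reconstruction**: exact marginal node probabilities
  (inside–outside) and Sankoff maximum-parsimony state sets with ties
  retained (`marginal_asr`, `parsimony_asr`).
* **Bayesian stochastic character mapping**: joint node-state draws from
  the exact conditionals followed by endpoint-conditioned path sampling
  via uniformization; mapping over a posterior tree sample with per-tree
  refit Q matrices, summarized onto a consensus tree by matching
  phylogenetically equivalent nodes (identical descendant leaf sets), with
  per-node clade frequencies (`generate_maps`, `summarize_maps`).
* **Transition rates through time**: for each ordered transition type,
  mean event counts in 50 equal-width time bins divided by the branch
  length within each bin — events per Myr of lineage — plus alignment of
  per-tree curves from a posterior sample on a common age axis
  (`normalized_transition_series`, `aggregate_over_posterior`).
* **An explicit audit rule** for counting post-boundary origins of
  arboreality from modal node states, returning the supporting edge list
  (`count_post_boundary_arboreal_origins`).
* **A synthetic study system** (`make_study_fixture`): a
  radiation-structured 164-tip, 90-Myr chronogram (stem lineages crossing
  the boundary, crown radiations just after it), a character history
  simulated under the ordered four-rate model with a post-66.02 Ma S→N
  rate increase, and a pseudo-posterior of age-jittered, NNI-perturbed
  trees — with the complete true history retained, so every stage is
  testable end to end without external downloads.

The model core: a CTMC with generator Q over the (expanded) state space,
P(t) = exp(Qt), tip data conditioned by pruning, root collapsed with equal
or FitzJohn (conditionals-proportional) weights, AIC = 2k − 2 log L.

## Worked example

```r
library(arbormk)

# a self-contained synthetic study bundle (deterministic in the seed)
fx <- make_study_fixture(seed = 1, n_posterior = 25)
table(fx$characters$state)
#>      arboreal   nonarboreal semi-arboreal
#>            23           118            23

# fit the ordered four-rate model and map character histories
spec <- build_model_spec("four_rate")
fit  <- fit_ml(fx$tree, fx$characters, spec, "fitzjohn",
               optimizer_config(restarts = 3, seed = 1))
fit
#> Mk fit 'four_rate': logL = -108.20959, k = 4, AIC = 224.41918
#> rates (1/Myr): 0.005770 0.021839 0.032934 0.009625

maps <- generate_maps(fx$tree, fx$characters, n_maps = 1000,
                      q_source = "fixed", Q = fit$Q,
                      root_prior = "fitzjohn", seed = 2)
sm <- summarize_maps(maps)
round(sm$mean_counts, 3)   # mean number of events per map, by type
#>               arboreal semi-arboreal nonarboreal
#> arboreal         0.000         3.132       0.000
#> semi-arboreal   18.162         0.000      27.941
#> nonarboreal      0.000        47.982       0.000

# post-K-Pg origins of arboreality under the audit rule
count_post_boundary_arboreal_origins(sm$node_probs, fx$tree)$count
#> [1] 13

# transition rates through time: where does the S->N intensity peak?
ser <- normalized_transition_series(maps, fx$tree, B = 50)
sn  <- ser[ser$type == "semi-arboreal->nonarboreal", ]
sn$older[which.max(sn$value)]
#> [1] 3.6
```

Read: the fitted S→N rate (0.033/Myr) is the largest of the four, as
expected from a generator whose S→N rate jumps after the boundary; maps
average ~28 S→N events against ~18 S→A gains; thirteen independent
post-boundary origins of arboreality are recovered; and the S→N intensity
attains its maximum after the boundary (the bin whose older edge is
3.6 Ma). The `analysis/` scripts run the same stages at
study scale (`01_simulate_study_data.R` … `04_transitions_through_time.R`),
writing tables under `results/`.

## Notes

The real mammalian inputs (the Meredith et al. 2011 and Upham et al.
2019 consensus chronograms, the VertLife posterior tree sample, and the
species-level character scores) are not redistributed here. All functions
accept user-supplied Newick/NEXUS trees and CSV/TSV character tables; see
`vignettes/arboreality-inference.Rmd` for the methods account, parameter
choices and known limitations.
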