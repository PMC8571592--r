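---
title: "Inferring the evolution of mammalian substrate preference across the K-Pg boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the evolution of mammalian substrate preference across the K-Pg boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, the algorithms, the tunable parameters, the design choices that
were genuinely open, and what the synthetic-data tests do and do not
demonstrate.

## The problem

Mammals can be scored by where they nest or reside: **arboreal** (A,
virtually always in living trees), **semi-arboreal** (S, often but not
exclusively), or **nonarboreal** (N). Given a time-calibrated phylogeny of
family-level mammalian lineages and one such score per tip, the package
infers how this three-state character evolved, with particular attention to
the Cretaceous-Paleogene (K-Pg) mass extinction at ca. 66.02 Ma: did
surviving lineages tend to be non-arboreal, and did arboreality re-originate
repeatedly afterwards?

The pipeline has four stages, each exposed as package functions and driven
by the numbered scripts under `analysis/`:

1. **Model selection** (`model_selection_table`): structured Mk models
   compared by AIC.
2. **Ancestral reconstruction** (`marginal_asr`, `parsimony_asr`): marginal
   likelihood probabilities and Sankoff most-parsimonious state sets per
   node.
3. **Stochastic character mapping** (`generate_maps`, `summarize_maps`):
   posterior draws of complete character histories, optionally across a
   posterior sample of trees, summarized onto a reference tree by clade
   matching.
4. **Transition rates through time** (`normalized_transition_series`):
   per-transition-type event frequencies in equal-width time bins,
   normalized by the branch length in each bin.

## The model family

All models are continuous-time Markov (Mk) models on the state space
\{A, S, N\}, or on its expansion by hidden rate classes. Rates are in
events per Myr; branch lengths must be in Myr. The six members
(`build_model_spec`) are:

| name | k | structure |
|---|---|---|
| `two_rate` | 2 | transitions touching S share one rate; direct A&harr;N share another |
| `four_rate` | 4 | ordered A&harr;S&harr;N with separate forward/reverse rates; direct A&harr;N forbidden (structural zeros) |
| `ard` | 6 | all rates different |
| `hmm_ard_plus_four_rate_2class` | 11 | one ARD class + one four-rate class |
| `hmm_ard_2class` | 13 | two ARD classes |
| `hmm_ard_3class` | 19 | three ARD classes |

The ordered four-rate model encodes the biological claim that moving
between obligate arboreality and nonarboreality requires passing through
the semi-arboreal intermediate.

Hidden-rate-class models expand the space to (state, class) pairs, blocked
as (A1, S1, N1, A2, ...). Class switching is a **single shared symmetric
rate** connecting the same observed state across classes; the observed
state and the class never change in the same instant. The symmetry is the
modeling assumption; the single-rate choice is this package's (the
smallest parameterization consistent with that symmetry). Because other
implementations may count per-pair switch rates, the parameter count `k`
is carried in every `ModelSpec` and printed in every output, so AIC values
can be reconciled: a different switch-rate convention shifts AIC by a
constant `2 * (k' - k)` at equal likelihood.

Likelihoods are computed by Felsenstein pruning over the expanded space
(`pruning_loglik`), with per-node rescaling for numerical stability. A tip
observed in state X is ambiguous over the hidden classes of X. Transition
probabilities `expm(Q t)` use an eigendecomposition reused across all
edges of a tree, with a scaling-and-squaring Taylor fallback whenever the
eigenvector matrix is ill-conditioned (condition number above 1e10) or a
negative probability beyond -1e-8 appears; entries are then clamped at 0
and rows renormalized (relative error at machine precision).

### Root priors

Two root treatments are provided everywhere: **equal** weights over the
(expanded) states, and **FitzJohn** weights proportional to the root
conditional likelihoods. Model selection defaults to equal weights and the
analysis driver reports both. The mapping and reconstruction stages default
to FitzJohn, for a concrete reason discovered while validating the
pipeline on synthetic data: under equal weighting, stochastic maps draw a
root state that the data all but rule out in a few percent of samples; the
forced correction is then squeezed onto the short root-adjacent edges, and
after branch-length normalization this fabricates an order-of-magnitude
spike in the oldest bins of the rate-through-time curves. FitzJohn
weighting, which is exactly "let the data weight the root", suppresses
this artifact. Both code paths remain selectable in every function.

### Fitting

`fit_ml` maximizes the likelihood over log-rates with `nlminb`, bounds
[1e-8, 1e2] per Myr, and multiple restarts (one deterministic start at
1/tree-height plus log-uniform random starts; 10 by default, fewer in the
scripted analyses where noted). The fit is flagged unconverged when fewer
than two restarts agree within 0.01 log-units - a deliberately strict flag,
since hidden-class likelihood surfaces are multimodal. AIC = 2k - 2 logL;
a small-sample AICc is available (`aicc_score`) but not used by default.

## Ancestral reconstruction

`marginal_asr` computes exact marginal node probabilities by the standard
inside-outside decomposition (downward pruning conditionals combined with
an upward pass), marginalizing hidden classes into the three observed
states (`per_class = TRUE` exposes the expanded marginals).

`parsimony_asr` is a two-pass Sankoff dynamic program returning, for every
node, the exact set of states attained by at least one globally
most-parsimonious assignment; ties are kept as sets and never broken. The
default cost is unordered (any change costs 1). Because the preferred
likelihood model is ordered, an ordered cost matrix (A-S-N linear, direct
A&harr;N costing 2) is provided as an option, since neither cost scheme is forced by the
data; both are reported when requested.

## Stochastic character mapping

A map is drawn in two exact steps:

1. **Joint node states**: the root from the prior-weighted root
   conditionals, then each child from its conditional given the sampled
   parent (`sample_joint_node_states`).
2. **Branch histories**: an endpoint-conditioned CTMC bridge on every edge
   by **uniformization** (`sample_branch_history`): the number of candidate
   jumps at the dominating rate mu = max exit rate is drawn from
   P(N = n) proportional to Pois(mu t)(n) R^n[a,b] with R = I + Q/mu; the
   candidate chain is bridged with cached powers of R; virtual jumps
   (self-transitions of R) are thinned. This is exact for any generator,
   including the structural zeros of the ordered model; a forward-rejection
   fallback was considered and rejected since uniformization is exact and
   never degenerates on long branches or unlikely endpoint pairs.

Per-(tree, map) seeds are drawn upfront from the master seed, so a run is
reproducible regardless of how work is scheduled. `summarize_maps`
projects maps onto a reference tree: for each reference internal node, the
frequency of each observed state across all (map, matched node) pairs,
where matching is by identical descendant leaf sets ("phylogenetically
equivalent" nodes). Nodes absent from a posterior tree are excluded from
that tree's average rather than imputed, and the clade frequency is always
reported alongside so consumers can filter; exclusion-plus-reporting is
the missing-clade rule that loses no information. Per-tree MLE Q matrices are averaged
element-wise (arithmetic mean; geometric mean behind a flag).

## Transition rates through time

For B equal-width bins spanning [root age, 0] (B = 50 by default, a
resolution fine enough to separate the boundary from its neighborhood on
a 90-Myr tree), the statistic for each ordered
transition type is

> mean over maps of the number of events of that type whose age falls in
> the bin, divided by the total branch length within the bin.

Events are timestamped at segment boundaries; bins are older-inclusive
(an event exactly on an interior bin edge belongs to the older bin), a
convention applied consistently throughout. Bins with zero branch length are reported as
undefined (NA), never as 0. Hidden-class switches are excluded from the
six observed-type series. The per-bin identity "sum over bins of value x
bin branch length = mean per-map event count" is enforced to 1e-9 by the
test suite.

Per-tree series are computed on each tree's own grid (the statistic is
defined relative to the tree that generated the maps); alignment across a
posterior sample happens only at aggregation, on an absolute-age axis
anchored at the present and spanning the oldest root, by
piecewise-constant lookup at common-bin midpoints. Per-tree curves are
retained; a pointwise median is attached but never substituted for them.

## Counting post-boundary origins of arboreality

Counting "independent origins of arboreality" from per-node state
summaries has no canonical formula. The package makes its rule explicit
and auditable
(`count_post_boundary_arboreal_origins`): an origin is an edge whose child
is modally arboreal (mode above a 0.5 threshold by default), whose parent
is determinately modal in a non-arboreal state, and whose child is younger
than the boundary (66.02 Ma by default; both configurable). Origins nested
inside an already-counted arboreal subtree are skipped. Indeterminate
nodes (ties or sub-threshold modes) are never origins and never serve as
the non-arboreal parent of one. The full audit edge list is returned so
real-data counts can be reconciled edge by edge.

## The synthetic study system

Because the real inputs (the Meredith et al. 2011 and Upham et al. 2019
consensus chronograms, the VertLife posterior tree sample, and the
species-level character table) are not redistributable here, the package carries a generator
(`make_study_fixture`) whose defaults *are* the study conditions used by
the tests and the acceptance script. Design, fixed after calibration and
not revisited:

* **Tree** (`simulate_kpg_radiation_tree`): 164 tips, root age 90 Ma,
  built as ~30 stem lineages diverging before the boundary, each crossing
  it and radiating with crown ages drawn in 58-64 Ma. This reproduces the
  defining feature of the mammalian timetree - a dense pulse of short
  internal edges just after the K-Pg - which is what localizes forced
  character transitions in time. A plain conditioned birth-death tree
  (`simulate_birth_death_tree`, via `phytools::pbtree` with retries and
  root-age rescaling) is used for generic simulations and is also
  available to the fixture's consumers.
* **Character truth** (`simulate_character_history`, exact Gillespie with
  epoch switching): ordered four-rate generator, nonarboreal root, three
  ecological epochs - N->S essentially closed before 82 Ma (0.002/Myr),
  an inflow epoch 82-66.02 Ma (N->S = 0.02/Myr, emulating the Late
  Cretaceous rise of tree-dwelling opportunities), and the post-boundary
  crash (S->N jumps 0.003 -> 0.03/Myr, N->S easing to 0.008/Myr). Base
  rates A->S = 0.004, S->A = 0.01/Myr throughout. These values were chosen
  once so that tip compositions are realistically mixed (every state above
  ~10% of tips), states are phylogenetically conserved (as in the real
  data), deep lineages persist nonarboreal, and the truth contains a
  post-boundary S->N pulse plus repeated independent origins of
  arboreality.
* **Pseudo-posterior** (`perturb_tree_set`): node ages jittered
  multiplicatively on the parent-fraction scale (preserving
  ultrametricity and the root age) plus rooted NNI moves; defaults 0.05
  log-SD and 2 moves, giving clade frequencies realistically below 1.

The epoch schedule lives only in the generator; all inference models are
time-homogeneous. This deliberately mirrors the model misspecification of
the real analysis, so recovery checks are qualitative where the
misspecification bites. What passing tests show: the likelihood machinery
is exact (enumeration oracles), the samplers are distributionally correct
(closed forms, uniformization truncation), parameters of a
correctly-specified model are recovered at scale, and the qualitative
K-Pg signature is recovered under the study conditions. What they do not
show: behavior under real-data features the generator omits - divergence
time error, taxon-sampling bias toward single-species families,
state-dependent diversification, or character scoring error.

A known limitation, documented rather than patched: with a 90-Myr root
and only two or three lineages in the oldest bins, the branch-length
normalization amplifies any residual deep-time reconstruction mass by an
order of magnitude, so in a substantial minority of generator draws the
S->N series maximum lands in a sparse pre-boundary bin rather than after
the boundary. The FitzJohn root prior removes the largest contributor
(root-draw correction); the remainder is intrinsic to maximum-seeking over
a ratio statistic on sparse bins.

## Problem sizes and numerical settings used by the shipped runs

The test suite and `scripts/acceptance.R` scale the study-scale run
sizes down to keep full runs in minutes: 1,000-5,000 consensus maps become
150-5,000 depending on the check; 500 maps x 1,000 posterior trees become
20-50 maps x 25-40 trees; optimizer restarts are 2-3 in scripted runs
(10 by default in `optimizer_config`). Oracle comparisons use trees of at
most 6 tips where enumeration over internal-state assignments is exact.
Tolerances: likelihood vs enumeration 1e-8; closed-form transition
probabilities 1e-10; rate-matrix row sums 1e-12; RTT conservation 1e-9;
Monte-Carlo map-vs-marginal agreement 0.03 at 5,000 maps.

## Degenerate inputs and tie-breaking

Zero-length edges are tolerated by the likelihood (P(0) = identity) but
make endpoint-conditioned sampling trivially deterministic; polytomies are
treated as hard. Non-ultrametric trees are accepted for likelihood work
and rejected (with an override flag) by age-dependent operations.
All-identical tip data drive rates to the lower bound, and the
log-likelihood to log(1/3). Parsimony ties are carried as sets; modal
ties in origin counting are treated as indeterminate rather than broken.
An all-zero root conditional (impossible data under structural zeros)
raises an error naming the offending clade rather than returning -Inf.
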