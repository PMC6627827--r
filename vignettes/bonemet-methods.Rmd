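---
title: "Gene dependency networks, driver genes and bone-metastasis risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene dependency networks, driver genes and bone-metastasis risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemet)
```

bonemet predicts 5-year bone-metastasis risk of breast-cancer patients from
expression profiles by (i) inferring a *gene dependency network* — which
gene's association with risk is modulated by which other gene — via
conditional mutual information, (ii) mining the network's *minimal driver
gene sets* under structural controllability, (iii) refining the always-driver
genes to a differential signature, and (iv) classifying patients with a
nearest-centroid model evaluated by survival analysis, AUC and MCC. This
vignette documents the model, its tunable parameters, the synthetic-cohort
generator, and the numerical and design choices the implementation makes.

## The risk model and preprocessing

Follow-up is reduced to a binary phenotype with the conventional 5-year
rule (`label_risk()`): an observed bone metastasis within `threshold_years`
(default 5; `time_unit` converts months to years when needed) makes a
patient high-risk; surviving metastasis-free past the threshold makes them
low-risk — including patients whose first event falls *after* the
threshold; a record censored at or before the threshold is uninformative
and is labelled `excluded` rather than dropped, so downstream stages can
decide what to do with it (the network, t-test and classifier stages use
only labelled patients; Kaplan–Meier evaluation uses everyone).

Expression is binarized per gene at its median (`binarize_expression()`),
with values equal to the median mapping to 0. Medians are computed once over
all retained (non-excluded) patients of the analysis cohort, not per split:
binarization is a preprocessing step of the network stage, and computing it
per split would make the network's input representation depend on the
split. A constant gene becomes an all-zero row, which is harmless: its
mutual information with anything is 0.

## The gene dependency network

For genes A (dependent) and B (modulator) the score is

$$\mathrm{CMI}(A;\mathrm{risk}\mid B) \;=\; I_{\mathrm{high}}(A;\mathrm{risk}) \;-\; I_{\mathrm{low}}(A;\mathrm{risk}),$$

where $I_{\mathrm{high}}$ is the plug-in mutual information (in bits, with
$0\log 0 = 0$) between A's binarized expression and the risk label over the
`fraction` (default 0.35) of patients with the *highest* continuous
expression of B, and $I_{\mathrm{low}}$ the same over the lowest fraction.
The score is asymmetric in (A, B) and may be negative; either sign
indicates that B's level modulates the A–risk association.

Design choices, each of which was genuinely open:

* **Continuous stratification.** Patients are stratified by B's continuous
  expression, not its binarized value: a 0/1 vector has no meaningful 35%
  tails, while continuous sorting preserves the intended extremes.
* **Ties.** Ties in B are broken by a seeded random shuffle applied before
  a stable sort — deterministic given the seed, unbiased across ties.
* **Two-sided test with pseudocount.** B's expression vector is permuted
  uniformly at random `n_perm` times (default 1000) and
  $p = (1 + \#\{|\mathrm{CMI}_{\mathrm{perm}}| \ge |\mathrm{CMI}_{\mathrm{obs}}|\})/(n_{\mathrm{perm}}+1)$.
  The pseudocount avoids $p = 0$; two-sidedness reflects that the score's
  sign is not part of the hypothesis.
* **Permutation short-cut.** Under a uniform permutation of B (ties
  randomized), the two strata are exactly a uniformly random pair of
  disjoint $k$-subsets of patients, $k=\lfloor f n\rfloor$; the null is
  therefore drawn by sampling $2k$ indices directly instead of re-sorting a
  permuted vector. This is an algebraic identity, not an approximation, and
  makes the edge test about an order of magnitude faster.
* **Per-pair RNG streams.** Each candidate pair derives its own seed from
  the master seed and the pair's index in the (deterministically ordered)
  candidate list, so results do not depend on evaluation order.
* **No multiplicity correction by default.** Edges are kept at raw
  `p < alpha` (default 0.05), matching the method's design; `adjust = "BH"`
  is available for users who want FDR control across pairs.

Candidate pairs are restricted to PPI scaffold edges
(`candidate_pairs()`): each undirected edge with both genes measured is
tested in both orientations; self-loops and duplicates are removed.
`network_stats()` reports mean in/out-degree and the conventional
scale-free diagnostic: $R^2$ and Pearson correlation of a least-squares
line on $\log_{10}(\text{degree})$ vs $\log_{10}(\text{frequency})$,
excluding empty bins and degree 0, undefined (`NA`) with fewer than three
distinct degrees.

## Structural controllability and driver sampling

A directed network is structurally controllable through the nodes left
unmatched on their in-side by a maximum matching of the bipartite split
(node $v$ → copies $v^+, v^-$; arc $u \to v$ → edge $(u^+, v^-)$). The
minimal driver set has size $\max(N - |M|, 1)$: when the matching is
perfect one input is still required, and the implementation assigns it to
the first node of the sampled order. Isolated nodes are their own drivers.

The matching engine (compiled; Kuhn's augmenting-path algorithm) takes the
node visitation order — and the order in which each node's neighbours are
tried — from a caller-supplied permutation. Any maximum matching has the
same *size*, but different permutations realize different matched sets;
`sample_driver_sets()` exploits exactly this to sample minimal driver sets
(default `runs = 500`), asserting the size invariant on every run.
`select_candidates()` keeps genes whose driver frequency equals `runs`.

A structural remark that matters for interpretation: if a node has any
in-edge, *some* maximum matching covers its in-copy (augmenting along that
edge), so with enough runs the always-driver candidates concentrate on
nodes with zero in-degree — upstream modulators and isolated sources. The
candidate set is thus a "most upstream" filter of the network, which is
what makes it informative for feature selection.

## Signature and classifier

`select_signature()` compares each candidate's *continuous* expression
between high- and low-risk training patients. The method's threshold is
p < 0.002; the test is Welch's by default (`var_equal = TRUE` gives
Student's) since the method family specifies only "t-test" and unequal
variances are the safer assumption for expression data. A gene with zero
variance in both classes gets $p = 1$ by convention. No FDR control, by
design.

`fit_centroid()` computes the class-mean centroids $c^+, c^-$ over the
signature genes and `predict()` scores
$\gamma = \langle s - \tfrac{1}{2}(c^+ + c^-),\; c^+ - c^-\rangle$,
predicting high risk iff $\gamma > 0$ ($\gamma = 0$ maps to the negative
class). The identity
$\gamma = \tfrac{1}{2}(\lVert s - c^-\rVert^2 - \lVert s - c^+\rVert^2)$
makes this exactly the nearest-centroid rule; it is asserted to $10^{-9}$
in the tests. Expression is not standardized by default (the score
contains no scaling); `standardize = TRUE` applies a z-score with
training-set statistics.

## Evaluation

`km_logrank()` wraps the survival package's product-limit estimator and
two-group log-rank test, returning tidy curves, observed/expected event
counts, $\chi^2_1$ and p. With zero events in both groups the statistic is
undefined and the convention $\chi^2 = 0, p = 1$ is reported. Survival
evaluation includes *all* patients of a split — also those excluded from
5-year labelling — grouped by predicted label, since metastasis-free time
is defined for everyone; AUC (rank-based with midrank ties, computed from
the continuous $\gamma$), accuracy and MCC use the labelled subset. MCC
returns 0 when any margin of the confusion matrix is empty.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study design end to end: a sparse
scale-free PPI scaffold (preferential attachment with `m = 2`, so a
140-gene scaffold has 276 edges; an Erdős–Rényi option exists), continuous
expression from a symmetric two-component Gaussian mixture (components
±1, sd 0.6) so median splits are non-degenerate, a latent 5-year risk
label, survival times consistent with that label, and train/test/
independent splits whose default fractions reproduce an 855-patient cohort
split 380/189/286.

Planted structure lives on `n_planted_pairs` *vertex-disjoint* scaffold
edges, each oriented at random, in two layers:

1. **Marginal layer.** The risk label is logistic in modulator activity:
   $\operatorname{logit} P(\mathrm{high}) = \operatorname{logit}(b + e/2) + 1.5\,e \sum_i (\mathbb{1}[B_i\ \mathrm{active}] - \tfrac12)$,
   with $b$ = `baseline_risk`, $e$ = `effect_size`, and "active" meaning
   above (or below, per `active_stratum`) the modulator's median. Real
   driver genes are both upstream and differentially expressed; this layer
   provides the differential expression, and its coefficient must stay
   below $e/2$ in contrast terms for layer 2 to be feasible.
2. **Conditional layer.** Inside each modulator's active stratum the
   dependent gene's mixture component is redrawn given the risk label by
   exact Bayes inversion so that
   $P(\mathrm{high}\mid A\ \mathrm{above}) - P(\mathrm{high}\mid A\ \mathrm{below}) = e$
   exactly. The contrast is centred on the *inactive* stratum's realized
   risk rate (clamped into the feasible band): centring there makes the
   reverse orientation $A \to B$ see symmetric contrasts $\pm e/2$ in the
   two strata of $A$, keeping the planted dependency directionally
   asymmetric. The inactive stratum is redrawn (independently of risk) to
   rebalance the gene's overall component frequency to $\tfrac12$, so its
   median split keeps tracking the mixture component. With $e = 0$ the
   cohort is exactly null.

Two properties of this construction are worth stating explicitly. First,
because each pair touches only its own dependent gene and pairs are
vertex-disjoint, pairs do not interfere: every pair carries its full
conditional contrast regardless of `n_planted_pairs`. Second, a per-pair
contract of the form "risk = baseline + effect within the active stratum"
cannot hold *jointly* for many overlapping pairs on the probability scale
(any risk function of the trigger count bounds the achievable contrast by
the total-variation distance between a binomial and its unit shift, far
below 0.5 at 20 pairs); the two-layer design is the package's resolution —
the planted *contrast* is exact, while stratum base rates float with the
cohort's heterogeneity.

Survival times are drawn conditional on the latent label so the emitted
time/event columns reproduce it exactly under the 5-year rule: high-risk
patients receive an observed event from a truncated exponential on
(0, 5] years (mean `followup_scale / 3`); low-risk patients survive past 5
years and are then censored with probability `censor_rate` or followed to
a late event at 5 + Exp(`followup_scale`). Consequently the generator
itself never produces `excluded` patients; the exclusion path is exercised
in tests with hand-built clinical tables.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: microarray noise and batch structure, correlated
co-expression modules, probe-level artefacts, informative censoring, and
dependency structure denser than disjoint pairs. It is a calibration and
power instrument, not a cohort simulator.

## Pipeline orchestration and problem sizes

`run_pipeline()` chains the stages with a master seed from which each
stochastic stage derives its own stream, and optionally writes per-stage
TSV/JSON artifacts plus a manifest (seed, parameters, per-stage counts)
sufficient to reproduce the run. The network, driver sampling, signature
and centroid fit all use the training split only, with held-out splits
reserved for evaluation; this is deliberately stricter than fitting the
network on the full cohort, which leaks test-set association structure
into feature selection. Any stage failure aborts with the stage's name.

Defaults follow the method's published parameterization: `fraction = 0.35`,
`alpha = 0.05`, `n_perm = 1000`, `runs = 500`, `t_threshold = 0.002`,
5-year horizon, split fractions 380/189/286 of 855.

The test suite and the acceptance script run scaled-down designs chosen as
the package's demonstration sizes: calibration on a null cohort of 400
patients and 500 candidate pairs at `n_perm = 200`; power on 800 patients
and 20 planted pairs of effect 0.5 at `n_perm = 500` (5 seeds); the
end-to-end experiment on 1000 patients, 140 genes and 24 planted pairs of
effect 0.6 at `n_perm = 200`, `runs = 100` (10 seeds). The matching engine
is verified against an independent subset-DP enumeration oracle on every
simple digraph with up to 5 nodes under 50 sampled node orders each, and on
random 8-node digraphs.

## Known limitations

* The CMI edge test conditions on one modulator at a time; higher-order
  modulation (two genes jointly gating a third) is invisible to it.
* Always-driver candidates concentrate on zero-in-degree nodes, so genes
  that are both strongly regulated *and* prognostic are structurally
  unlikely to enter the signature; this is a property of the method, and
  the simulator mirrors it by putting marginal signal on modulators.
* Permutation p-values are discrete with resolution 1/(`n_perm`+1);
  calibration statements at small `n_perm` should use tolerances coarser
  than that grid.
* The driver-frequency criterion (`count == runs`) is a finite-sample
  proxy for "in every maximum matching": with few runs it can retain genes
  whose covering matchings were merely never sampled.
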