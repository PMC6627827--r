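# bonemet

Predicting bone metastasis of breast cancer from a **gene dependency
network**: bonemet implements, as a tested R pipeline, a feature-selection
and classification method in which the association between a gene and
metastasis risk is allowed to depend on the expression level of another
gene, and in which prognostic signatures are drawn from the *driver genes*
that structurally control the resulting directed network.

The package is aimed at computational biologists who want to apply (or
probe) this class of network-controllability biomarker methods on their own
expression + follow-up cohorts, or to study its statistical behaviour on
simulated data: a first-class synthetic-cohort generator with planted
conditional dependencies makes every stage testable without any external
download.

## The method

Given a genes × patients expression matrix, per-patient bone-metastasis
follow-up, and a protein–protein interaction (PPI) scaffold:

1. **Risk labels.** Patients with an observed bone metastasis within 5
   years are high-risk (1); patients metastasis-free beyond 5 years are
   low-risk (0); patients censored earlier are explicitly `excluded`.
   Expression is binarized per gene at its median (values ≤ median → 0).

2. **Gene dependency network.** For each ordered pair (B modulates A)
   whose genes interact in the PPI scaffold, the conditional mutual
   information

   CMI(A; risk | B) = I_high(A; risk) − I_low(A; risk)

   contrasts the mutual information of A's binarized expression with the
   risk label between the 35% of patients with the highest and the 35%
   with the lowest continuous expression of B. Significance is assessed by
   permuting B's expression (default 1000 permutations, pseudocount
   p-value); pairs with p < 0.05 become directed edges B → A.

3. **Minimal driver sets.** A directed network is structurally
   controllable through the driver nodes left unmatched by a maximum
   matching of its bipartite split (node v → out-copy v⁺ and in-copy v⁻;
   arc u→v → edge (u⁺, v⁻)); the minimal driver set has size
   max(N − |matching|, 1). Because maximum matchings are not unique, the
   matching is repeated under (default) 500 random node orderings and genes
   present in **every** sampled driver set become feature candidates.

4. **Signature and classifier.** Candidates differentially expressed
   between high- and low-risk training patients (Welch t-test, p < 0.002)
   form the signature. A nearest-centroid classifier is fitted on it:
   with class centroids c⁺ and c⁻, a patient vector s is scored by
   γ = ⟨s − (c⁺+c⁻)/2, c⁺−c⁻⟩ and predicted high-risk when γ > 0
   (algebraically the nearest-centroid rule, since
   γ = (‖s−c⁻‖² − ‖s−c⁺‖²)/2).

5. **Evaluation.** Predicted risk groups are compared by Kaplan–Meier
   curves with the log-rank test on metastasis-free survival, and by AUC
   (rank-based, from γ), accuracy and the Matthews correlation coefficient.

## Worked example

Everything runs on a simulated cohort — 1000 patients, 140 genes, 24
planted modulator→dependent dependencies of effect size 0.6 on a
scale-free PPI scaffold:

```r
library(bonemet)

cfg <- synth_config(n_genes = 140, n_patients = 1000,
                    n_planted_pairs = 24, effect_size = 0.6, seed = 42)
cohort <- simulate_cohort(cfg)

run <- run_pipeline(cohort$expression, cohort$clinical, cohort$scaffold,
                    n_perm = 200, runs = 100, seed = 42)
run
#> bonemet pipeline run (seed 42)
#>   network: 60 edges / 73 nodes from 552 candidate pairs
#>   drivers: matching size 43; 24 all-run driver candidates; signature of 6 genes
#>   train: AUC = 0.748, MCC = 0.339, log-rank p = 1.42e-06
#>   test: AUC = 0.67, MCC = 0.211, log-rank p = 0.0021
#>   independent: AUC = 0.721, MCC = 0.344, log-rank p = 1.37e-08
```

Reading the output: of 552 PPI-restricted candidate ordered pairs, 60
passed the permutation test (20 of the 24 planted orientations among
them); the bipartite maximum matching of the 73-node network
has size 43, so every sampled minimal driver set contains 30 genes, 24
genes appear in *all* 100 sampled driver sets, and 6 of those survive the
t-test to form the signature. On the two held-out splits the centroid
classifier reaches AUC 0.67 / 0.72 and separates the Kaplan–Meier curves at
log-rank p = 2.1e-3 / 1.4e-8.

The fitted pieces are ordinary tidy objects:

```r
tidy(run$network)                  # edge tibble: modulator, dependent, cmi, p
glance(run$network)                # nodes, edges, degree means, power-law fit
tibble::as_tibble(run$signature)   # gene, p_value
#> # A tibble: 6 x 2
#>   gene        p_value
#> 1 G0005 0.00000000243
#> 2 G0072 0.000218
#> 3 G0022 0.000297
#> ...
autoplot(run$evaluation$test$survival)   # KM curves of the predicted groups
```

Individual stages (`label_risk()`, `binarize_expression()`,
`candidate_pairs()`, `build_network()`, `sample_driver_sets()`,
`select_candidates()`, `select_signature()`, `fit_centroid()`,
`predict()`, `km_logrank()`, `auc_score()`, `mcc_score()`) are exported and
composable; `write_run_artifacts()` / `write_cohort_tsv()` emit every table
as plain TSV/JSON plus a reproducibility manifest.

See `vignettes/bonemet-methods.Rmd` for the statistical details, the
simulator's design and the package's numerical conventions.

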