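# morphkls

Single-subject grey-matter morphological brain networks from
Kullback–Leibler similarity, with graph-theoretic characterization,
permutation-based group inference, and SVM classification.

## What problem this solves

Conventional structural-covariance brain networks are built per *group*
(one correlation matrix across subjects), so individual subjects have
no network of their own and network properties cannot be correlated
with individual clinical scores or used for single-subject diagnosis.
The KLS approach builds one network per subject: for each of the 90
AAL regions, the distribution of grey-matter voxel values is estimated
by kernel density estimation, and every pair of regions is connected
by the similarity of their distributions,

    KLS(P, Q) = exp( −Σᵢ [ P(i) log(P(i)/Q(i)) + Q(i) log(Q(i)/P(i)) ] ) ∈ [0, 1],

the exponentiated symmetric Kullback–Leibler divergence on an
n = 2⁷-point discretization. Every subject gets a 90 × 90 weighted,
undirected, identically scaled network — comparable across subjects.

The package implements the full downstream analysis used in
early-stage Parkinson's disease studies of such networks:

* **Graph metrics over a sparsity range** (default 0.10–0.34, step
  0.01): Cp, Lp, Eglob, Eloc, and γ, λ, σ against 100
  degree-preserving rewired null networks; nodal betweenness, degree,
  efficiency; AUC summaries; hub scores (top 10% of nodes per metric).
* **Group inference**: permutation tests (default 5000) with Cohen's
  d on the 7 global and 3 × 90 nodal AUCs, Benjamini–Hochberg FDR per
  nodal metric, partial correlations with clinical scores (UPDRS-III,
  Hoehn–Yahr, MMSE) adjusting for age, gender, education, and a
  network-based statistic (NBS) localizing altered connections with
  family-wise-corrected component p-values.
* **Classification**: linear SVM on network matrices (4005 edges) or
  graph-metric AUC vectors, five-fold stratified nested
  cross-validation with an inner grid search over C = 10⁻³…10⁴,
  permutation significance, and weight-based region rankings.
* **Synthetic cohorts**: a generator with community-structured
  regional distributions, planted group effects (module coherence,
  dispersion, or shift) scaled by a latent severity that also drives
  UPDRS-III — so the whole pipeline is testable end to end without
  imaging data. NIfTI export/import round-trips exactly.

See `vignettes/morphological-network-methods.Rmd` for the model,
conventions and design decisions.

## Worked example

```r
library(morphkls)
set.seed(7)
d  <- simulation_design(n_per_group = 10, voxels_per_region = 150,
                        effect_regions = 46:60, effect_magnitude = 2)
co <- simulate_cohort(d)

net <- build_network(co$subjects[[1]])
net
#> KLS morphological network: sub-001
#>   90 nodes, 4005 weighted edges; weights in [0.000, 0.990], median 0.159

au  <- cohort_aucs(cohort_networks(co), n_null = 20, seed = 1)
pat <- co$meta$group == "patient"
sub <- function(a, i) list(global = a$global[i, , drop = FALSE],
                           nodal  = a$nodal[i, , , drop = FALSE])
compare_groups(sub(au, pat), sub(au, !pat), n_perm = 999, seed = 2)
#> Group comparison (999 permutations per test)
#> Global AUC metrics:
#>  metric    diff     p      d
#>      Cp  0.0073 0.001  2.379
#>      Lp  0.0077 0.345  0.450
#>   Eglob  0.0009 0.063  0.939
#>    Eloc  0.0052 0.001  2.253
#>   gamma -0.0079 0.536 -0.285
#>  lambda  0.0131 0.008  1.324
#>   sigma -0.0153 0.038 -0.973
#> Nodal tests: 42 of 270 significant after FDR (q <= 0.05)
```

The cohort plants strengthened within-module similarity in one
15-region community (occipito-parietal, regions 46–60) in the patient
group. The comparison recovers exactly the expected signature: higher
clustering (Cp) and local efficiency (Eloc) in patients — higher
network segregation — while global efficiency is preserved, and the
FDR-significant nodal list is dominated by the planted regions
(Cuneus, Lingual, Occipital, Fusiform, Postcentral, Parietal_Sup).

`run_pipeline(run_config(...))` chains simulate (or NIfTI ingest) →
network construction → metrics → group comparison / NBS / clinical
correlation → classification, writing every table as TSV beside a
persisted JSON config; one global seed makes reruns bit-identical. A
thin CLI wrapper lives at `inst/cli/morphkls`.

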