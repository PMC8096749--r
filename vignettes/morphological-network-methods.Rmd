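---
title: "Single-subject grey-matter morphological networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject grey-matter morphological networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A subject's grey-matter morphology is summarized as a weighted,
undirected network on the 90 cerebral regions of the AAL parcellation.
The nodes are regions; the edge between regions $j$ and $k$ encodes how
similar the two regions' *distributions* of grey-matter voxel values
are. For each region the probability density of its voxel values is
estimated by Gaussian kernel density estimation and discretized on a
grid of $n = 2^7$ sample points into a probability mass vector. For two
such discrete distributions $P$ and $Q$ the directed Kullback–Leibler
divergence is

$$D_{KL}(P\|Q) = \sum_{i=1}^{n} P(i)\,\log\frac{P(i)}{Q(i)},$$

which is asymmetric; the symmetric variant adds the two directions,

$$D_{KL}(P,Q) = \sum_{i=1}^{n}\Big(P(i)\log\frac{P(i)}{Q(i)} +
Q(i)\log\frac{Q(i)}{P(i)}\Big),$$

and is mapped to a bounded similarity

$$\mathrm{KLS}(P,Q) = e^{-D_{KL}(P,Q)} \in [0,1],$$

equal to 1 exactly when the distributions coincide. Filling all
$\binom{90}{2} = 4005$ pairs yields the subject's symmetric KLS matrix
(diagonal fixed at 0 by convention). Because every subject's network has
the same node set and the same weight scale, networks are comparable
across subjects — the property that makes single-subject inference and
classification possible.

### Numerical choices in the construction

* **Logarithm base.** Natural log throughout. The KLS stays in $(0,1]$
  for any base; the natural log also makes the sparsity-selection
  degree rule $2\log(90) \approx 9.0$ consistent with a lower sparsity
  bound near 0.10 (see below).
* **Grid.** One common grid per subject, spanning the subject's pooled
  regional value range extended by three times the largest regional
  bandwidth. A shared grid means 90 density evaluations per subject
  instead of 8010, and every pair shares support.
* **Bandwidth.** Silverman's rule of thumb (`stats::bw.nrd0`) per
  region — the standard default where nothing else is specified.
* **Discrete PDF semantics.** The KDE is evaluated at the grid points
  and renormalized to sum to one, matching the summation form of the
  divergence above (probability mass on sample points, not a continuous
  integral).
* **Zero masses.** Masses are floored at $10^{-10}$ and renormalized
  before logs. Without the floor, disjoint supports give infinite
  divergence; with it, KLS degrades continuously to (effectively) 0
  while $\mathrm{KLS}(P,P)$ stays 1 to within $10^{-9}$.
* A region whose voxel values are all identical has no bandwidth; this
  raises an error naming the region rather than propagating NaNs.

## Thresholding and graph metrics

Networks are analyzed across a sparsity range: at sparsity $S$ the
$K = \mathrm{round}(S \cdot 4005)$ strongest edges are retained with
their weights (R's round-half-even; ties in weight are broken by
ascending node-index pair so reruns are bit-identical). The default
analysis window is $S \in [0.10, 0.34]$ in steps of 0.01, and every
metric curve is summarized by its trapezoidal area under the curve
(AUC) over that window, giving one threshold-free scalar per metric per
subject.

Global metrics: clustering coefficient $C_p$, characteristic path
length $L_p$, global and local efficiency $E_{glob}, E_{loc}$, and the
small-world indices $\gamma = C_p/C_p^{rand}$,
$\lambda = L_p/L_p^{rand}$, $\sigma = \gamma/\lambda$. Nodal metrics:
betweenness, degree (strength), efficiency. Conventions:

* **Weighted by default.** The binary clustering coefficient
  $C_p = \frac{1}{n}\sum_i 2t_i / (k_i(k_i-1))$ ($t_i$ triangles around
  node $i$, $k_i$ its degree) is available as `mode = "binary"` and is
  the form checked exhaustively against brute-force oracles; the
  weighted default is the Onnela geometric-mean-of-triangle-weights
  generalization with weights scaled by their maximum.
* **Distances.** Path-based metrics use Dijkstra on reciprocal weights
  (similarity → length). Disconnected pairs are excluded from $L_p$ and
  contribute 0 to efficiencies, keeping both finite on fragmented
  graphs.
* **Betweenness** is Brandes', unnormalized, on the same lengths.
* **Nodes with fewer than two neighbours** contribute 0 to clustering
  and local efficiency.

### Null models

$\gamma$, $\lambda$, $\sigma$ are normalized by the mean $C_p$ and
$L_p$ of 100 degree-preserving random references per thresholded graph.
Each reference applies $10\times|E|$ attempted Maslov–Sneppen
double-edge swaps; an accepted swap exchanges endpoints and each weight
travels with its edge, so node count, edge count, degree sequence and
the exact multiset of weights are all invariant. The swap loop and the
null-reference statistics run in compiled code (`src/nulls.cpp`)
because they execute 100 × ~25 × n_subjects times per analysis; all
randomness is drawn from R's RNG, so a single `set.seed` reproduces the
entire ensemble.

### Sparsity-window selection

`select_sparsity_range()` finds the sparsities where (a) the mean
nodal degree $2K/90$ exceeds $2\log(90) \approx 9.0$ and (b)
$\sigma > 1.1$ for every subject. Criterion (a) is closed-form: at
$S = 0.10$, mean degree is $2\cdot400/90 = 8.89$, marginally *below*
the rule, while $S = 0.11$ gives 9.8. The package follows the stated
criterion (so the recomputed floor is 0.11) but ships the conventional
$[0.10, 0.34]$ window as the default analysis range; the 0.10 boundary
case is a known rounding ambiguity, documented rather than guessed
away.

### Hubs

For each nodal metric the top 10% of nodes (9 of 90) by group-mean AUC
are flagged; a region's hub score (0–3) counts the metrics flagging
it, and `is_hub` defaults to score ≥ 2. Ties at the cutoff rank are
broken by node index.

## Group inference

* **Permutation tests.** Group differences in AUC metrics use the
  difference of group means with seeded label permutations and a
  two-tailed, add-one p-value
  $(1 + \#\{|d_{perm}| \ge |d_{obs}|\})/(n_{perm}+1)$ — never exactly
  zero, and $p = 1$ when all values tie. Default 5000 permutations.
* **FDR.** Nodal p-values receive Benjamini–Hochberg correction within
  each metric (90 tests); a region is "altered" when significant in at
  least one of the three nodal metrics. Pooling all 270 tests is
  available via `fdr_scope = "pooled"`.
* **Effect sizes.** Cohen's d with pooled SD accompanies every test.
* **Partial correlations** between nodal AUCs and clinical scores
  (UPDRS-III, Hoehn–Yahr, MMSE) adjust for age, gender (coded 0/1) and
  education by least-squares residualization; p-values use the t
  distribution with $n - k - 2$ degrees of freedom.

### Network-based statistic

The NBS tests for connected components of altered connections. Per
edge, a pooled-variance two-sample t-statistic is computed on the raw
KLS weights (an assumption — the procedure is equally applicable to
thresholded matrices) and thresholded at the one-tailed critical value
for the primary p (default 0.05), separately for the decreased and
increased directions. Connected components of suprathreshold edges are
measured by their *number of connections*, and each observed
component's family-wise corrected p is the fraction of label
permutations whose maximal component size reaches it
($\ge N$; 5000 permutations by default).

One property of *synthetic* data matters when exercising the NBS: with
statistically independent edges, a primary threshold of $p < 0.05$
admits noise edges at mean degree $0.05 \times 89 > 1$ per node, so
the suprathreshold noise graph percolates and the null maximal
component is huge. Detection of a small planted subnetwork in the
package's tests therefore uses a stricter primary threshold (0.01),
which keeps the noise graph subcritical. Real imaging data, with
strongly correlated edges, does not behave like independent noise; the
default stays 0.05.

## Classification

Linear soft-margin SVMs discriminate patients from controls using
either the 4005 upper-triangle edge weights or the 7 global + 270
nodal AUC metrics. The procedure is a five-fold stratified outer
cross-validation; within each outer training fold, features are
z-scored with training statistics only and C is selected from
$10^{-3},\dots,10^{4}$ by an inner five-fold stratified grid search
(ties go to the smallest C — the weakest-regularization-pressure
choice). Reported sensitivity, specificity and balanced accuracy
(their mean; the second factor level is "positive") are fold averages.
Significance repeats the whole procedure on permuted labels; the
default estimator is the fraction of permutations whose balanced
accuracy strictly exceeds the real one, floored at $1/(n_{perm}+1)$,
with an add-one variant available.

Implementation note: the linear-SVM dual depends on the training data
only through inner products, so each fold's feature block is replaced
by a Cholesky factor of its (slightly jittered) Gram matrix before
being handed to libsvm via e1071; held-out rows are mapped into the
same inner-product space. This makes each of the ~200 fits per nested
CV independent of the feature count and is exact to numerical
precision (verified against direct fits in the test suite).

Region contributions average absolute weights across folds; nodal
metric features map to their region directly, while edge features add
their weight to both endpoint regions. The top 20 regions are reported
by default.

## The synthetic cohort generator

No imaging data ships with the package; every analysis is exercised on
synthetic cohorts designed to have the statistical structure the
method assumes:

* Each region draws `voxels_per_region` values from a two-component
  Gaussian mixture truncated at zero — mimicking heterogeneous
  grey-matter volume distributions. Defaults: component SDs 0.08/0.12,
  mixing 0.6/0.4, means spaced across [0.25, 0.83].
* The 90 regions form six 15-region communities sharing mixture
  parameters; per-region jitter (SD 0.05, comparable to the component
  SDs) keeps within-community similarity high but far from saturated.
  Since KLS measures distribution-shape similarity, shape-sharing
  plants strong edges and a modular network.
* The patient group's planted effect, scaled per subject by a latent
  severity factor uniform on [0.5, 1.5]: `"cohere"` pulls affected
  regions toward their community's base parameters (strengthened
  within-module similarity → higher segregation), `"disperse"` spreads
  them apart (weakened within-set edges), `"shift"` translates them.
* Patients' UPDRS-III is `slope × severity + noise` (defaults 20 and
  4), so severity-driven network changes carry a clinical correlation
  of known sign; age, gender and education are drawn independently of
  the effect, which is what makes covariate adjustment testable.
* Defaults `n_per_group = 20`, `voxels_per_region = 300` give stable
  KDEs at desk-scale runtime.

What the generator does **not** emulate: brain geometry and spatial
smoothness, registration artifacts, realistic covariance of edges
(edges are conditionally independent given the design), site or
scanner effects, and realistic effect sizes. Passing tests therefore
demonstrate that the machinery is correct and calibrated — not that
real grey-matter networks will show effects of any particular size.

## Problem sizes and budgets

The package's own end-to-end demonstration (and its test) runs 20+20
subjects, 300 voxels per region, the 0.10–0.34 window, 100 random
references per thresholded graph, 1000 permutations for group and NBS
inference, and 100 label permutations for classifier significance —
sizes chosen so a complete run takes minutes on a single core while
every stage still has measurable power. The function defaults
(5000 inference permutations, 1000 classifier permutations) match
common practice for real analyses.

## Known limitations

* The KDE kernel, bandwidth rule and grid placement are conventions;
  other defensible choices shift KLS values slightly (the identities
  and orderings tested are insensitive to this).
* The Onnela weighted clustering and the subgraph-based weighted local
  efficiency are one of several reasonable weighted generalizations.
* NBS assumes exchangeability of subjects under the null and uses a
  pooled-variance t per edge; heavy-tailed edge noise would call for a
  robust edgewise statistic.
* With 90 independent-ish nodal tests per metric, FDR control is per
  metric; regions flagged through the "at least one metric" rule carry
  the usual selection caveats.
* The SVM weight-based region ranking is a heuristic: correlated
  features share weight mass, and the edge-to-region aggregation
  (sum over incident edges) is an assumption, flagged as such.
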