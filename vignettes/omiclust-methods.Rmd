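---
title: "Sparse joint latent-variable clustering: model, tuning and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse joint latent-variable clustering: model, tuning and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiclust)
```

## The model

Tumor subtypes rarely announce themselves in a single molecular assay. Copy
number, DNA methylation and mRNA expression each see a different facet of the
same underlying disease process, and clustering each data type separately
then reconciling the labels by hand loses exactly the cross-platform
correlation that makes a driving alteration recognisable. `omiclust` instead
models all data types jointly. With $m$ feature-by-sample matrices
$X_1, \dots, X_m$ (type $t$ holding $p_t$ features on the same $n$ samples),
the model is a Gaussian factor analysis with a latent variable shared across
types:

$$X_t = B_t Z + \varepsilon_t, \qquad Z_i \sim N(0, I_{K-1}), \qquad
\varepsilon_t \sim N(0, \Psi_t),$$

where $B_t$ is the $p_t \times (K-1)$ loading matrix of type $t$, $\Psi_t$ is
diagonal, and the latent dimension is fixed at $K - 1$ for a $K$-cluster
solution: $K$ well-separated groups need at most $K-1$ discriminating
directions. Cluster structure lives in the shared latent subspace; K-means on
the posterior means $E[Z \mid X]$ produces the labels.

Estimation is by EM on the stacked matrix $X$ ($p = \sum_t p_t$ rows). The
E-step is the standard Gaussian factor-model posterior,

$$\mathrm{Cov}(Z \mid X) = (I + B'\Psi^{-1}B)^{-1}, \qquad
E[Z_i \mid X] = \mathrm{Cov}(Z \mid X)\, B'\Psi^{-1} x_i,$$

computed through the Cholesky factor of the $(K-1)\times(K-1)$ inner matrix
so cost is linear in $p$. The M-step first forms the unpenalized update
$\hat{B} = X E[Z]' \left(\sum_i E[Z_i Z_i']\right)^{-1}$ and then passes every
entry through a soft-threshold, $\mathrm{sign}(b)(|b| - \lambda)_+$, so that
features carrying no cluster information end with exactly-zero loading rows —
feature selection is part of the fit, not a pre-filter. In the default
*variance-weighted* mode the threshold applied to feature $j$ is
$\lambda \sigma_j^2$: features whose residual variance stays high (features
the factors explain poorly) are penalized harder and leave the model first.

## Numerical choices that turned out to matter

* **Penalty parameterization.** Users give a per-type sparsity level
  $s \in [0,1]$ with $s = 0$ the null model (nothing selected) and $s = 1$
  the full model. Internally $s$ maps to an absolute threshold
  $(1-s)\max_j |\hat b_{jk}|$ *per factor column* within the data type (in
  weighted mode, the analogous maximum of $|\hat b_{jk}|/\sigma_j^2$). The
  per-column scale matters: a single threshold scaled by the type-wide
  maximum lets a dominant factor dictate the threshold for every factor, and
  in multi-factor fits we observed the weaker factor's entire column being
  annihilated, destroying cluster structure that the data clearly support.
* **Residual variances from the unpenalized update.** The diagonal
  $\Psi$ update uses the residuals of $\hat{B}$, not of the thresholded $B$.
  Using the shrunken loadings folds the shrinkage bias into
  $\sigma_j^2$; under the variance-weighted penalty that creates a feedback
  loop (more shrinkage → larger apparent variance → larger threshold) which
  can annihilate even enormous planted effects. With the unpenalized
  residuals the weights measure what they are meant to measure — how well
  the factors explain a feature.
* **Clamped variance weights.** In the weighted threshold the variances are
  clamped below at 5% of the type's median, so a handful of near-perfectly
  explained features (variances at the floor) cannot set the penalty scale
  for the rest of the type.
* **Initialization and convergence.** Loadings start from the truncated SVD
  of the stacked standardized data (deterministic, with a sign convention);
  $\Psi$ starts at the residual feature variances. EM stops when the largest
  absolute parameter change falls below `tol` (default `1e-4`) or after
  `max_iter` (default 200) iterations, returning `converged = FALSE` with a
  warning in the latter case. Residual variances are floored at `1e-6`.
  With all penalties at 1 the observed-data log-likelihood (tracked every
  iteration via the Woodbury identity) is non-decreasing — the classical EM
  guarantee, asserted in the tests; with active thresholding convergence is
  declared on parameter change instead, as penalized EM need not be monotone
  in the unpenalized likelihood.
* **Cluster assignment.** K-means on $E[Z\mid X]$ with 20 restarts under a
  fixed seed; clusters are renumbered by first occurrence so runs are
  reproducible bit for bit. Degenerate all-zero fits (possible at $s = 0$)
  return a single cluster with a warning rather than an error.
* **Standardization.** `omiclust()` z-scores each feature by default, the
  usual choice for real expression/methylation matrices whose per-feature
  scales are arbitrary. The simulation benchmarks instead run center-only:
  the generators produce unit-SD noise by construction, and z-scoring data
  with planted mean shifts caps the attainable per-feature effect at 2 SD
  (the planted shift inflates the very SD it is divided by), which would
  make the extremely sparse scenario unreproducible at any effect size.

## Choosing K and the penalties

Two complementary criteria drive model selection, both computed by
resampling rather than from the likelihood (which keeps growing with K and
with the number of retained features):

* **Reproducibility index (RI).** The samples are repeatedly split in half.
  The model is fit on the learning half; the held-out samples are projected
  through the learned loadings and assigned to the nearest learned centroid;
  the model is refit on the held-out half; and the adjusted Rand index
  between predicted and refit labels is recorded. RI is the mean across
  splits: a clustering worth reporting should reproduce on data the fit
  never saw. Balanced halves are used so both fits rest on equal sample
  sizes; 20 splits give a reporting-quality estimate, and a coarser
  8-split, iteration-capped version ranks penalty points during tuning.
* **POD separability.** The product matrix $E[Z]'E[Z]$, min–max mapped to
  $[0,1]$ and sorted by cluster, should be block-diagonal — ones within
  clusters, zeros between — if clusters are well separated. POD is the mean
  absolute deviation from that ideal; small is good. It breaks RI ties and
  gives the diagnostic plot (`autoplot()` on a tuning object).

The per-type penalty vector lives in $[0,1]^m$, and RI is too expensive to
evaluate on a grid. Tuning therefore samples the cube with a **uniform
design**: $T$ points such that every coordinate takes each of the $T$
centred levels $(2i-1)/2T$ exactly once, constructed from good-lattice
generating vectors (tabulated for $T \in \{5, 8, 13, 21, 34\}$ at 2 and 3
dimensions, chosen by centred-$L_2$-discrepancy search; other sizes fall
back to a seeded maximin Latin hypercube snapped to the same levels). Unlike
a grid, no two trials share any coordinate value, so $T$ fits explore $T$
distinct sparsity levels per data type. `tune_omiclust()` evaluates RI at
every point for every candidate $K$ and recommends the $K$ with the best
RI, ties broken by smaller POD, then smaller $K$.

## The simulation test bed

Because the package's accuracy claims are benchmarked on synthetic data, the
generators are first-class, tested code:

* **Scenario 1** — two matched 200 × 100 types, two equal clusters, 20
  planted features per type carrying a mean shift of $\delta$ noise-SD
  units (±δ/2), 180 pure-noise features.
* **Scenario 2** — identical shape, but only 2 planted features per type:
  the extreme-sparsity regime where whole-matrix methods drown.
* **Three-cluster** — 150 samples, two 1,000-feature types; 5 features
  shared by both types mark cluster 1, 5 type-2-only features mark cluster
  2, cluster 3 is background. The cluster-2 signal is invisible in type 1,
  so no single data type can recover all three groups — the scenario that
  makes the case for joint modelling. The planted features are strongly
  mutually correlated ($r \approx 2/3$ at the default effect size) through
  the cluster indicator they share.

The published benchmarks these scenarios emulate do not print the effect
size or noise model, so the generator defaults were **calibrated once and
frozen** (`scripts/calibrate_effect_size.R`): the scenario-1 $\delta = 0.90$
anchors the per-type K-means baseline to its published CV error of 0.08;
the scenario-2 $\delta = 2.90$ minimises a combined discrepancy against that
baseline's published error (0.11) and reproducibility (0.48), each gap
scaled by the published scenario-1 SD of the quantity, because no single
$\delta$ reproduces both exactly under Gaussian noise; the three-cluster
$\delta = 3.0$ puts the concatenated-PCA baseline in its published regime —
visibly but incompletely separating the clusters — while the sparse joint
fit separates them nearly perfectly. These defaults are study conditions,
not tuning knobs: every benchmark, test and acceptance run uses them.

What the generators deliberately do not emulate: copy-number segmental
correlation along the genome, bounded beta-distributed methylation values,
heavy-tailed expression noise, unequal cluster sizes, or batch structure.
Passing benchmarks here show the estimator and its model selection behave
as published under the planted-Gaussian conditions — they do not certify
performance on any particular real cohort.

One published behaviour is knowingly not reproduced: the benchmark table's
correct-K frequencies (90%/60% and 92%/40%). Under this generator the RI
criterion selects the planted $K$ in essentially every replicate, for the
baseline as well as the integrative model, at the frozen effect sizes; the
frequencies evidently depend on unpublished details of the original noise
model that the error-rate and RI anchors do not pin down. The benchmark
harness reports the frequencies it actually measures.

## Benchmark protocol and problem sizes

`run_benchmark()` is the machine twin of the published comparison table.
Per replicate it tunes the integrative model ($K \in \{2,3,4\}$, 8 UD
points, 8 coarse splits with EM capped at 60 iterations), then scores both
methods at the planted $K$: 5-fold cross-validated misclassification versus
the planted labels (predicted labels aligned by optimal assignment, found
exhaustively — cluster counts are tiny) and the 20-split RI. Per-type
baseline results are averaged, matching the reporting convention of the
published table. The shipped acceptance script runs 25 replicates per
scenario, a size chosen to keep a full two-scenario run in the
ten-minutes-per-scenario range on one core while leaving Monte-Carlo SEs
well below the published SDs; the three-cluster comparison uses 20 paired
replicates at a fixed mid-range penalty of 0.45 (tuning adds nothing to a
paired contrast and the conclusion is stable for penalties 0.45–0.6).

## Validation utilities

`knn_loocv()` and `knn_transfer()` implement the single-data-type
validation loop: leave-one-out $k$-nearest-neighbour reproduction of
integrated cluster labels from one data type alone (Euclidean distance,
majority vote, $k$ chosen to minimise the CV error). Both use deterministic
tie-breaking — distance ties by sample order, vote ties by lowest cluster
index — which is why they are hand-rolled rather than delegated to a
library classifier. `gaussian_mi()` converts a Pearson correlation to
mutual information via the bivariate-Gaussian closed form
$-\tfrac12\log(1-\rho^2)$ (natural log, nats), and `mi_enrichment()` asks
whether the selected feature space is enriched for cross-type dependence:
feature pairs matched by identifier, per-pair MI, and a one-sided Wilcoxon
shift test of selected against unselected pairs. Pearson correlation is
used (consistent with the Gaussian formula); a rank correlation would be
the natural swap for heavy-tailed data.

## Known limitations

* The latent factors are only identified up to rotation when the penalty is
  inactive; reported loadings at $s = 1$ should be read as a subspace.
* The EM objective is non-convex: different penalties can settle into
  different local solutions, so the selected-feature count is guaranteed
  monotone in $s$ only within one M-step (the tests assert exactly that,
  plus the endpoint identities).
* Missing values are not modelled — ingestion either drops incomplete
  features or refuses the matrix.
* Cross-validated error against planted truth uses optimal label alignment
  per fold; with more than ~7 clusters the exhaustive assignment search
  would need replacing with a Hungarian solver.
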