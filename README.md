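# omiclust

Integrative clustering of multi-omics data by a sparse joint latent-variable
model, for statisticians and computational biologists who have two or more
genomic data types — copy number, DNA methylation, mRNA expression — measured
on the same samples and want subtypes defined by *all* of them at once,
together with the features that define each subtype.

The standard workflow clusters each data type separately and reconciles the
labels by hand; that discards the cross-platform correlation that makes a
driving alteration recognisable, and its results are notoriously data-type
dependent. `omiclust` instead models the types jointly:

```
X_t = B_t Z + e_t,    Z ~ N(0, I_{K-1}),    e_t ~ N(0, Psi_t diagonal)
```

where the latent factor vector `Z` is shared across all data types
(`K - 1` factors for `K` clusters), `B_t` is the loading matrix of type `t`,
and K-means on the posterior means `E[Z | X]` gives the cluster labels.
Fitting is by EM with lasso-style soft-thresholding applied to the loading
update at every iteration — by default with a *variance-weighted* penalty
whose threshold is proportional to each feature's residual variance, so
noisy features are removed first and the surviving nonzero loading rows are
the subtype-discriminant features. The number of clusters and the per-type
penalties are chosen by a resampling-based cluster **reproducibility index**
(mean adjusted Rand between predicted and refit labels over learning/test
splits) and a **POD** separability measure (deviation of the latent product
matrix from an ideal block-diagonal), evaluated over a number-theoretic
**uniform design** of the penalty cube rather than a grid.

Also included: per-type K-means and concatenated-PCA baselines, planted-
cluster simulation generators with a benchmark harness, k-nearest-neighbour
leave-one-out validation of cluster labels from a single data type, and
Gaussian mutual-information enrichment analysis of the selected features
(`-0.5 * log(1 - rho^2)` per cross-type feature pair).

## Worked example

```r
library(omiclust)

# two matched 200 x 100 data types, two planted clusters, 20 relevant
# features per type among 180 noise features
sim <- gen_scenario1(seed = 42)

tuned <- tune_omiclust(sim$dataset, K_range = 2:4, n_trials = 8,
                       n_splits = 8, seed = 1, scale = "center")
glance(tuned)
#> # A tibble: 1 × 5
#>       K    RI   POD penalty_type1 penalty_type2
#>   <int> <dbl> <dbl>         <dbl>         <dbl>
#> 1     2 0.624 0.389         0.938         0.938

rec <- recommended_k(tuned)
fit <- omiclust(sim$dataset, K = rec$K, penalties = rec$penalties,
                scale = "center", seed = 1)
fit
#> <omiclust_fit> K = 2 (1 latent factor(s)), n = 100
#>   penalties: type1 = 0.938, type2 = 0.938
#>   selected features: type1 = 128, type2 = 142
#>   converged: TRUE after 16 iterations

adjusted_rand(fit$labels, sim$true_labels)
#> [1] 0.9208013

sel <- selected_features(fit)
sum(sel$index[sel$type == "type1"] %in% sim$true_features$type1)
#> [1] 20
```

The tuning table recommends the planted `K = 2`: its reproducibility index
(0.62 here, on the coarse 8-split estimate used for ranking) beats the
K = 3 and K = 4 candidates, and the chosen fit recovers the planted
partition almost exactly (adjusted Rand 0.92) while keeping all 20 planted
type-1 features among those with nonzero loadings. `autoplot(fit)` draws the
samples in the latent subspace coloured by cluster; `tidy(fit)` returns the
loadings as a long tibble; `cluster_assignments(fit)` the labels.

A command-line entry point wraps the same functions
(`exec/omiclust fit|tune|simulate|benchmark|validate|mi`), writing labels,
loadings and selections as TSV plus a JSON report with the seed and
configuration hash, so every run is reproducible from its artifacts.

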