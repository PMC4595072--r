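# ednacomp

Tools for asking whether soil **environmental DNA (eDNA) metabarcoding**
sees the same biodiversity structure as **traditional field surveys**.
The setting: a set of forest plots along an elevational gradient, each
censused by several eDNA markers (16S, 18S, trnL, ITS, COI, spun-COI) and
by conventional methods (seedling and tree counts, invertebrate
collections, bird counts), every method summarised as a sample-by-OTU
community matrix. Absolute diversity numbers are incomparable across such
methods — they census different organisms at read depths differing by
orders of magnitude — but the *between-plot structure* can be compared,
and that comparison is what this package implements.

## What it computes

At the core are Jost's multiplicative **Hill-number partitions**. With
relative abundances $p_{ij}$ (OTU $i$, sample $j$), equal sample weights
$w_j = 1/N$, and pooled frequencies $\bar p_i = \sum_j w_j p_{ij}$:

$$D_\gamma = \Big(\sum_i \bar p_i^{\,q}\Big)^{1/(1-q)},\quad
D_\alpha = \Big(\tfrac{\sum_{ij}(w_j p_{ij})^q}{\sum_j w_j^q}\Big)^{1/(1-q)},\quad
D_\beta = D_\gamma/D_\alpha,$$

with the usual exponential-entropy limits at $q = 1$. Pairwise
**turnover** $(D_\beta - 1)/(N-1) \in [0,1]$ over plot pairs is the
dissimilarity fed to every comparison:

- **Mantel tests** (one-tailed, joint row/column permutation, exact
  enumeration when $n! \le 5040$) of turnover against elevation
  difference, and between methods (the method correlation matrix);
- **distance-decay regression** of turnover on elevation separation;
- **NMDS / PCoA** ordinations and **Procrustes (PROTEST)** concordance
  ($m^2_{12}$ with permutation p);
- **second-stage MDS** of methods from their Mantel correlations;
- **greedy conservation prioritization** (iteratively remove the plot
  maximising the retained effective beta) and Spearman agreement of
  rankings across methods;
- **stepwise VIF screening** of environmental covariates and
  **distance-based RDA** with permutation tests and forward/backward
  selection;
- **rarefaction** of all three diversity components by pooled read
  subsampling;
- a **synthetic gradient-metacommunity generator** (Gaussian elevational
  niches, lognormal abundances, multinomial read sampling, planted
  covariate collinearity) for calibration and testing without sequence
  data.

## Worked example

Simulate three methods over the ten packaged plots (50–640 m elevation),
then compare:

```r
library(ednacomp)
cfg <- synthetic_config(
  profiles = list(
    "18S" = marker_profile("18S", S = 1300, depth = 11000, g = 0.9),
    "COI" = marker_profile("COI", S = 2800, depth = 2000, g = 0.9),
    "seedlings" = marker_profile("seedlings", S = 90, depth = 1300, g = 0.85)),
  seed = 11)
sim <- simulate_gradient_metacommunity(cfg)

cm <- pool_to_plots(sim$communities[["COI"]])
partition_diversity(cm, q = 1)
#> Diversity partition (q = 1, 10 samples):
#>   alpha 1032.8996  beta 1.6373  gamma 1691.1356
```

The COI-like marker recovers about 1033 effective OTUs per plot and 1691
overall; beta 1.64 means the ten plots hold the equivalent of 1.64
completely distinct communities. Does turnover track elevation?

```r
turn <- pairwise_turnover_matrix(cm, q = 1)
elev <- setNames(sim$env$elevation, rownames(sim$env))
mantel_test(turn, dist(elev), n_perm = 4999, seed = 1)
#> Mantel r = 0.9806, p = 0.0002 (Monte Carlo, 4999 permutations, one-tailed greater)
distance_decay_regression(turn, elev)
#> Distance decay: slope 0.000715 per m, r = 0.981, R^2 = 0.962, p = 4.72e-32 (45 pairs)
```

Strong distance decay: plots 100 m further apart in elevation differ by
about 0.07 more turnover. (The planted synthetic gradient is much cleaner
than field data, hence the near-perfect correlation.) The full battery:

```r
rep <- run_full_comparison(sim$communities, sim$env, n_perm = 999, seed = 2)
rep$method_correlation
#> Method correlation matrix (3 methods, 10 common plots)
#>             18S   COI seedlings
#> 18S       1.000 0.997     0.985
#> COI       0.997 1.000     0.989
#> seedlings 0.985 0.989     1.000
greedy_beta_ranking(cm, q = 1)
#> Greedy beta-retention ranking [COI], q = 1 (first removed = lowest priority)
#>    1. remove Plot4        retained beta 1.652
#>    ...
#>   10. remove Plot10       retained beta -
```

All three methods see the same between-plot structure (Mantel r ≥ 0.985),
and the gradient endpoints (Plot1 at 50 m, Plot10 at 640 m) survive
longest in the prioritization — they contribute the most complementary
composition.

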