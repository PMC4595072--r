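---
title: "Comparing biodiversity across eDNA markers and traditional surveys"
author: "ednacomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing biodiversity across eDNA markers and traditional surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Soil environmental DNA (eDNA) metabarcoding censuses a community by
amplifying and sequencing a taxonomically informative marker (16S for
prokaryotes; 18S, ITS, trnL, COI for various eukaryote groups) directly
from soil, clustering the reads into operational taxonomic units (OTUs) at
a fixed similarity threshold, and tallying reads per sample and OTU into a
*community matrix*. Whether such matrices are useful proxies for
traditional biodiversity surveys (vegetation counts, invertebrate
collections, bird counts) is an empirical question: the methods census
different organisms at wildly different depths, so raw diversity numbers
are incomparable, but the *structure* of between-plot differences may
still agree. `ednacomp` implements the statistical battery for exactly
this comparison, for designs in which a set of plots spanning an
environmental gradient (here, elevation) is sampled by several methods at
once.

## Diversity model

All diversity quantities are Hill numbers (effective numbers of species).
For a community matrix with $N$ samples, relative abundances
$p_{ij}$ of OTU $i$ in sample $j$, sample weights $w_j$ (equal,
$w_j = 1/N$, throughout the pipeline) and pooled frequencies
$\bar p_i = \sum_j w_j p_{ij}$, the order-$q$ partition is

$$
D_\gamma = \Big(\sum_i \bar p_i^{\,q}\Big)^{1/(1-q)}, \qquad
D_\alpha = \Bigg(\frac{\sum_i \sum_j (w_j p_{ij})^q}{\sum_j w_j^q}\Bigg)^{1/(1-q)}, \qquad
D_\beta = D_\gamma / D_\alpha,
$$

with the $q \to 1$ limits $D_\gamma = \exp(-\sum_i \bar p_i \ln \bar p_i)$
and $D_\alpha = \exp(-\sum_j w_j \sum_i p_{ij} \ln p_{ij})$; terms with
$p = 0$ contribute nothing and logarithms are natural. The partition is
multiplicative ($D_\gamma = D_\alpha D_\beta$ exactly, by construction of
$D_\beta$, and the implementation is tested against an independent
direct-formula oracle at $10^{-10}$ relative tolerance), and with equal
weights $D_\beta$ ranges from 1 (all samples compositionally identical) to
$N$ (all disjoint). *Turnover* between two samples is the normalised
pairwise effective beta, $(D_\beta - 1)/(N - 1)$ with $N = 2$, bounded in
$[0, 1]$; order $q = 1$ turnover is the canonical pairwise dissimilarity
for every comparison stage because it is bounded and abundance-weighted.

Reported summary rows follow the effective-number convention: "alpha
diversity" is the $q = 0$ partition (mean within-sample richness) and
"effective alpha diversity" the $q = 1$ partition (exponential of mean
Shannon entropy). This reading is fixed by the magnitudes such tables
show (richness far exceeding the effective number) and by the
effective-number language itself.

## Comparison battery

* **Mantel tests** correlate the off-diagonal entries of two distance
  matrices over the same plots; significance is by jointly permuting rows
  and columns of one matrix. The test is one-tailed (greater), matching
  the directional hypotheses (more separation, more turnover), with
  $p = (1 + \#\{r^* \ge r\})/(n_\text{perm} + 1)$ so $p$ can never
  undercut the permutation resolution. When $n! \le 5040$ the test
  switches to exact enumeration automatically. Conventional usage is
  4,999 permutations.
* **Distance decay** regresses pairwise turnover on absolute elevation
  difference by OLS over all unordered pairs; the Mantel test provides the
  permutation significance for the same relationship.
* The **method correlation matrix** (pairwise Mantel $r$ between the
  turnover matrices of every pair of methods, restricted to common plots)
  summarises which methods see the same between-plot structure; feeding
  $1 - r$ to non-metric MDS gives the **second-stage MDS** of methods.
* **NMDS** (global monotone regression, stress-1, 20 random starts) and
  **PCoA** (Gower double-centering; negative-eigenvalue axes dropped with
  their magnitude reported, no Lingoes/Cailliez correction) provide
  sample ordinations. **PROTEST** measures ordination concordance by the
  symmetric Procrustes statistic $m^2_{12} = 1 - (\sum_k \sigma_k)^2$
  (singular values of the cross-product of unit-sum-of-squares
  configurations), with the permutation scheme and exhaustive mode as for
  Mantel.
* **Greedy prioritization** ranks plots by iteratively removing the plot
  whose removal maximises the $q = 1$ beta diversity of the remainder;
  first removed = most redundant. Ties break lexicographically by plot
  id. Removal stops when two plots remain (beta of a single plot is
  degenerate); the final pair is ordered by the same lexicographic rule,
  a convention this package states rather than infers. Rank agreement
  between methods uses tie-corrected Spearman rho with exact enumeration
  for $n \le 8$.
* **Environmental drivers**: aspect (circular) enters as
  $\sin(\text{aspect})$ and $\cos(\text{aspect})$ (east- and
  north-facing components); skewed soil chemistry is log-transformed.
  The default log list — Olsen P, electrical conductivity, nitrate,
  ammonium — covers the measurements that are right-skewed in typical
  soil data; it is configuration, not inference, and can be replaced.
  All predictors are standardized so db-RDA inertia fractions are
  scale-free. Collinearity is pruned by the classic stepwise VIF loop
  (drop the largest VIF $\ge 10$, recompute, repeat), with exact
  singularities treated as infinite VIF. **db-RDA** embeds the Jaccard
  community distance by PCoA (positive axes, $\sqrt\lambda$ scaling) and
  projects the site scores onto the predictor space; constrained inertia
  is the squared norm of the fitted values, and the pseudo-$F$ is tested
  by free permutation of site-score rows (the cited constrained-ordination
  default; residual-permutation schemes are out of scope). Forward
  selection adds the smallest-$p$ candidate while $p < \alpha$; backward
  drops the largest-$p$ variable while $p \ge \alpha$.

## What the synthetic generator emulates — and what it does not

`simulate_gradient_metacommunity()` draws, per marker, a species pool with
uniform niche optima $\mu_i$ over the elevation range, Gaussian niche
width $\sigma$ (meters), lognormal abundances $A_i$, and a mixture weight
$g \in [0,1]$ interpolating between the pure niche model and a flat
(structureless) model, so power and type-I calibrations share one code
path. Expected plot compositions are sampled multinomially per subplot at
the profile's depth, preserving the plot $\supset$ subplot hierarchy. The
environment table plants the collinearities these analyses must cope
with: temperature is a linear function of elevation plus noise (the
observed lapse rate of the packaged fixture, about $-0.5\,^\circ$C per
100 m), and a latent soil-fertility factor drives electrical conductivity,
organic carbon, total nitrogen, ammonium and water content jointly.

Default marker profiles mirror the characteristic field contrasts at
desk scale: pool sizes from 600 to 6000 OTUs, depths from 1,500 to
15,000 reads per sample, and gradient strengths ordered so the 18S- and
COI-like markers respond most strongly to elevation, the 16S- and
trnL-like ones least. The elevations default to the packaged
`table1_fixture()`: ten plots, one per 60 m band, 50–640 m.

The generator reproduces the *statistical* structure the analyses assume,
not real data: no OTU-clustering noise, chimeras or taxonomic
mis-assignment; niches are Gaussian on a single latent gradient
(elevation, with temperature derived from it); abundances are
exchangeable lognormals with no phylogenetic or spatial autocorrelation
beyond the gradient. Because the planted gradient is much cleaner than
field data, distance-decay correlations on default synthetic runs come
out higher than field surveys typically show; passing calibration and
recovery tests therefore demonstrates correctness of the machinery, not
field-level effect sizes.

## Numerical choices

* $0 \ln 0 := 0$; all logs natural.
* Orders $q \ne 1$ use the closed form directly; the $q = 1$ limit is a
  separate branch. Continuity through $q = 1$ is tested at
  $q = 1 \pm 10^{-5}$.
* Turnover values are clamped to $[0, 1]$ against floating-point drift.
* Permutation tails use a $10^{-12}$ tolerance when counting
  $r^* \ge r$ so the identity relabeling always counts in exhaustive
  mode.
* NMDS convergence follows `vegan::metaMDS` (procrustes-stable best
  solution over 20 random starts); non-convergence is flagged on the
  result, not fatal. Tie treatment in the monotone regression is vegan's
  primary (weak) treatment, under which completely tied dissimilarities
  fit any configuration with zero stress.
* PCoA eigenvalues below $10^{-9} \times$ the spectral radius are treated
  as null; negative eigenvalues are reported as `negative_inertia`.
* Empty samples are always errors, never silent drops — except inside
  rarefaction replicates, where a sample that receives no reads at a
  small depth is necessarily absent from that replicate's partition.
* Rarefaction subsamples the *pooled* read multiset (the x-axis is total
  reads); per-sample rarefaction is available as an option. Replicate
  streams are split from the master seed so each replicate is
  reproducible in isolation.
* Pipeline stages derive their seeds by hashing the stage name into the
  master seed, so adding a stage never perturbs the others, and reruns
  are byte-identical.

## Open design points resolved here

* Whether plot-level or subplot-level rows feed the summary tables is not
  fixed by the data deposit; the reader supports both and the pipeline
  pools to plot level (`pool_to_plots()`) for all plot-indexed analyses.
* Jaccard is computed on presence/absence (the index form); the
  quantitative Ružička variant sits behind `quantitative = TRUE`.
* The significance machinery for the elevation analysis is the Mantel
  permutation test (the form the tabulated statistics take); no separate
  PERMANOVA is implemented.
* Diversity totals are never summed across markers: OTU counts add, but
  diversities of different markers are not commensurable.

## Problem sizes used by the test suite

The calibration and recovery checks run at: 100 random matrices
($\le 5$ samples $\times \le 20$ OTUs) for oracle equivalence; 1,000 null
simulations of 10 plots with 999 permutations each for Mantel and PROTEST
type-I error; 100 seeds of the strong-gradient condition ($g = 1$,
$\sigma = 50$ m, $S = 200$, depth 5,000) for recovery; 100 random 5–6
plot instances for greedy optimality; 50 replicates at depths 100 and
5,000 for rarefaction stability. These sizes were chosen to make the
binomial bands on the calibration rates tight (about $\pm 1.4\%$ at
1,000 simulations) while keeping a full test run around a minute and a
half on one core.

## Limitations

* Plug-in (empirical) Hill numbers only: no Chao-type bias correction or
  coverage-based rarefaction, so alpha and gamma estimates at low depth
  are downward-biased — which is precisely the sensitivity the
  rarefaction module exposes.
* Free permutation is the only permutation scheme; restricted or
  residual-based schemes (strata, blocks) are not implemented.
* The db-RDA is the projection form on positive PCoA axes; imaginary-axis
  variance is excluded from the constrained decomposition and reported
  separately.
* With ten plots, Spearman rank tests over methods have little power, and
  stepwise selection at $\alpha = 0.05$ with 999 permutations sits near
  the resolution limit of the permutation p-values; both are properties
  of the design, not the implementation.
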