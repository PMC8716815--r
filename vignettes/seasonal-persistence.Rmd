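---
title: "Methods: seasonal dynamics and persistence of microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal dynamics and persistence of microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, the parameters that matter, and
the design decisions taken where the methodology is genuinely open. The
setting is a factorial survey of host-associated microbial communities —
two sites (a reference site and a stressed one), two tissue types, four
seasons, five replicate plants — yielding taxa-by-sample count tables
(amplicon ASVs/OTUs) rarefied to a common depth.

## Preprocessing

`filter_taxa()` removes taxa with a dataset-wide total count below 3
(singletons and doubletons) and taxa whose dataset-wide relative abundance
(taxon total over grand total) is below 0.001. Both rules are evaluated on
the table as loaded, *before* rarefaction, and filtering precedes
rarefaction throughout the pipeline. The total-count rule is interpreted
at the dataset level (not per sample): the per-sample reading would
remove different taxa from different samples and make the taxon universe
unstable across the analysis.

`rarefy_table()` subsamples each sample's reads without replacement to a
common depth, by default the minimum sample sum; a single draw is used
(not an average over draws) so the downstream table is an ordinary count
table, and the seed is mandatory in pipeline use. Samples below the depth
are dropped with a warning rather than padded.

## Hill-number diversity

`hill_number()` implements the effective number of taxa
$^qD = (\sum_i p_i^q)^{1/(1-q)}$ with the natural-log Shannon limit at
$q = 1$; the Hill framework is base-free after exponentiation. Diversity
curves (`hill_curve()`) work on incidence data: the sampling unit is the
replicate, matching a design where within-group replicates are the
natural unit of effort.

*Interpolation.* For $q = 0$ the interpolated value is the exact
hypergeometric expectation of richness in a random subset of $t$ units.
For $q = 1, 2$ the interpolated value is defined as the expectation of
the empirical (plug-in) Hill number over random $t$-subsets, computed by
exact enumeration when $\binom{T}{t} \le 20{,}000$ and by Monte Carlo
(200 subsets) otherwise. This estimand is directly checkable against a
brute-force subsampling oracle, which is how the test suite validates it;
asymptotically debiased interpolants exist but have no such finite-sample
oracle.

*Extrapolation.* Richness extrapolates with the Chao2 estimate of
undetected taxa, $\hat Q_0 = \frac{T-1}{T}\,\frac{Q_1^2}{2Q_2}$ (with the
usual bias-corrected form when $Q_2 = 0$), approaching
$S_{obs} + \hat Q_0$ at the geometric rate $Q_1/(Q_1 + T\hat Q_0)$. For
$q = 1, 2$ the curve approaches the asymptotic incidence estimators (a
coverage-adjusted exponential entropy for $q = 1$; the nearly unbiased
inverse Simpson for $q = 2$) at the same rate — the rate is not
separately identifiable for these orders, so sharing the $q=0$ rate is a
package design choice. Curves pass through the empirical value at the
observed size by construction. Confidence bands come from bootstrap
resampling of sampling units (200 replicates by default) rather than
analytic variance formulas: simpler, and testable.

## Composition

Bray-Curtis dissimilarities are computed on rarefied counts (not
re-normalised relative abundances), consistent with rarefaction-first
preprocessing. `permanova()` is the one-factor pseudo-F partition of
squared dissimilarities with label-permutation p-values
$p = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$, and `anosim()` the rank-based
R statistic with average ranks for ties; both default to 999
permutations. Multi-factor and nested designs are out of scope — the
pipeline tests each factor separately within tissue. NMDS delegates to
`vegan::metaMDS` (Kruskal stress-1, 20 random starts, isotonic
regression with primary tie treatment). One consequence of primary ties
worth knowing: a distance matrix in which all dissimilarities are equal
carries no rank constraints at all and fits with zero stress.

## Sloan neutral community model

The model treats a local community as a sample of the metacommunity under
drift and immigration. The local relative abundance of a taxon with
metacommunity frequency $p$ is approximately
$\pi \sim \mathrm{Beta}(Nm\,p,\; Nm\,(1-p))$, and expected occupancy is
the mass above the detection limit $d = 1/\text{depth}$:

$$\widehat{freq}(p) = 1 - B(d;\; Nm\,p,\; Nm\,(1-p)).$$

`fit_ncm()` estimates $Nm$ by least squares on the occupancy-abundance
cloud, searching $\log Nm \in [\log 1, \log 10^7]$ with five bounded
scalar searches (tolerance $10^{-8}$); the profile is one-dimensional and
unimodal in practice, which avoids gradient pathologies near $p \approx
0$. $R^2 = 1 - SSE/SST$ (SST about the mean occupancy) may be negative:
with five replicates occupancy takes only six values and the binomial
noise can exceed the systematic signal. Confidence intervals for $Nm$ and
$R^2$ come from 1,000 taxon-resampling bootstrap replicates.

Per-taxon deviations use a 95% Wilson score band around
$\widehat{freq}_i$ at the observed number of samples; `above` / `below` /
`neutral` labels are exhaustive and exclusive. The band convention is the
one used in the widely circulated fitting scripts; note that for any
prediction strictly below 1 the Wilson upper bound is strictly below 1,
so a taxon observed in every sample is always labelled `above` — with few
samples this is permissive, which is why the persistence requirement
(same direction in **all** seasons, `persistence_across_seasons()` with
`min_count = 4`) is the meaningful filter. The direction labels are
reported neutrally; whether `above` reflects host selection and `below`
dispersal limitation is an ecological interpretation left to the user.

Two details matter for fitting quality. First, the detection-threshold
approximation ignores that detection at finite depth is binomial, not a
step function; for taxa below ~$10^{-3}$ relative abundance this inflates
occupancy relative to the threshold prediction and biases $\hat{Nm}$
upward by roughly 20% if such taxa are included. The standard
preprocessing (removing taxa under 0.001 dataset relative abundance)
excises exactly that region, and the parameter-recovery tests fit after
filtering, as the pipeline does. Second, $p$ is the *observed* mean
relative abundance, as in practice.

## Raup-Crick stochasticity

`raup_crick()` reduces samples to presence/absence and compares each
pair's observed shared-taxon count against a null in which two communities
of the observed richnesses are drawn without replacement from the
regional pool (all taxa of the table passed in; in the pipeline, the
site x tissue group pooled over seasons). Draws are weighted by
occurrence frequency by default — the null preserves which taxa are
common — with a uniform option for sensitivity analysis. Ties count at
half weight:

$$RCI = \frac{2\left(\#\{SS^* < SS\} + \tfrac12 \#\{SS^* = SS\}\right)}{n_{reps}} - 1 \in [-1, 1].$$

The default is 999 null replicates (9,999 in some published scripts; the
flag is exposed). Weighted sampling without replacement uses exponential
keys, with the same two null ensembles shared across the pairs of one
call — each pair's index remains marginally valid and the computation
stays quadratic rather than cubic. `stochastic_fraction()` reports the
proportion of (within-group) pairs with $|RCI| < 0.95$; the pipeline
groups pairs within season, matching a per-season presentation of
stochasticity. Abundance-weighted Raup-Crick and phylogenetic null models
are out of scope.

## Co-occurrence persistence networks

`spearman_test()` computes rho on average ranks with a two-sided p: exact
by full enumeration of the $n!$ rank permutations when $n \le 9$ and the
data are untied, t-approximation otherwise. `season_network()` screens
all taxon pairs of one site x tissue x season slice (five replicates) and
keeps $|\rho| > 0.8,\ p < 0.01$. The gate deserves a frank note: at
$n = 5$ the exact two-sided p can never be below $2/120 \approx 0.017$,
so with exact p-values the 0.01 gate would keep nothing. The screen
therefore uses the t-approximation by default — the behaviour `cor.test`
falls back to on tied count data — under which $|\rho| = 1$ yields
$p \to 0$ and the gate is operative; an `exact` mode is provided. The
practical consequence is that five-replicate networks contain essentially
only perfect monotone associations, including chance ones at the
enumeration rate of $2/120$ per untied pair, which the test suite checks
explicitly.

`combine_networks()` keeps edges present in at least two of the four
seasonal networks. Edge identity includes the correlation sign by default:
a positive and a negative association between the same two taxa are
biologically different relationships (a flag relaxes this).
`network_properties()` reports the node/edge counts, edge density with
the ordered-pair denominator $E/(V(V-1))$ — the convention locked in by a
regression test against published node/edge/density triples — global
transitivity, diameter (longest finite shortest path), and Freeman
centralisation of closeness (reachable pairs only, on disconnected
graphs), eigenvector centrality and betweenness. Eigenvector scores come
from a dense symmetric eigendecomposition rather than an iterative solver
so that repeated runs are bit-identical. Structural dissimilarity between
networks is the Jaccard distance on edge-identity sets — the published
analyses cite an unidentifiable reference for this step, so the package
states its own definition; `ordinate_networks()` ordinates the resulting
matrix with NMDS. Networks are built per kingdom and per site x tissue;
cross-kingdom edges and module detection are out of scope.

## The synthetic study generator

`generate_study()` emulates the survey the analysis assumes: 2 sites x
2 tissues x 4 seasons x 5 replicates at depth 7,500, with a lognormal
regional pool of 400 taxa (sdlog 0.8) so that a few hundred taxa survive
the 0.001 filter, as in real amplicon tables of this kind. The neutral
backbone draws compositions from $\mathrm{Dirichlet}(Nm\,p)$ and counts
from a multinomial — exactly the beta approximation the estimator fits,
so parameter-recovery tests are internally consistent. The default
backbone `Nm = 50` gives the patchy occupancy regime in which replicate
communities are mostly stochastic by the Raup-Crick criterion (the regime
the analysis is designed to detect); seasonal pools drift by 10%
multiplicative lognormal jitter between consecutive seasons and each
site x tissue group carries a fixed 15% perturbation, so season and site
are present but not dominant factors.

Planted ground truth:

* *selected taxa* (6, pool abundance 0.0015-0.003): forced present in
  every sample at a floor of 5 reads — rare but filter-safe, and the
  floor keeps the planted presence from being erased by rarefaction;
* *dispersal-limited taxa* (6, pool abundance 0.03-0.06): zeroed in 60%
  of the replicates of every slice;
* *correlated pairs* (four spanning >= 2 seasons, two single-season):
  seasonal specialists with pool abundance 0.006 in their active seasons
  and effectively zero otherwise. In active seasons the pair's counts are
  rewritten as strictly monotone transforms of a shared latent sample
  ranking with a spacing of 15 reads between consecutive ranks, so
  $|\rho| = 1$ survives the mild thinning of a later rarefaction. In
  inactive seasons the taxa are absent, so their vectors have zero
  variance and are skipped by the correlation screen — transient
  associations cannot recur by chance, which is what makes "present in
  one season only" a decidable ground truth at five replicates.

Sample sums are renormalised to the exact depth after planting by
redistributing reads proportionally across non-planted taxa.

What the generator does **not** emulate: sequence-level error, taxonomy
mis-assignment, compositional correlations beyond the planted pairs,
phylogenetic signal in the pool, and tissue-specific taxon pools. Passing
tests therefore demonstrate that the estimators recover the signals the
model family can express, not that real endophyte data meet those
assumptions.

## Validation scale and numerical choices

The test suite exercises: exact worked examples for every closed-form
quantity; the published node/edge/density convention on all eight
published rows; neutral-model recovery over 50 simulations (true
$Nm = 500$, 300 taxa, 30 samples, depth $10^4$, within ±20%); type-I
error of both permutation tests over 1,000 null datasets at ±2 SE;
Raup-Crick behaviour over 100 forced-sharing runs and neutral replicate
groups; planted-signal recovery over 20 full synthetic studies; and the
exact Spearman null at $n = 5$. These problem sizes keep the whole suite
in a few minutes while leaving the Monte-Carlo bands meaningful.

Numerical conventions: seeds are explicit everywhere and per-stage seeds
are derived from the global seed and the stage name, so adding a stage
never perturbs another stage's stream; optimisation tolerances are
$10^{-8}$ on SSE; Wilson bands use $z = \Phi^{-1}(0.975)$; ties in
Spearman ranks use average ranks; empty graphs yield an all-zero property
record with a warning rather than NaNs.

## Known limitations

* The per-slice neutral-model fit at five replicates has low explanatory
  power (negative $R^2$ is common); its value lies in the deviation
  labels aggregated across seasons, not in the fit statistic.
* The t-approximation p-value at $n = 5$ makes the network gate an
  effectively exact-correlation screen; edges should be read as candidate
  persistent associations, not as significance-tested interactions.
* The occupancy-threshold detection model is biased for taxa near the
  detection limit; keep the standard low-abundance filter ahead of
  `fit_ncm()`.
* Raup-Crick values saturate at ±1 when samples nearly exhaust the
  regional pool; the index is informative only when per-sample richness
  is well below pool size.
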