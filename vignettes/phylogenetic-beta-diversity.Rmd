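---
title: "Measuring phylogenetic beta diversity and its link to functional turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetic beta diversity and its link to functional turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phybeta)
```

## The problem

Species beta diversity asks *whether* two communities differ in composition;
phylogenetic beta diversity asks *how deep in evolutionary time* those
differences lie.  Two plots may share no species at all, yet be composed of
sister species drawn pairwise from the same genera (terminal turnover), or of
entirely different major clades (basal turnover).  Distinguishing these
regimes is what makes phylogenetic metrics informative about community
assembly: habitat preferences that are conserved deep in a phylogeny produce
clade-level turnover along environmental gradients, while recent, labile
habitat shifts do not.

`phybeta` provides the eight most commonly used phylogenetic beta-diversity
metrics, the machinery to probe what part of a phylogeny each one responds
to, a trait-evolution laboratory for asking when phylogenetic turnover is a
usable proxy for functional turnover, and a synthetic community generator
for exercising all of it end to end.

## The metrics and the conventions fixed here

Throughout, a community is a set of tips of a rooted, branch-lengthed tree;
$d_{ij}$ is the patristic (branch-sum) distance between tips, and a branch
*belongs to* a community if at least one of its species descends through it.

* **PhyloSor** (similarity): $2 BL_{k_1 k_2} / (BL_{k_1} + BL_{k_2})$, where
  $BL_k$ is the total belonging branch length and $BL_{k_1 k_2}$ the total
  shared branch length.
* **UniFrac** (dissimilarity): branch length belonging to exactly one
  community divided by branch length belonging to at least one.  The
  metric is implemented in this branch-length-fraction form; it is the form
  that reproduces the published worked-example values (e.g. $14/15 = 0.9333$
  for sister four-species clades on the unit-branch 16-tip tree), and the
  package treats that reproduction as the defining constraint.
* **Dnn / Dnn'**: mean distance to the nearest neighbour in the other
  community.  Presence mode pools minima over both communities and divides
  by $n_1 + n_2$; abundance mode weights each minimum by the species'
  relative abundance within its own plot and halves the sum of the two
  community totals.  When the two plots share species, those species
  contribute a distance of zero; they are not excluded.
* **Dpw / Dpw'**: mean pairwise distance over all $n_1 n_2$ cross-community
  pairs; abundance mode is $\sum_i \sum_j f_i f_j d_{ij}$ with relative
  abundances within each plot.  Presence mode is exactly the equal-abundance
  special case ($f_i = 1/n$), a convention used consistently for every
  abundance-capable metric here.
* **Rao's D**: $\tfrac12 \sum_i \sum_j f_i f_j d_{ij}$ across plots — exactly
  half of Dpw', which is why the two are perfectly collinear across plot
  pairs and carry identical correlation structure.  The factor one half, and
  the inclusion of self pairs ($d_{ii} = 0$) in the within-plot terms below,
  are pinned by the worked example (basal scenario: $D = 4$, $H = 2.75$).
* **Rao's H**: $D_{12} - (D_{11} + D_{22})/2$, the cross-plot quadratic
  entropy corrected for the two plots' alpha diversity.
* **Jaccard** and **Bray–Curtis** are computed by `vegan::vegdist` and serve
  as the species-level baselines.

PhyloSor is the only similarity-oriented output; everything downstream
(`metric_orientation()`, the PCA's $1 - s$ conversion) keys off that
registry rather than guessing from values.

## Probing depth: the lambda transformation

`lambda_transform()` rescales every internal node's height (distance from
the root) by $\lambda \in [0, 1]$ while pinning tips at the original depth
$T$.  At $\lambda = 1$ the tree is untouched; as $\lambda \to 0$ it
approaches a star phylogeny on which all species are equally related, every
cross-pair patristic distance approaches $2T$, and the phylogenetic metrics
collapse onto their species-level analogues (PhyloSor onto Sorensen's index
exactly — an invariant the test suite asserts).  The transformation is
defined only for ultrametric trees (checked at a relative tolerance of
$10^{-9}$) and refuses other input rather than approximating.

`fig1_fixture()` carries the 16-tip unit-branch tree and four community
pairs — basal turnover between opposite root halves (A) or sister clades
(B), and terminal cherry-mate turnover across both halves (C) or within one
half (D).  `scenario_metric_table()` evaluates all six presence-weighted
metrics over $\lambda \in \{1, 0.75, 0.5, 0.25, 0.001\}$; the acceptance
tests compare all 120 cells against the published table.

```{r}
head(scenario_metric_table(lambdas = c(1, 0.5)), 12)
```

## Polytomies

Supertree-style phylogenies are rarely fully resolved, and branch-sharing
metrics are sensitive to resolution.  `resolve_polytomies()` replaces each
multifurcation with a binary expansion drawn uniformly from all rooted
binary shapes on its children (by sequential edge addition, so each of the
$(2k-3)!!$ shapes is equally likely — verified against a chi-square oracle
over the 15 shapes of a four-way polytomy).  Inserted branches get length
zero: total tree length and all patristic distances are conserved, so
`resolution_ci()` intervals isolate the branch-sharing metrics' sensitivity
— the distance-based metrics are provably invariant and their replicate
spread is asserted to be zero.

## Traits, signal, and functional turnover

`simulate_ou()` evolves a trait root-to-tips with the exact
Ornstein–Uhlenbeck transition (child mean
$x e^{-\alpha t} + \theta(1 - e^{-\alpha t})$, variance
$\sigma^2 (1 - e^{-2\alpha t}) / 2\alpha$), starting the root at the optimum
$\theta$.  Defaults follow the study design this package operationalizes:
$\alpha$ spanning $0.2$–$0.99$, $\theta = 0$, $\sigma = 0.1$.  Drift
without constraint is a separate sampler (`simulate_bm()`), not a
small-$\alpha$ limit.

`blomberg_k()` measures phylogenetic signal as the observed-to-expected
ratio of mean squared errors under the tree's Brownian covariance $V$
(GLS-estimated mean).  $K = 1$ exactly on a star tree for any trait vector;
Brownian traits on their generating tree give $K$ centred on 1 (asserted
over 500 replicates on a 64-tip tree).

`trait_dendrogram()` clusters species on absolute trait differences
(UPGMA by default; complete and single linkage available) and returns the
dendrogram as an ultrametric `phylo` with tip depth equal to half the merge
height, so cophenetic distance equals merge height and every beta metric
applies unchanged to functional turnover.

`signal_sweep()` ties it together: it simulates `oversample` times the
requested number of OU trait datasets across the $\alpha$ grid, measures
$K$ for each, and keeps `n_datasets` of them spread evenly across the
realized $K$ range (one per quantile bin of the $K$ order statistics — the
stated goal is maximizing the spread of $K$; the binning procedure is this
package's concrete choice).  For each retained dataset it computes
functional beta diversity from the trait dendrogram and reports the $R^2$
of functional on phylogenetic beta per metric.  The headline property —
asserted, not assumed — is that for the terminal metrics (PhyloSor,
UniFrac, Dnn, Dnn') the Spearman correlation between $K$ and $R^2$ is
positive: more signal, better functional recovery.

## Mantel tests, correlations, PCA

`mantel_test()` correlates lower triangles and permutes rows and columns of
the second matrix simultaneously, with the add-one correction
$p = (1 + \#\{r_\mathrm{perm} \ge r_\mathrm{obs}\})/(1 + n_\mathrm{perm})$,
so the smallest attainable $p$ is $1/(1+n_\mathrm{perm})$.  The default is
999 permutations and the one-sided "greater" alternative; a two-sided
alternative is available.  The implementation is a plain permutation loop
so that sidedness and seeding are fully caller-controlled;
`vegan::mantel` is used as an independent cross-check in the test suite,
which also verifies the permutation null exhaustively on $4 \times 4$ cases
and the test's type-I error on independent random matrices.

`metric_correlations()` and `pca_metrics()` summarize metric redundancy.
The PCA z-scores each metric vector (a correlation-matrix PCA — the metrics
have incommensurate scales), converts the $[0,1]$-bounded similarity
(PhyloSor) to a dissimilarity as $1 - s$ first, and flips each component's
sign so its largest-magnitude loading is negative (component signs being
arbitrary, this is purely cosmetic).

## The synthetic gradient world

`simulate_gradient()` stands in for the kind of data that motivates these
analyses: a network of forest plots along a steep rainfall gradient.  Its
defaults are the study conditions the package is benchmarked under — 96
plots, 446 species, 61,965 individuals, latitude 13.2–15.2°, altitude
55–1060 m, annual rainfall 776–8340 mm.

* The phylogeny is a coalescent tree normalized to unit depth
  (`tree_age = 1`).  With the default OU grid this yields realized
  Blomberg's $K$ spanning well over the five-fold range the signal sweep
  requires; this was checked across tree ages 1–8 before freezing the
  default, and the smallest was kept.
* Each species' rainfall optimum is a Brownian tip value mapped affinely
  onto the rainfall range, so habitat preference is phylogenetically
  conserved; `mode = "labile"` shuffles the same optima across species,
  destroying that structure while keeping the species-level gradient.
* Plots sit evenly spaced on a constant-longitude latitude transect.
  Rainfall rises monotonically as a gentle linear ramp (35% of the range)
  plus one sharp escarpment step (65%) at a random crest position in the
  middle third of the transect — the signature of orographic rainfall on
  mountain gradients, where a crest separates a dry leeward from a wet
  windward side.  The step matters statistically: if rainfall were an
  affine function of latitude, rainfall difference and geographic distance
  would be the same Mantel predictor up to scale and the conserved-niche
  contrast (environment beats space) would be unmeasurable by construction.
  An earlier geometric (log-linear) ramp was tried and discarded: community
  turnover saturates across the wide top-end rainfall gaps it creates,
  which can hand the advantage to geographic distance whenever the clades
  happen to segregate at the dry end.
* Abundances are multinomial draws per plot with weights
  $\exp(-(p_k - o_i)^2 / 2\beta^2)$, $\beta$ = `niche_breadth` = 600 mm;
  per-plot totals divide the individual target exactly, so the realized
  total always matches it.  Altitude is drawn independently of assembly and
  is therefore a negative control in Mantel analyses.

What the generator does **not** emulate: dispersal limitation and spatial
autocorrelation beyond the shared gradient, detection error, rarefaction
effects, multi-trait niches, speciation/extinction realism, or non-monotone
rainfall fields.  Tests passing on these worlds show the metrics and the
machinery behave as designed under niche-driven assembly; they do not show
that any particular empirical system behaves this way.

## Numerical choices and degenerate inputs

* Ultrametricity: relative tolerance $10^{-9}$ on root-to-tip depths.
* Branch lengths are attached to child nodes; the root carries none.
  Missing newick branch lengths default to 1.
* Zero-length branches (from resolution or $\lambda = 0$) are legal
  everywhere; branch-belonging is set membership, not length-weighted.
* Empty plots are rejected at validation; species present in a table but
  absent from the paired tree are a hard error rather than being dropped.
* `hclust` breaks distance ties by its internal ordering; trait vectors
  with duplicated values therefore have a deterministic but
  convention-dependent dendrogram.
* All stochastic functions take a `seed` argument and restore the caller's
  RNG state, so seeded pipelines compose.

## Problem sizes used by the test suite

The acceptance tests run the signal sweep on a reduced world of 24 plots
and 64 species (60 trait datasets), the Mantel ordering contrast on 50
worlds of 16 plots and 48 species, oracle equivalence on 200 random
instances of up to 8 tips, and the Brownian $K$ calibration on 500
replicates over 64 tips.  These sizes were chosen as the smallest at which
the corresponding properties are comfortably away from their thresholds;
the full-size defaults (96 × 446) run in seconds and are exercised once in
the unit tests.

## Known limitations

* Rao's H can be negative on non-ultrametric trees; it is reported as-is.
* The lambda transformation requires ultrametry; there is no fallback for
  additive trees.
* `signal_sweep()` regresses per-pair metric values; it does not attempt
  standardized effect sizes or null models (out of scope here, as are
  weighted-UniFrac variants and alpha-diversity statistics).
* Mantel tests are plain (no partial Mantel), and significance across many
  metric-by-environment combinations is left uncorrected; the package
  reports raw $r$ and $p$.
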