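---
title: "Quantifying ontogenetic and evolutionary limb allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ontogenetic and evolutionary limb allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloaxis)
```

## The scientific question

Adaptive radiations often diversify along conserved directions of trait
covariation. One candidate explanation is developmental: if the bones of a
limb grow along a common multivariate trajectory within species, selection
may find it easiest to move adult morphology along that same trajectory —
a "developmental line of least resistance". `alloaxis` implements the
statistical machinery needed to test this idea on limb skeletons: it
estimates the major axis of covariation of log bone lengths within species
(ontogenetic allometry), the major axis across species means on a
phylogeny (evolutionary allometry), and asks whether the two are aligned.

Two datasets enter the analysis. An *ontogenetic* table holds embryo and
hatchling specimens of a modest number of species, with six forelimb
elements (humerus, ulna, metacarpal and three phalanges of the longest
digit), seven hindlimb elements (femur, tibia, metatarsus, four
phalanges), and spine length — the cervical-to-sacral vertebral distance —
as the body-size proxy. An *evolutionary* table holds adult bone lengths
for hundreds of species together with the centroid size of the pelvic
girdle as the size proxy, reduced to species means, plus a rooted
ultrametric phylogeny and a map of species to major biogeographic groups
(Antillean, Primary Mainland, Secondary Mainland).

## The model and its estimators

All analyses work on natural-log lengths. Logs make growth multiplicative
effects additive; the base cancels in every angle statistic because
loading vectors are normalized to unit length.

**Allometric vectors.** For a data matrix $X$ (observations $\times$ $p$
elements) the allometric vector is the first principal component of the
column-centered matrix, computed by singular value decomposition,
normalized and oriented so its coefficient sum is positive (all bones
grow, so the biological axis has positive loadings; the convention makes
angles well defined). Under multivariate isometry every coefficient
equals $p^{-1/2}$ ($\approx 0.408$ at $p = 6$, $0.378$ at $p = 7$);
coefficients above that value mark positive allometry of an element.

**Angles.** Two unit vectors are compared through
$\Theta = \arccos(v_1 \cdot v_2)$, reported in degrees. Angles are
invariant to adding a constant to every log measurement and to row order.

**Common (pooled) axis, cPC1.** Each species' matrix is centered at its
own mean before pooling, so between-species differences in size and shape
do not contaminate the shared within-species axis.

**Phylogenetic PCA.** For species means $X$ on a tree with Brownian
covariance $C$ (shared root-to-ancestor path lengths), the mean is the
generalized-least-squares root estimate
$a = (1'C^{-1}1)^{-1}1'C^{-1}X$ and the evolutionary covariance is
$R = (X-1a)'C^{-1}(X-1a)/(n-1)$, eigen-decomposed in covariance mode
(all variables are same-unit log lengths; a correlation-mode PCA would
discard exactly the size information the allometric reading depends on).
Species scores are projections of $X - 1a$ on the eigenvectors. The
sensitivity variant replaces $C$ with the identity. On a star tree with
equal branch lengths the two coincide — the keystone equivalence the test
suite checks to $10^{-10}$.

## Bootstrap constructions

Three resampling tests are built in; each takes an explicit seed and
$B \ge 100$ iterations ($B = 1000$ by default).

**Isometry.** Rows are resampled with replacement, the oriented PC1
recomputed, and per-element percentile 95% intervals compared with
$p^{-1/2}$. Percentile intervals (rather than BCa) keep the procedure
transparent; the suite verifies a ~5% per-element false-positive rate
under isometric truth.

**Shared-allometry null for pairwise angles.** To ask whether two species'
axes differ more than sampling noise allows, we need data that truly share
one axis. `conformingDataset()` builds them: each species' centered rows
are split into the score on the common axis cPC1 and the residual about
the species' own PC1; the residual is transported into the orthogonal
complement of cPC1 by the minimal rotation carrying the species axis onto
cPC1. The transport is a rotation, so every specimen's off-axis residual
norm — the species' noise magnitude — is preserved, while the species'
major axis becomes exactly cPC1. Specimens are then resampled within
species and all pairwise angles recomputed, giving each pair its own null;
an observed angle above the 95% quantile flags a deviant pair. The exact
recipe behind published analyses of this kind is usually relegated to
supplements; ours is isolated in one exported function precisely so it can
be swapped for an alternative construction without touching the test
logic.

**Alignment null from rotated datasets.** The headline test compares cPC1
with a group's pPC1. Under the null of perfect alignment the evolutionary
deviations from the GLS mean are rotated by the minimal rotation (a plane
rotation, identity on the orthogonal complement) carrying pPC1 exactly
onto cPC1. The rotation is applied to the evolutionary side because
species means are fewer and cheaper to re-estimate per iterate; either
choice forces alignment. Each iterate then re-estimates both axes from
resampled data and records their angle; the observed angle is compared
with the one-sided 95% quantile, matching the usual reading of a null
histogram with a marked confidence bound.

**Resampling units.** Within the ontogenetic data the exchangeable unit is
the specimen, resampled within species. On the evolutionary side species
are *not* exchangeable — they are correlated through shared branches — and
a naive species bootstrap has a second defect: duplicate tips cannot exist
on a tree, and collapsing duplicates turns the bootstrap into an
m-out-of-n subsample without replacement ($m \approx 0.632\,n$), which
understates the sampling variance of the axis by the finite-population
factor ($\approx 0.77$) and makes the alignment test reject aligned worlds
far too often (we measured ~16% instead of 5%). `alloaxis` therefore
resamples the *phylogenetically whitened* deviations: rows of
$L^{-1}(X - 1a)$, with $LL' = C$, are i.i.d. under the Brownian model, are
resampled with multiplicities, re-coloured through $L$, and the PCA
re-fit on the unchanged tree. On a star tree this reduces to an ordinary
residual bootstrap. The measured acceptance rate of truly aligned worlds
is ~95-97%, and a 25° misalignment at low noise is rejected essentially
always.

## Missing-data imputation

Fractured bones leave a few percent of cells missing. They are completed
by iterative PCA on the log scale: missing cells start at column means, a
low-rank PCA of the completed matrix refills them from its reconstruction,
and the loop runs to a relative change below `tol` (default $10^{-6}$,
at most 500 sweeps per rank). Two refinements matter in practice. First,
signal eigenvalues are shrunk by the trailing-eigenvalue noise estimate
(regularized iterative PCA); without it the plain EM refill can drift
indefinitely at ontogenetic sample sizes (20-30 rows, rank 4 of 6
columns). Second, the rank is swept upward with warm starts (1, 2, ...,
up to `min(4, p-1)`): starting directly at the target rank can freeze at
the arbitrary initial fill whenever the filled matrix has rank $\le k$,
since the rank-$k$ reconstruction then reproduces it exactly. With both
refinements a noiseless rank-1 table is completed exactly (the shrinkage
vanishes when trailing eigenvalues are zero) and noisy tables converge in
a few hundred sweeps. Observed cells are never modified. Ontogenetic
tables default to per-species scope (covariation is species-specific);
adult tables, with two to three specimens per species, default to a
single global model.

## What the simulators emulate

`simulateOntogeny()` draws, for each specimen, a latent size $u$ uniform
on `growth_range` and sets the log element vector to
`intercepts + u * axis + noise`, with the species axis tilted from the
common vector by a fixed angle in a random plane. The defaults are the
study conditions the package is designed around: 15 species, 25
specimens per species spanning the stages at which cleared-and-stained
skeletons are measurable through hatching, ~3% missing cells,
residual noise of 0.05 log units, an ~8-fold elongation of each bone
(`growth_range = c(0, 5)` along a unit axis), and a total-limb-versus-
spine log-log slope of 1.3 — limbs outpacing the trunk, as positive
bivariate allometry implies. Spine length is generated from the same
latent size so that the slope is controlled; it is the bivariate
predictor, not part of the multivariate vector. `simulateTree()` draws
pure-birth trees rescaled to unit height, and `simulateEvolution()` runs
exact multivariate Brownian motion ($vec(X) \sim N(1 \otimes root,\,
C \otimes \Sigma)$), typically with a rank-1-dominant $\Sigma$ built by
`rank1Covariance()` to mimic the strongly size-dominated evolutionary
covariance of real limb data.

What the generator deliberately does *not* emulate: ecomorph clustering,
measurement-device error structure, stage-dependent noise, or
non-Brownian evolution (selection regimes, rate shifts). Passing
calibration on these synthetic worlds therefore shows the machinery is
correct and calibrated under its own assumptions — not that real limb
data satisfy those assumptions.

## Numerical choices and edge cases

- PC sign ties (coefficient sum exactly zero) fall back to the sign of
  the first nonzero coefficient; exactly antipodal axes have no unique
  minimal rotation and raise an error.
- A leading eigenvalue tie in a (p)PCA triggers a warning — the major
  axis is then not identifiable; ties further down the spectrum are
  common in rank-deficient bootstrap resamples and are ignored.
- Bootstrap resamples that collapse to zero variance (possible on tiny
  noiseless fixtures) fall back to the full-sample axis rather than
  aborting the run.
- Degenerate inputs error early with context: non-positive lengths on
  the linear scale, double log transforms, unmatched tree tips, singular
  phylogenetic covariances, fully missing element columns within an
  imputation scope.

## Problem sizes used by the validation suite

The test suite and the acceptance script validate calibration with
Monte-Carlo experiments sized as a compromise between binomial precision
and turnaround: 500 replicate datasets for the two 5% false-positive
checks (bootstraps of $B = 500$ inside each replicate) and 500 replicates
for the alignment self-consistency and power checks ($B = 200$ inside
each). The end-to-end pipeline check runs at the design scale of the
motivating study type: 374 ontogenetic specimens of 15 species, 693
adults collapsing to 267 species means on a 267-tip tree in three major
groups (121 + 29 + 107 species plus 10 outside them), $B = 1000$.

That study-scale world is built to be *coherent across its datasets*,
the way a real comparative study is: one latent body-size signal on the
tree drives both limbs' species means (Brownian, rank-1-dominant along
the growth axis, trace 1.2 per unit tree height, 94% of it on the
axis); the 15 ontogenetic species are tips of the same tree, with
anlage intercepts equal to their adult means shrunk down the shared
axis, so hatchling proportions anticipate adult proportions; and every
species carries a persistent relative-limb-length offset (a uniform
log offset of all limb elements, s.d. 0.15, not shared by the size
proxies). The offsets matter: they are evolution *off* the growth axis,
so the world reproduces the qualitative regime the method exists to
detect — a tightly shared ontogenetic allometry, hatchling-derived and
adult-derived evolutionary axes that are indistinguishable, a dominant
size axis tightly correlated with the size proxy, and an evolutionary
major axis that deviates measurably from the ontogenetic one.

## Known limitations

- The shared-allometry and alignment nulls are bootstrap approximations;
  they are first-order calibrated (the suite measures ~5% / ~95% rates)
  but carry the usual small-sample optimism of resampling tests.
- Phylogenetic machinery assumes Brownian motion on a fixed, known tree;
  topology or branch-length error is not propagated.
- The imputation model assumes cells are missing at random and that
  within-scope covariation is low rank; both hold for fracture-type
  missingness of strongly allometric measurements but not for, say,
  stage-dependent breakage.
- MANCOVA uses Pillai's trace with its approximate F; with very small
  within-species samples the multivariate tests are the first to lose
  validity, and the preconditions (more specimens than elements per
  species) are enforced rather than worked around.
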