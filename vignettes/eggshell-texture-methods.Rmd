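---
title: "Methods: surface metrology and phylogenetic comparative analysis of eggshell texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface metrology and phylogenetic comparative analysis of eggshell texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggtexture)
```

This vignette documents the models the package implements, the numerical
choices behind them, and the limits of what its synthetic-data tests can
show about real scan data.

## Height maps and texture parameters

A scan is a rectangular grid of surface heights in nanometres on a
regular pixel lattice (pitch in µm), with a per-pixel validity mask.
Optical profilometry of curved shell fragments loses pixels where the
surface is steep or out of focus, so missingness is a first-class part of
the data model: invalid pixels carry `NA` and never enter any sum.

The four areal parameters are plain moments of the valid-height
distribution about its mean: Sa (mean absolute deviation, nm), Sq (RMS
deviation, nm), Ssk (third standardized moment) and Sku (fourth
standardized moment). Two conventions had to be fixed:

* **1/n normalisation.** All moments use the population convention,
  which is the standard areal-parameter definition. Metrology software
  does not always document its choice; ours is recorded here and in the
  `texture_summary` object. At the pixel counts involved (tens of
  thousands and up) the 1/n vs 1/(n−1) difference is far below every
  tolerance used.
* **Degenerate surfaces.** A perfectly flat patch has Sq = 0 and no
  defined skewness or kurtosis; Sa and Sq are returned as 0 and
  Ssk/Sku as `NA` with a `degenerate` flag and a warning, rather than an
  error, because a rejected scan is data to be counted downstream.

Useful invariants, all tested: Sa ≤ Sq; Sku ≥ Ssk² + 1 (Pearson);
scaling heights by c > 0 scales Sa and Sq by c and leaves Ssk/Sku
unchanged; adding a constant changes nothing; mirroring the surface
negates Ssk only.

## Form correction

Shell fragments present an approximately spherical cap to the
objective, so a bivariate polynomial of total degree 2 (default) is
least-squares fitted to the valid pixels and subtracted, and the result
is shifted so the lowest valid height is exactly 0 nm. Numerical
choices:

* Pixel coordinates are centred and rescaled to [−1, 1]² before building
  the polynomial design. On a 768 × 576 grid a raw-coordinate
  Vandermonde matrix is catastrophically ill-conditioned; the rescaled
  design is benign and the fit is done by QR.
* The fit requires at least (order+1)(order+2)/2 valid pixels and a
  full-rank design; collinear valid pixels (e.g. a single surviving
  scan line) are a hard error, because the "corrected" surface would be
  an extrapolation artefact.
* Because subtraction of a fitted polynomial is a linear projection,
  adding a known quadratic trend to a field and correcting recovers the
  corrected trend-free field exactly (to floating point); this
  add-then-remove identity is one of the test oracles.

Texture on an uncorrected map is a warning, not an error: the parameters
are well defined, they just include form.

## Coverage QC and cropping

Scans with at least 40 % valid pixels pass unchanged. Below that, border
rows/columns whose own valid fraction is below the threshold are trimmed
iteratively, worst line first (ties resolve in the order top, bottom,
left, right), until every remaining border line meets the threshold.
This axis-aligned trimming matches how pixels are actually lost — at
edges and corners that fall outside the focal plane — and deliberately
avoids a general sub-rectangle search, which could salvage scan regions
whose quality a human inspector would reject. The crop is accepted only
if its coverage reaches the threshold *and* its area reaches `min_area`
(default 2500 px ≈ a 50 × 50 px evaluation area). Texture parameters are
scale-dependent, so arbitrarily small "clean" patches are not comparable
with full-field scans; the default is our choice of the smallest patch
worth keeping, and is configurable. Rejection is a report with a reason
(`low-coverage` or `too-small-after-crop`), never an exception.

## Repeatability, aggregation, and influence filtering

**Repeatability.** The intraclass correlation
R = σ²_b/(σ²_b + σ²_w) from the one-way random-effects model with
specimen as the grouping factor. Balanced designs use the closed-form
ANOVA estimator (negative between-group estimates truncated at 0);
unbalanced designs use REML via `lme4`. Confidence intervals come from a
parametric bootstrap (default 1000 replicates) that re-simulates from
the fitted Gaussian components — we implement only the Gaussian case,
since every response here is Gaussian after transform. Specimens with a
single scan are dropped with a warning; a dataset with zero variance is
defined to have R = 1 and flagged degenerate.

**Aggregation** is strictly two-stage — scans average to specimen means,
specimen means average to species means — never a pooled mean, so a
specimen with many scans cannot dominate its species.

**Cook's distance.** Influence is assessed per response on specimen
values under the intercept-only linear model over all specimens; no
regression design is canonical for this operation, and the
intercept-only model is the minimal choice that makes "influential"
mean "far from the consensus value". The cutoff defaults to the common
4/n rule and is configurable and logged — we treat it as a knob, not
ground truth. Species-level retention then applies exactly three rules:
single-specimen species lose a flagged specimen; multi-specimen species
with *all* specimens flagged retain all (the species is consistently
extreme rather than internally contaminated); otherwise only flagged
specimens are dropped. The filter is applied once per response, not
iterated to a fixed point — re-computing distances on the filtered set
would re-flag the new extremes of a clean sample. Filtering is
independent across responses: a specimen may be excluded for Sa and kept
for Ssk. Whether filtering should precede or follow scan→specimen
averaging is ambiguous in the source protocol; we filter specimen means,
which is the reading most consistent with "specimen values".

**Study table.** Species mean Sa and Sku are log10-transformed (their
cross-species distributions are right-skewed); Ssk is not. Non-positive
Sa or Sku is an error naming the species, and join losses between the
texture and trait tables are reported, never silent.

## Phylogenetic signal and PGLS

The Brownian covariance C has C(i,j) = shared root-to-MRCA path length
(via `ape::vcv.phylo`). Pagel's λ multiplies the off-diagonals only.
For fixed λ the likelihood profiles analytically: the GLS mean and the
mean squared Mahalanobis residual maximise the multivariate-normal
likelihood, leaving a 1-D problem in λ. We maximise with a 21-point grid
followed by `optimize()` on the bracketing interval (tolerance 1e-6),
then guard against the refinement landing below either boundary by
comparing with λ = 0 and λ = 1 directly. A 1001-point grid scan is the
test oracle for the optimizer. Likelihood-ratio statistics against
λ = 0 and λ = 1 are referred to χ²(1), the conventional construction;
both null values sit on the boundary of [0, 1], where χ²(1) is only an
approximation (the λ = 1 test's realised type-I error is checked by
simulation in the tests rather than assumed). ML rather than REML
likelihoods are used throughout, matching the LR-test construction. On a
star phylogeny the likelihood is constant in λ; the fit is flagged
`flat` instead of reporting a spurious estimate.

PGLS whitens the model with the Cholesky factor of C_λ and solves by
QR in whitened space; with an identity covariance every output
(coefficients, SEs, t, p, R²) equals OLS exactly, which is tested
without tolerance slack. R² is defined in whitened space against the
GLS intercept-only fit, since no other definition is canonical for GLS.
Rank-deficient designs error and name the aliased columns.

**Collinearity screen.** Pass 1 drops, while any cross-predictor pair of
indicator columns has |r| ≥ 0.75, the member of the worst pair with the
larger mean absolute correlation to everything else; pass 2 drops the
predictor with the highest generalized VIF until all are below 10.
Categorical predictors enter pass 1 as full indicator sets (within-
predictor correlations are ignored — they are structural) and pass 2 as
whole terms via the determinant-based GVIF, which reduces to 1/(1−R²)
for single columns. The coding of categorical predictors for screening
is not specified anywhere authoritative; indicators for the pairwise
rule plus GVIF for the whole-term rule is our choice, cross-checked
against `car::vif` in the tests.

## The phylogenetic mixed model

Individual-level values are modelled as
y = Xβ + Z a + Z b + e, with a ~ N(0, σ²_p A) (A = Brownian correlation
from the tree, depth-normalised so its maximum diagonal is 1 — variance
components are then comparable across trees), b ~ N(0, σ²_s I) the
non-phylogenetic species effect, and e ~ N(0, σ²_e I). The phylogenetic
correlation is fixed at λ = 1 inside the model; signal flexibility is
carried by the σ²_p/σ²_s split. All responses are Gaussian after
transform, so only the Gaussian family is implemented.

Every full conditional is conjugate, so the sampler is plain Gibbs:
multivariate-normal blocks for β, a and b; inverse-gamma draws for the
three variances. When every species contributes the same number of
individuals, Z'Z is a multiple of the identity and the a-block becomes
diagonal in the eigenbasis of A — the eigendecomposition is done once
and each sweep costs two matrix-vector products. Unbalanced designs take
a fresh Cholesky of the q × q precision each sweep. Both paths draw the
same number of random variates per sweep, so chains are deterministic
under the seed either way.

Priors default to N(0, 10⁸) on fixed effects and inverse-gamma(0.001,
0.001) on variances — weakly informative choices of the kind standard in
MCMC mixed-model software; they are configuration, not constants, and
the no-phylogeny agreement test (below) is one sensitivity check. The
default chain controls (80 000 iterations, 20 000 burn-in, thinning 500
in `run_config`) mirror a realistic production prediction run; tests use
shorter chains, noted below.

Reported summaries: posterior means; HPD intervals (shortest window of
⌈mass·n⌉ sorted draws; ties resolve to the leftmost window; an
all-windows enumeration is the test oracle); pMCMC = 2·min(Pr(>0),
Pr(<0)) floored at 1/n_draws; effective sample sizes from the initial
positive-autocorrelation estimator.

**Posterior prediction** evaluates the fixed-effects linear predictor
Xβ over a factorial grid (continuous predictors at 3 equally spaced
representative values spanning the observed range — min, midpoint, max —
crossed with all categorical levels, rows in lexicographic order), with
random effects marginalised at zero. Rows are processed in batches
(default 500) to bound memory; each row's posterior is an independent
matrix-vector product, so output is bitwise identical for any batch
size — an exact invariant, tested as such.

Correctness of the sampler is established three ways: exact seed
determinism; agreement of fixed-effect posteriors with `lme4::lmer` on
data generated with σ²_p = 0 (the nested-model oracle); and coverage of
the generating β by their own 95 % HPDs across 50 seeded refits.

## What the synthetic data does and does not emulate

`gen_height_map` composes a spherical-cap base form (default radius
20 mm, a realistic shell radius, giving ~2.5 µm of sag across the
default 636.61 × 477.25 µm field at 768 × 576 px), a correlated Gaussian
field (seeded white noise convolved with a separable Gaussian kernel of
sd = 3 px truncated at 4 correlation lengths, rescaled by the
theoretical kernel norm so the marginal sd is exact and the field stays
exactly Gaussian — convolution rather than spectral synthesis keeps the
result bit-reproducible across platforms), radial-cosine pore pits and
peaks (smooth, so they survive second-order form correction; depths
drawn per feature, counts Poisson in the stated density), and
edge-biased dropout (exactly the stated fraction of pixels, sampled with
probability decaying exponentially with distance to the nearest edge,
length scale 6 px). One integer seed expands into fixed per-component
substreams (predictors, species effects, scan noise offset by 0, 1, 2)
in the study simulator.

This reproduces the *statistical* structure the pipeline assumes —
curvature, spatially correlated noise, negative-skew porosity, edge
missingness, replicated scans nested in specimens nested in species with
λ-transformed Brownian species effects. It deliberately does not target
absolute empirical Sa ranges of real eggshells, instrument-specific
noise (speckle, fringe artefacts), spatially structured dirt, or the
foreground/background pigment dichotomy of maculated eggs. Passing tests
therefore demonstrate that the estimators recover known truth under the
assumed generative model, not that the model captures every property of
real scans. No public within-species variance estimates exist to
calibrate the specimen- and scan-level sds against, so the simulator
defaults (`sd_phylo` 1, `sd_species` 0.5, `sd_resid` 0.5) are chosen for
testability: each component is large enough to matter and none dominates.

## Problem sizes and tolerances used in the test-suite

Chosen as the smallest sizes at which each statistical check is stable:

* Gaussian-moment check: one full-field 768 × 576 surface; |Ssk| < 0.1,
  |Sku − 3| < 0.3 (a pilot Monte-Carlo of the estimator at this pixel
  count and correlation length puts the sampling sds near 0.05 and 0.1,
  so these are ~2 sd bands).
* Porosity sign: 100 seeded 144 × 192 surfaces at pore density 5 per
  1000 px²; ≥ 95 % negative Ssk.
* λ recovery: 200 replicates per true λ ∈ {0, 0.5, 1} on 200-tip Yule
  trees; mean λ̂ within ±0.1; LR power ≥ 0.9 under Brownian motion.
* Mixed-model recovery: 50 refits of 40 species × 3 individuals at
  20 000 iterations; pooled 95 % HPD coverage of the generating fixed
  effects ≥ 0.9.
* Exact checks (PGLS = OLS, Cook's closed form vs leave-one-out, HPD vs
  enumeration, batching invariance, seed determinism) use tolerances of
  1e-10 or exact identity.

## Known limitations

* Only the λ correlation structure is implemented for signal and PGLS —
  no Ornstein–Uhlenbeck, no Blomberg's K, no multi-trait signal.
* The mixed model is single-response Gaussian with exactly two variance
  components plus residual; no parameter expansion, no DIC.
* The repeatability module covers the Gaussian case only.
* The coverage/area test operationalises scan exclusion; the manual
  "extensive pixelation" judgement of a human inspector is not
  replicated by any texture heuristic.
* χ²(1) reference distributions for the λ tests are boundary
  approximations (see above).
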