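---
title: "Models and methods for testing Batesian mimicry in space and time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for testing Batesian mimicry in space and time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mimicry)
```

This vignette explains the statistical machinery of the package: the
spatial co-occurrence test between venomous models (coral snakes) and
their presumed Batesian mimics (red–black banded, "RBB", colubrids),
the phylogenetic model of gains and losses of the mimetic phenotype,
and the synthetic-data generators the package is validated against. It
also records the numerical and design choices a user of the results
should know about.

## 1. Ranges and rasters

Species ranges are built from occurrence points by a record-count rule:

* **≥ 5 records** — an alpha hull. The alpha complex (Delaunay
  triangles with circumradius ≤ α) is grown multiplicatively (×1.5 per
  iteration, starting from the mean nearest-neighbour distance among
  the points) until it is a single connected polygon containing at
  least 99% of the records, applied as a count `≥ ceiling(0.99 n)`
  with boundary points counting as contained. The published procedure
  states the stopping rule but not the growth schedule or starting
  value; both are therefore declared choices here, and only the
  contract (contiguity, ≥ 99% containment, smallest accepted alpha in
  the tested schedule) should be relied upon.
* **3–4 records** — the minimum convex hull. Record counts of exactly
  five are claimed by both published rules; the alpha hull takes
  precedence at n = 5.
* **1–2 records** — a union of disks of radius 0.5°, planar in degree
  space (the source convention is a degree-radius buffer, not a
  geodesic one).

Degenerate inputs degrade gracefully: collinear point sets cannot be
triangulated and fall back to buffering; an alpha search that exhausts
its iterations falls back to the convex hull; both fallbacks warn.

Geometry is represented internally as *mosaics*: lists of convex
polygons with disjoint interiors. Every area computation — clipping a
range to the coastline, the covered fraction of a grid cell — reduces
to convex–convex clipping of the pieces and is exact, not sampled.
Presence in a cell requires coverage of **at least half the cell area,
inclusive** (a range covering exactly 50% counts; coverage is compared
with a 1e-9 relative guard so exact-half geometries are not lost to
floating point). Cells are identified by their midpoints; cells whose
land coverage is below one half are treated as off-mainland and carry
no values. Specimen-count (abundance) rasters assign each record to
exactly one cell via half-open intervals [west, east) × [south, north),
and mimic:model abundance ratios use the pseudocount form
`log2((m + 1) / (c + 1))`.

## 2. The spatial co-occurrence test

The question is whether coral-snake richness predicts mimic richness
beyond the general richness gradient. Three devices address the
non-independence of grid cells:

1. **SAR error regression.** `fit_sar_error()` fits
   `y = Xβ + u, u = λWu + ε` by maximum likelihood, profiling β and σ²
   out and optimizing the concentrated likelihood of λ over its stable
   interval (computed from the eigenvalues of W; the row-standardized
   W built from a symmetric proximity matrix has real spectrum).
   Coefficient z-tests use the GLS covariance at the ML λ; the
   standard error of λ comes from the curvature of its profile
   likelihood; AIC counts k = p + 2 parameters (coefficients, λ, σ²).
   Neighbour weights are built from great-circle distances (haversine,
   spherical Earth R = 6371 km — the metric is not stated in the
   source and is declared here), with binary, distance or
   inverse-distance weighting, always row-standardized (also a
   declared choice). `select_neighborhood()` scans radii in 50-km
   steps from the smallest radius at which no cell is isolated and
   picks the (radius, weighting) pair with minimal AIC.
2. **Moran's I** of the model residuals, with a permutation p value,
   checks that the SAR term removed the residual autocorrelation.
3. **The permutation null.** `permutation_test()` shuffles the
   species-identity tags of all non-model polygons (without
   replacement) and rebuilds the richness rasters. Because polygons
   never move, every iteration preserves the range distributions, the
   per-cell totals and the model raster *exactly* — the test suite
   asserts these identities rather than trusting them. Null-iteration
   regressions are ordinary least squares (the SAR model is reserved
   for the primary fit), the additive model `mimic ~ model + total` is
   the default (an interaction term is supported but off by default),
   and the one-tailed p is the fraction of null slopes ≥ the observed
   slope. A p of zero is reported alongside the (b+1)/(n+1) upper
   bound so "P < 0.001" at 1,000 iterations can be cited. The cell
   subset entering the regression (cells with ≥ 1 model by default, or
   ≥ 1 mimic in the observed data) is fixed across iterations.

Per-cell standardized residuals use the chi-squared-framework form
`z = (f − f̄)/√f̄` with `f̄` the null mean; the exact published formula
is not legible in the source, so the alternative standardization by
the null standard deviation is also implemented
(`denominator = "sd"`), with `√f̄` the default.

## 3. The Mk partition model of colour evolution

RBB coloration is a binary character (0 cryptic, 1 RBB); species
polymorphic for RBB components are coded 1, since the trait analysed
is *presence* of the banded signal (the source does not state its
coding; this is a declared choice). Evolution follows a two-state
continuous-time Markov chain with gain rate q01 and loss rate q10 per
Myr; `P(t)` has the closed form `Π + (I − Π)e^{−(q01+q10)t}` and the
likelihood is computed by Felsenstein pruning (compiled, with
underflow rescaling). The root is combined either with the stationary
frequencies of the root partition's matrix (default) or a fixed prior
on the RBB state (0.05 in the motivating analysis).

**Rate partitions.** A partition model attaches one rate matrix to
every branch: a shift declared at a node governs that node's stem
branch and its whole subtree, and nested shifts override outer ones on
their own subtrees. `stepwise_partition_search()` starts from one
matrix and greedily adds shifts: every internal node with ≥ 5
descendant tips is screened (the new matrix's two rates optimized, all
existing rates held fixed, one optimizer start seeded from the current
fit), the best candidate is then jointly re-optimized over all rates
(three starts), and the shift is kept only if AIC improves by more
than 2, with k = 2m + (m − 1). The joint refit at acceptance avoids
path-dependence in the rate estimates while keeping shift locations
greedy; rates are optimized in log space with bounds [1e−8, 1e3]/Myr.

**A caution on calibration.** Under homogeneous (one-matrix)
simulation on 300-tip trees, this search — implemented exactly as
specified — retains the one-matrix model in only about 30–50% of
replicates at rare-trait rates (q01 = 0.01, q10 = 0.025), and about
70% even under fast symmetric rates. The false positives are genuine
properties of the procedure, not optimizer artifacts (the likelihoods
agree with an independent Mk implementation to four decimals): under
slow rates, chance clustering of states in large clades mimics rate
heterogeneity, and in all regimes the acceptance rule takes a maximum
over ~100 correlated candidate improvements but penalizes only one.
This mirrors the documented false-discovery behaviour of greedy
stepwise-AIC shift searches for diversification rates. Accepted shifts
should therefore be read as descriptive model improvements, not as
calibrated hypothesis tests; the planted-shift *recovery* side is
well behaved (a 60-tip clade with 10× rates is found at or near its
true root in ≳ 85% of simulations).

**Parsimony cross-check.** `fitch_parsimony()` computes the minimal
change count by the unit-cost dynamic program (equivalent to Fitch on
binary trees, exact on polytomies) with a deterministic tie-breaking
resolution; it lower-bounds the number of events in any history
consistent with the tips.

## 4. Bayesian rates and stochastic mapping

With the partition locations fixed (a hybrid ML-location /
Bayesian-rate design), `mcmc_rates()` samples the 2m log rates by
Metropolis–Hastings with per-parameter Gaussian proposals adapted
during a 25% burn-in toward 20–40% acceptance, under independent
exponential priors whose mean is 10× the whole-tree symmetric ML rate.
Stored samples are thinned to at most 5,000; effective sample sizes
use the initial-positive-sequence autocorrelation estimator, with a
warning (not an error) below 100. Prior-only mode (likelihood switched
off) exists purely so the sampler can be validated against its target.

`sample_stochastic_map()` draws complete histories: the root state
from prior × root conditionals, node states top-down in proportion to
`P(t)` × downpass conditionals, and branch paths conditional on both
endpoints by **uniformization** — exact endpoint-conditioned CTMC
sampling that remains robust when endpoints differ and rates are small
(a rejection sampler would stall there). Ensembles (default 500 maps,
each from a fresh posterior rate draw) are summarized by
`summarize_ensemble()`: the frequency of the RBB state among extant
lineages at 1,000 equally spaced times (a deterministic function of
time, so refining the grid never changes values at shared times),
per-branch mean gain/loss counts, and a maximum-credibility map. The
published "maximum credibility" configuration comes from an external
toolkit and is under-specified; here it is the sampled map maximizing
the sum over branches of the log marginal frequency of that branch's
(gain, loss) count pair — a declared scoring rule.

## 5. Gains and losses in latitude and time

Ancestral latitudinal midpoints are reconstructed under **single-rate
Brownian motion** by generalized least squares: the internal node
values minimize the sum of squared changes per unit branch length, a
sparse harmonic system solved exactly; σ² is the REML estimate (mean
squared standardized contrast). The motivating analysis used a
multi-rate BM from an external program; single-rate GLS is a declared
divergence (an optional per-clade σ² map exists in the generator so
the approximation can be stress-tested). Zero-length branches are
floored at 1e−8 Myr.

An event at fractional position δ along a branch is placed at
`δ·s_child + (1 − δ)·s_parent` — the convention that uniquely
reconciles the published formula with both its printed anchors
(δ = 0.5 is the branch midpoint; δ = 0.1 lies 10% of the way from the
parent). The published definition labels the endpoints ambiguously;
this identification is the only self-consistent one. Event ages are
measured from the maximum node depth (so tips of an ultrametric tree
are at age 0). Gain/loss positions feed Gaussian kernel densities
(Silverman's bandwidth by default), time × latitude grids in which
both event types are scaled by their joint maximum (so the hotter of
gains/losses peaks at exactly 1), and the tropical-to-north-temperate
loss ratio with zones [−23°, 23°] (closed) and (23°, 35°] (half-open,
no double counting); a zero temperate count flags the ratio undefined
rather than erroring.

Latitudinal conservatism is tested by `pic_conservatism()`: the
variance of phylogenetic independent contrasts of tip latitudes is
compared with its distribution under random permutation of the tip
values; conserved latitudes give an observed variance far below the
null (negative z, small one-tailed p). Polytomies are resolved
arbitrarily with zero-length branches (warned); the two-tip case is
flagged degenerate. By default event interpolation uses the
posterior-GLS node estimates (point values); a per-draw mode would
propagate reconstruction uncertainty but is out of scope.

## 6. The synthetic-data generators

Every generator takes an explicit seed and is bit-reproducible; no
global RNG state leaks.

* `simulate_yule_tree()` — pure-birth trees with exponential waiting
  times, extended past the n-th birth by one further waiting time so
  pendant branches are positive. The empirical analyses use a fixed
  dated phylogeny, so any time-scaled tree source is acceptable
  plumbing; Yule is the minimal one.
* `simulate_discrete_history()` — exact forward simulation of the
  partitioned Mk process (exponential waits per branch segment),
  returning both tip states and the full true history in the same
  `character_map` container the stochastic mapper emits, so the two
  can be compared like for like.
* `simulate_bm_latitude()` — Brownian increments per branch with true
  internal values retained for recovery tests; optional per-clade σ².
* `simulate_virtual_biogeography()` — a convex rectangular continent
  (70° × 70°, roughly the New World's tropical-to-temperate span)
  tiled into 10° regions. Model and "other" species get clumped
  ranges (buffered random walks clipped to the continent — contiguous
  like real ranges, with no habitat model behind them). Mimic counts
  per region are Poisson with mean `a + b_model·model_r +
  c_other·other_r`, where richness is the ≥ 50%-coverage count at
  region resolution, and each seeded mimic occupies most of its
  region — so the planted slope is exactly the estimand of a richness
  regression at region scale (`fit_richness_lm()` regresses mimic on
  model and other richness; regressing on a total that includes the
  mimics themselves would be endogenous). The default fauna (14
  models, 100 others, ~35 mimics, b_model = 1, ~25 records per
  species) mirrors the composition of the real data, where mimics are
  roughly an eighth of the fauna — with mimic-dominated faunas the
  paper-style `mimic ~ model + total` regression loses its meaning.
  When both couplings are zero there is nothing to plant and mimics
  are generated as plain clumps, exchangeable with "other" ranges;
  this makes the permutation test's type-I calibration exact. The
  planting is at the level of regional species pools, not individual
  cells; recovery tests at region resolution are exact, finer
  resolutions are approximations.

What the generators deliberately do **not** emulate: real coastline
geometry, habitat- or climate-driven range placement, taxonomic error,
spatial sampling bias in occurrence records, extinction, and multgain
polymorphism dynamics. Passing the validation suite therefore shows
the *machinery* is correct and calibrated under clean conditions, not
that the empirical conclusions are robust to those real-data
complications.

## 7. Problem sizes and tolerances used in validation

The validation suite runs at desk scale, chosen to make the
statistical checks sharp while keeping the whole suite in minutes:
pruning vs enumeration on 200 trees of ≤ 5 tips (1e−10), closed-form
`P(t)` vs matrix exponential (1e−12), 20 homogeneous and 20
planted-shift searches on 300-tip trees, prior-recovery at 100k MCMC
steps (5%), credible-interval coverage on 20 500-tip data sets,
endpoint-conditioned event counts vs numerical integration (3
Monte-Carlo SEs at 10,000 draws), permutation type-I over 100
null-coupling continents at 199 iterations, and planted-slope CI
coverage over 20 continents. Monte-Carlo assertions use 3-SE bands
throughout; geometric identities are exact to 1e−12.
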