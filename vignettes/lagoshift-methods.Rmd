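---
title: "Methods: dispersal-constrained bioclimatic envelope modelling and trait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersal-constrained bioclimatic envelope modelling and trait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lagoshift` implements an end-to-end workflow for projecting species
bioclimatic envelopes under changed climates and relating the projected
changes to species traits:

1. occurrence quality control (taxonomy, range-polygon screening, a 2 km
   spatial-resolution cut, pre-/post-1950 period assignment, grid-cell
   deduplication);
2. period-matched samples-with-data (SWD) extraction from co-registered
   climate stacks;
3. temporally stratified target-group background sampling;
4. presence-background suitability modelling with linear, quadratic and
   product features under bootstrap or cross-validation replication;
5. threshold-dependent evaluation (Cohen's kappa, TSS, sensitivity,
   specificity, omission, proportion correct, rank AUC) and a joint
   expert-rating and kappa gate;
6. geographic post-processing: land-class masking, minimum convex polygon
   (MCP) dispersal buffers, and clipping of current and future predictions;
7. per-period range metrics and between-period change summaries;
8. comparative statistics: GLS temporal trends with AR(1) errors, and
   phylogenetic generalized least squares (PGLS) with Pagel's lambda,
   AICc all-subsets ranking and model averaging.

A synthetic-data module generates every input with known ground truth, so
each stage can be validated against simulation rather than against
unobtainable field data.

# The suitability model

The estimator is the background-normalized exponential (Gibbs) model, the
mathematical core of maximum-entropy presence-background modelling. Let
$z(x)$ be the feature vector at location $x$ (all linear terms, then all
quadratic terms, then pairwise products, each scaled into $[0,1]$ by its
training range). The model places probability mass

$$P(x) = \frac{e^{\beta^\top z(x)}}{\sum_{x' \in B} e^{\beta^\top z(x')}}$$

on each training background cell $x' \in B$, and $\hat\beta$ maximizes the
penalized presence log-likelihood

$$\sum_{i \in \text{presences}} \log P(x_i) \;-\; \sum_k \lambda_k |\beta_k|.$$

At the optimum, the model's background-expected value of each feature
matches the presence mean to within $\lambda_k$ — the standard
regularization interpretation. Per-feature penalties are
$\lambda_k = \beta_{\mathrm{reg}} \, m_c(n) \, s_k / \sqrt{n}$ with $n$ the
presence count, $s_k$ the presence standard deviation of the scaled
feature, and $m_c(n)$ a per-feature-class multiplier interpolated from the
published defaults of the reference presence-background program (linear:
1.0/0.2/0.05 at n = 10/30/100; quadratic and product classes analogously).
$\beta_{\mathrm{reg}} = 1$ by default.

Optimization is proximal gradient (FISTA with backtracking and restart) on
the smooth part plus soft-thresholding; convergence is declared when the
infinity norm of the L1 stationarity residual falls below `tol` (default
1e-6). The test suite verifies the solution against an independent
generic-optimizer route: the split parameterization
$\beta = p - q,\; p, q \ge 0$ makes the same objective smooth and
box-constrained, solved by L-BFGS-B; agreement is required to
$|\Delta\beta| < 10^{-3}$.

The reported suitability is the cloglog transform
$1 - \exp(-e^{H}\,\mathrm{raw})$, with $H$ the entropy of the fitted
background distribution (the modern default output; `type = "raw"` gives
the density itself, which sums to 1 over the training background).

**Feature clamping.** During projection, features are clamped into the
training $[0,1]$ range — the standard extrapolation guard. Clamping has a
known failure mode worth understanding: if the training background spans
only a narrow climate range, everything beyond that range is clamped to the
boundary and inherits the boundary's suitability. Target-group backgrounds
drawn from few, climatically similar species can trigger this when maps are
projected over a much wider domain. The recovery experiments therefore use
backgrounds that span the projection domain; with the full multi-species
world the target-group background does span it.

# Replication and evaluation

Species with fewer than 30 records are replicated by 10 bootstrap
resamples of the presences (out-of-bag rows held out); species with 30 or
more records by 4-fold cross-validation stratified by period (about 8
points per test fold, the accepted minimum). Below 8 records a species is
flagged unmodellable-by-data and never fitted.

Binary maps come from the 10-percentile training presence threshold: the
suitability below which the lowest 10% of training presences fall, computed
with the lower-interpolation (type 1) percentile convention (deterministic,
and exactly one training presence at or below the cut for n = 10).

Confusion metrics treat background points as absences. Kappa corrects the
proportion of correct predictions for chance agreement computed from the
marginals; TSS is sensitivity + specificity − 1; AUC is the Mann–Whitney
rank statistic (reported for completeness only — it plays no role in model
selection or gating).

**Which points enter the confusion matrix.** Metrics are computed, for each
replicate model, from *all* input presence records plus the background, and
averaged across replicates; `points = "heldout"` scores only each
replicate's held-out presences instead. The all-records convention is the
package default because kappa under held-out scoring depends strongly on
the test-fold/background imbalance: scoring n/4 presences against a
10,000-point background caps kappa near 0.3 *for a model that is
essentially perfect* (the cap is a property of the marginals, not of model
quality), which would make a kappa > 0.4 gate unpassable by construction.
All-records scoring restores kappa to the scale at which the 0.4 threshold
is conventionally interpreted.

The validation gate admits a species as modellable iff kappa > 0.4 **and**
the species expert rated the mapped range good or medium. Four model
variants are assessed per species — (i) pre+post-1950 data; (ii) pre+post,
habitat-restricted; (iii) post-1950 only; (iv) post-1950 only,
habitat-restricted — with the expert's chosen variant winning outright and
a deterministic kappa/tie-break rule (habitat-restricted first, then
pre+post data) standing in when no expert choice exists.

# Geography

The accessible region of a species is the convex hull (MCP) of its
records, buffered outward by a dispersal distance: one year of dispersal
for the current period (configurable multiplier; the appropriate horizon is
genuinely open, so it is a config knob), and annual dispersal × years since
1975 (the midpoint of the 1950–2000 reference period) for future periods —
2025, 2055 and 2085 are the default scenario midpoints. Buffering projects
the hull to an azimuthal equidistant projection centred on its centroid,
takes the convex hull of discs around the vertices (exact for convex input
up to the 72-gon disc approximation, area within 0.15% of a true disc), and
reprojects. Clipping keeps cells whose centres fall inside the region;
clipped maps can only lose presences, and future regions nest over time.

Cell areas use the spherical band formula (within 0.5% of the spheroidal
value); mean latitude is area-weighted (the unweighted alternative differs
negligibly at these extents but the weighted form is exact under the stated
area model). Poleward movement is the mean-latitude difference signed
toward the species' pole; a species with no remaining presence cells is the
extinction case (range change −100%, latitude/elevation undefined).

# Comparative statistics

PGLS fits $y = X\beta + \varepsilon$, $\varepsilon \sim
N(0, \sigma^2 V(\lambda))$ with $V$ the Brownian-motion covariance (shared
root-to-MRCA path lengths) and $\lambda$ scaling the off-diagonal entries.
$\lambda$ is estimated by profile maximum likelihood on $[0,1]$ — a
21-point grid pre-scan guards against profile multimodality, then bounded
1-D refinement to 1e-6. ML (not REML) is used so that likelihood-ratio
tests against the $\lambda = 0$ and $\lambda = 1$ boundaries and AICc
comparisons across fixed-effects structures are coherent. The test suite
cross-checks $\hat\lambda$, $\hat\beta$ and the log-likelihood against the
independent `nlme::gls` + `ape::corPagel` route.

AICc uses $k$ = number of coefficients + 2 (for $\sigma^2$ and $\lambda$).
`dredgePGLS` refits every subset of the full term set (each with its own
$\hat\lambda$), ranks by AICc and attaches Akaike weights;
`modelAverage` does full (zero-substituted) averaging by default with
conditional averaging behind a flag. Outliers are externally studentized
residuals > 3 in the whitened ($V^{-1/2}$) space, removed in one pass with
a single refit; residual normality is Shapiro–Wilk on the whitened
residuals.

Group temporal trends use `nlme::gls` with an AR(1) correlation within
species — the minimal ARMA structure for serially dependent period
metrics; the order is configurable in principle but AR(1) is the default
because nothing in the period-level metrics motivates more structure.

Missing species are grafted onto the phylogeny at the midpoint of their
designated clade's stem branch, with the pendant length restoring
ultrametricity; pre-existing tip distances are provably unchanged.

# The synthetic world

`genWorld()` builds the default study conditions: a 200 × 200 grid of
0.1° cells, four climate variables (`temp` with a latitudinal gradient,
`prec` longitudinal, `seas` mixed, `soil` pure smoothed noise; all with
Gaussian-filtered spatial noise), a past period 0.3 units cooler, and
future periods that warm progressively (+1/+2/+3 units) or translate the
whole field poleward by a prescribed number of degrees. Twelve virtual
species in three groups mimic the pika/rabbit/hare contrasts: 2-D Gaussian
niches (temperature × precipitation) make congeners allopatric restricted
blobs rather than full-width climate bands; pikas sit at the cool poleward
edge with the narrowest tolerances, smallest masses and lowest dispersal
(0.3–0.6 km/yr), hares warm, broad, heavy and mobile (1.5–3 km/yr).
Presences are drawn proportional to truth suitability (200 per species,
15% pre-1950 drawn against the past climate), with 10% of precisions
drawn above the 2 km cut so the QC filters always have work to do. Expert
ratings are emulated by the Jaccard overlap of predicted and truth ranges
(≥ 0.7 good, ≥ 0.4 medium, else poor).

What the generator does *not* emulate: spatial sampling bias fields beyond
the optional weight map, observer error in coordinates, disequilibrium
between species and climate, biotic interactions, and land-cover change
over time. Passing recovery tests on this world therefore demonstrates the
estimators are correct and the plumbing faithful — not that real occurrence
data meet the model's assumptions.

Two design notes on the recovery experiments, both consequences of a
finite world rather than of the estimators. First, species whose niches
touch the domain edge cannot translate cleanly (the coolest climates exit
the domain poleward; the southern edge is extended by replication), so the
poleward-recovery experiment centres its species mid-domain. Second, that
experiment samples its background across the landscape so that training
spans the projection domain's climate range and feature clamping stays
inactive (see above); its dispersal rates (2 km/yr) are set so the
dispersal clip is active but non-binding, isolating change-metric error
from the dispersal constraint that the geometry tests verify separately.

# Problem sizes and determinism

The shipped experiments run at desk scale as a deliberate choice: the
default world is 200 × 200 cells with 12 species; the test suite uses a
120 × 120, 9-species world; recovery simulations use 100 replicates at 100
tips (PGLS) and 100 replicates of 3 × 20 AR(1) series. Every generator and
every stochastic stage is a pure function of (parameters, seed); rerunning
the pipeline with an identical configuration reproduces byte-identical CSV
outputs, which the acceptance suite asserts.

# Known limitations

- The land-class restriction is a no-op when a well-sampled species
  occupies every class in its region — frequent in the 4-class synthetic
  world, rarer with real land-cover products with tens of classes.
- Buffering convexifies concave geometry (the MCP is convex by definition,
  so this only matters for user-supplied polygons) and refuses geometries
  spanning more than a hemisphere rather than splitting at the
  antimeridian.
- Composite environmental variables are expressed through the generic
  expression interface (`deriveLayer`); no fixed composite set is bundled.
- Sub-population split/merge is supported at the function level
  (`unionBinaryMaps`) but the orchestrator models each species as a single
  population.
- PGLS assumes the tree is correct and ultrametric; grafting inserts tips
  at stem midpoints, which is a convention, not an inference.
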