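---
title: "Methods: presence-only distribution modelling with maxsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only distribution modelling with maxsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

maxsdm implements the species-distribution-modelling workflow used for rare
forest carnivores surveyed with presence-only data — the Humboldt marten is
the motivating case: a large, heterogeneous occurrence database (telemetry
bursts, scat-dog finds, baited stations, incidental records) is reduced to a
spatially thinned presence set, covariates are smoothed to their most
predictive spatial scale, a maximum-entropy model is fitted over a background
sample with an L1 penalty tuned by information criteria, and the resulting
suitability surface is evaluated with rank-based statistics and
predicted-to-expected curves. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices, in the order
the pipeline runs them.

## Occurrence filtering and spatial thinning

Records carry a detection type mapped to a retention priority: (1) telemetry
den/rest structures, (2) scat-detection-dog locations, (3) baited
camera/track-plate stations, (4) everything else. Records in cells disturbed
by fire or harvest *after* the detection year but at or before the
vegetation layers' vintage (default 2016) are removed first — the covariates
no longer describe what the animal used.

`thin_by_grid()` overlays a square grid (default 500 m) and keeps one record
per occupied cell: among the records of the best priority present, one is
drawn uniformly under the seed. The grid is anchored at the data
bounding-box lower-left corner by default; the anchor is an explicit
argument because thinned counts depend on it, and a thinned set remembers
its anchor so thinning is idempotent. Thinning runs globally in a single
pass over all records.

Replicate evaluation uses repeated random 75/25 train/test partitions
(default 10 replicates). This mirrors the "bootstrap with random test
percentage" behaviour of the standard Maxent interface: the *partition* is
redrawn per replicate; records are never resampled with replacement within a
split, so train and test are always disjoint and exhaustive.

## Scale optimization

Each covariate is focally smoothed at candidate radii of 50, 270, 742 and
1,170 m — local conditions, a core-area scale, a female home range, and the
largest male home range. `focal_mean()` averages unmasked cell values whose
centers fall within the radius (inclusive); nodata neighbours are excluded
rather than propagated so coastline cells keep large-radius values, and a
fully masked neighbourhood yields nodata.

For each variable and radius, a univariate binomial GLM contrasts the
presences with a dedicated background sample of 25 points per presence,
drawn disjointly from the maximum-entropy background (the two samples play
different roles and should not share locations). Covariates are standardized
inside the GLM so coefficient magnitudes are comparable across variables and
scales; raw-scale slopes are reported alongside. The radius with the lowest
AIC wins; the radius with the most extreme standardized coefficient is
recorded as a secondary indicator and a disagreement flag is set when the
two differ, because the two rules can genuinely disagree. Exact AIC ties go
to the smallest radius (parsimony), and radii whose GLM shows complete
separation are excluded from the race with a warning rather than raising.

## Collinearity screening

`pearson_screen()` walks pairs with |r| above the threshold (default 0.6) in
decreasing |r| and drops the member ranked lower in a user-supplied
interpretability order, recomputing eligibility after each drop; the
screened set is then checked with variance inflation factors
(VIF = 1/(1 − R²), values above ~5 flag trouble). The interpretability
order is deliberately explicit configuration: which of two collinear
covariates is "more interpretable" is a judgement the analyst must own.

## The maximum-entropy model

The model estimates a Gibbs density over the background sample,

$$q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z_\lambda},$$

with features $f$ built from the raw covariates after scaling to [0, 1] by
the background minimum and maximum: linear ($\tilde v$), quadratic
($\tilde v^2$) and pairwise product ($\tilde v_i \tilde v_j$) classes. When
projecting outside the training range, scaled values are clamped to [0, 1]
so responses are never extrapolated. "Auto" class selection admits a class
only when the presence count supports it (quadratic from 10, product from
80 presences). Fitting minimizes the convex penalized objective

$$\mathrm{NLL}(\lambda) = -\tfrac1m \sum_{\text{presences}} \log q_\lambda(x)
  + \sum_j \beta_j |\lambda_j|,
\qquad
\beta_j = \mathrm{RM} \cdot \rho(\mathrm{class}_j, m) \cdot
  \frac{\max(s_j, 0.05)}{\sqrt m},$$

where $s_j$ is the presence-sample standard deviation of feature $j$ and
$\rho$ the published per-class default schedule, interpolated
piecewise-linearly in $m$ and held constant beyond its endpoints. The 0.05
floor on $s_j$ is a numerical guard: a feature constant across the
presences would otherwise carry no penalty at all, and in degenerate
configurations (all presences in one cell) the unpenalized optimum runs off
to infinity. Features live in [0, 1], so the floor is small relative to any
informative feature's spread and rarely binds in realistic fits.

The solver is cyclic coordinate descent: per coordinate, a Newton step on
the smooth part with soft-thresholding for the L1 part, plus backtracking so
the objective never increases. The objective — not the algorithm — is the
contract: the test suite certifies the solver against an independent
golden-section coordinate search on small instances (objective gap below
1e-4) and checks exact moment matching when the penalty is off. Convergence
is declared when the relative objective change over a full sweep falls below
`tol` (default 1e-5) or after `max_iter` sweeps (default 500). Every
accepted update is recorded in a gain trace (the regularized training gain
is non-decreasing along it by construction), which later feeds percent
contribution.

Predictions come in two flavours: `raw` is $q_\lambda$ normalized over the
training background (the 10,000-point sample, not all landscape cells — the
choice matches the reference tool's training behaviour and is
self-consistent with the AICc module); `logistic` is
$e^H q/(1 + e^H q)$ with $H$ the entropy of the fitted density, the
conventional suitability index with indifference value 0.5.

## Model selection

`rm_sweep()` fits one candidate per regularization multiplier (default 0.5
to 4 by 0.5) on the *full* presence set — selection uses all data; the
replicates exist for evaluation. `aicc_rank()` renormalizes each candidate's
density over the normalization background, computes the presence
log-likelihood, counts nonzero coefficients ($k$), and ranks by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ the presence
count; candidates with $k \ge n-1$ are flagged invalid. Candidates within
$\Delta\mathrm{AICc} < 2$ of the best are conventionally competitive.

Variable importance is reported two ways. Percent contribution allocates
each positive gain increment of the fitting trace to the updated feature's
parent variable (product features split 50/50 between their parents — the
simplest defensible attribution; any trace-based attribution is
path-dependent). Permutation importance permutes one variable's raw values
across presences and background jointly, rebuilds features with the model's
scaling and clamping, and records the training-AUC drop, floored at zero and
normalized to 100; the single-permutation default mirrors common practice,
with `n_perm` available for averaging. Jackknife refits with only/without
each variable's features and reports training gains. Response curves come in
a marginal mode (others held at background means) and a univariate mode
(refit on that variable alone — the curve free of correlated-variable
influence).

## Evaluation and suitability classes

Discrimination is the rank-based AUC (ties count one half), and the binary
threshold is maximum sensitivity + specificity over observed scores (ties to
the lowest threshold). The predicted-to-expected curve slides 101
overlapping windows, each 10% of the background score range wide, across the
logistic axis — the window scheme follows the continuous-Boyce literature
defaults, as the procedure itself fixes neither. Per replicate,
$F_i = P_i / E_i$ compares the share of test presences in window $i$ with
the share of background there; windows with zero background mass are
dropped and recorded, and percentile (2.5/97.5) bands across replicates
avoid distributional assumptions at 10 replicates. The continuous Boyce
index is the Spearman correlation between mean $F$ and the window
midpoints. Note that a perfectly monotone curve with flat segments (exact
ties in $F$) cannot reach Boyce = 1; the index is also strongly
autocorrelated across overlapping windows, so its null distribution is much
wider than an independent-samples intuition suggests — the tests therefore
compare against enumeration oracles rather than asserting idealized
constants.

Thresholds derive from the curve. The lower threshold is the midpoint of
the first window where mean $F$ rises above 1 *and stays at or above 1*
thereafter — where the model durably beats random chance. In
`methods_text` mode the upper threshold is the median of test-presence
scores above the lower threshold ("lower half suitable, upper half highly
suitable"); `figure4` mode instead requires the lower 95% band to clear
the reference before suitability starts, folding mean-only windows into a
marginal class. The reference defaults to $F = 1$ (the random-chance line);
a literal reading against 0 is available via `reference = 0`. Both modes
are provided because the verbal descriptions of the published procedure are
ambiguous between them; neither is asserted to be "the" original rule.
`classify_raster()` applies half-open bins
$[0, t_\text{unsuitable})$, $[t_\text{unsuitable}, t_\text{high})$,
$[t_\text{high}, 1]$ and dissolves rook-connected components into polygons.

## The synthetic-landscape generator

`simulate_landscape()` draws Gaussian random fields with exponential
covariance (circulant embedding on a doubled torus; negative embedding
eigenvalues are clamped and fields re-standardized), mixes them through the
Cholesky factor of a requested cross-correlation matrix, and rank-maps each
field to its marginal bounds, so minima and maxima are honored exactly and
marginals are uniform. Defaults emulate coastal forest covariates: canopy
cover (2–99%), shrub-occurrence probabilities (0–100%), an old-growth
structural index, pine share, and smoother climate-like surfaces
(precipitation 13–198, August maximum temperature 8–24) with kilometre-scale
ranges at 30-m cells. Optional gradient variables are monotone in x
(coast-distance stand-ins) and an optional contiguous nodata blob emulates
masked urban/water cells.

`simulate_occurrences()` draws presence cells without replacement with
probability proportional to $\exp(\sum_v \beta_v \tilde v)$ — the same Gibbs
form the engine fits, so truth is recoverable — then duplicates each
presence with a heavy-tailed count (default mean ≈ 26, so a few hundred
presence cells produce a record database of the size real survey
compilations reach) with sub-thinning-cell jitter and a
telemetry-dominated detection-type mix. Sampling without replacement at the
cell level separates sampling redundancy (the duplication mechanism, which
thinning must undo) from the habitat signal.

What the generator does *not* emulate: imputation error in remotely sensed
vegetation products, interpolation artifacts in climate normals,
observer-specific detection bias, or spatial survey-effort clustering beyond
per-point duplication. Passing tests therefore demonstrate that the
algorithms recover known structure under the stated statistical
assumptions, not that any particular field dataset satisfies them.

## Numerical choices and degenerate inputs

- Cells are addressed by `floor((p − origin)/cell_size)` with half-open
  intervals, so boundary points map to exactly one cell; all coordinates are
  projected meters.
- Focal means run as FFT convolutions of the masked values and the mask;
  counts are rounded before division to remove FFT noise, and the
  neighbourhood test is inclusive with a 1e-9 slack.
- The solver caps coordinate steps at 10, backtracks by halving (at most 40
  times), and treats a window of 1e-13 as "no improvement".
- Background sampling, thinning, replicate splits, permutations and the
  generator all consume explicit integer seeds through isolated RNG scopes;
  reruns are bit-identical.
- Degenerate inputs have defined behaviour rather than crashes where the
  workflow benefits: complete GLM separation is flagged; constant covariates
  are excluded from features with a warning; constant prediction surfaces
  and all-empty window sets raise informative errors; an all-masked
  neighbourhood or an empty trace degrade to nodata / zero contributions
  with warnings.

## Problem sizes in the test suite

The packaged checks run on sizes chosen to exercise every code path while
staying desk-sized: recovery tests use a 200 × 200-cell landscape (30-m
cells) with 2 informative + 4 noise covariates, 500 presence cells and
10,000 background points at RM = 1; scale recovery uses 100 presence draws
of 400 presences against 9,600 GLM background points over the four standard
radii; solver certification uses dozens of randomized instances with at
most 100 background cells and 3 features, where golden-section search is
exact. The end-to-end acceptance run simulates a 400 × 400-cell landscape
and a ~10,000-record survey database thinned on the 500-m grid — the same
order of redundancy reduction the motivating study reports.

## Known limitations

- Raster I/O is plain-text ESRI ASCII grid (plus GeoJSON/CSV for vector
  data); GeoTIFF and CRS-aware reprojection are out of scope, and grids must
  be co-registered before use.
- Feature classes stop at linear/quadratic/product: hinge, threshold and
  categorical features, cumulative and cloglog outputs are not implemented.
- Percent contribution inherits the path-dependence of any trace-based
  attribution; prefer permutation importance when covariates are
  correlated.
- The "auto features" rule reproduces the sample-size minima of the default
  schedule, not the reference implementation's exact pruning of
  ineffective features.
- Thinned counts depend on the (configurable) thinning-grid anchor; the
  default anchors at the data bounding box.
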