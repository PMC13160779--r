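---
title: "Methods: space-time weighted regression for small region-year panels"
author: "gtwr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space-time weighted regression for small region-year panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtwr)
```

## The problem this package addresses

Administrative incidence data — police-reported domestic violence counts,
hospitalizations, service calls — are often available only as small panels:
a dozen or so irregular regions observed at a handful of annual time points.
A global regression on such a panel answers "what is the association on
average", but public-health targeting needs to know *where* and *when* an
association holds. `gtwr` implements the standard toolkit for that question
at desk scale: spatial autocorrelation diagnostics (global and local
Moran's I), a global OLS baseline with multicollinearity screening, and the
core method, geographically and temporally weighted regression (GTWR), in
which every region-year gets its own coefficient vector estimated by
kernel-weighted least squares.

Because panels of this kind are usually access-restricted, the package
ships a synthetic-data module that generates region lattices, covariate
panels and outcomes with *known* spatially varying coefficient surfaces, so
every stage of the pipeline is testable end to end and parameter recovery
can be measured against ground truth.

## Model and estimator

For region $i$ at time $t$ with covariates $x_{ik}$:

$$y_i(t) = \beta_{i0}(t) + \sum_k \beta_{ik}(t)\, x_{ik} + \varepsilon_i$$

Each local coefficient vector is a weighted least-squares solution

$$\hat\beta_i(t) = (X^\top W_i X)^{-1} X^\top W_i y,$$

where $W_i$ is diagonal with entries that are the *product* of a spatial
and a temporal kernel:

* spatial: fixed Gaussian, $w^S_{ij} = \exp(-d_{ij}^2 / 2b^2)$, with
  $d_{ij}$ the Euclidean distance between region centroids in km and $b$
  the spatial bandwidth (km);
* temporal: exponential decay, $w^T_{ij} = \exp(-|t_i - t_j| / h)$, with
  $h$ the temporal bandwidth in years.

The product form (rather than a single unified space-time distance) is the
design here because it keeps the two bandwidths separately interpretable:
$b$ is the distance at which influence falls to $e^{-1/2} \approx 0.61$,
$h$ the number of years over which it falls to $e^{-1} \approx 0.37$.
Time is the integer calendar year and distance is planar km, so fitted
bandwidths read directly in natural units. The self-weight is 1 (no
leave-one-out correction); the estimator is exactly the weighted
normal-equation solution at every calibration point.

Local standard errors use $\hat\sigma^2\,\mathrm{diag}(C_i C_i^\top)$ with
$C_i = (X^\top W_i X)^{-1} X^\top W_i$ and
$\hat\sigma = \sqrt{\mathrm{SSR}/n}$; the ratio `beta/se` is reported as a
*pseudo*-t. The "percent significant" column of `coefficient_summary()`
uses $|t| \ge 1.96$ by default — a conventional cutoff, configurable,
and not an exact test (the local fits share data).

## Bandwidth selection

Both bandwidths are chosen by minimizing the corrected AIC of the linear
smoother,

$$\mathrm{AICc} = 2n\ln\hat\sigma + n\ln 2\pi
  + n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)},$$

with $\mathrm{tr}(S)$ the hat-matrix trace (effective parameters) and
$\hat\sigma = \sqrt{\mathrm{SSR}/n}$. The search is an exhaustive
log-spaced 15 x 15 grid spanning $[0.1, 10] \times$ the maximum pairwise
centroid distance (spatial) and $[0.25, 10 \times \text{time span}]$
(temporal), followed by golden-section refinement along each axis around
the grid minimum. A deterministic grid was chosen over derivative-free
optimizers because at $n \approx 39$ the AICc surface can be flat or
multimodal, and the full surface is returned for inspection. Grid points
where $n - 2 - \mathrm{tr}(S) \le 0$ (bandwidths so small the smoother
nearly interpolates) have no defined AICc and are skipped; if every point
is undefined, selection fails loudly. As $b, h \to \infty$ all weights
approach 1 and the fit provably collapses to OLS with
$\mathrm{tr}(S) \to p+1$; the test suite checks this limit at
$b = h = 10^9$ to $10^{-6}$.

GTWR's adjusted $R^2$ uses effective parameters:
$1 - (1-R^2)(n-1)/(n - \mathrm{tr}(S))$. The OLS baseline reports the same
AICc formula with $\mathrm{tr}(S) = p + 1$ so the two models are compared
on one scale.

## Spatial weights and Moran's I conventions

Queen contiguity links regions sharing *any* boundary point; rook requires
a shared positive-length segment. Detection compares polygon vertices and
edges snapped to a tolerance grid (default $10^{-9}$ km) — robust for
tessellation output, where shared boundaries have numerically identical
vertices. k-nearest-neighbour weights use centroid distances with ties
broken toward the lowest region index, for determinism.

Moran computations default to row-standardized weights (each nonempty row
divided by its sum), the common convention of desktop spatial-analysis
tools; raw binary mode is retained for sensitivity. Inference is by random
permutation: 999 permutations by default, two-sided pseudo p-value
$(1 + \#\{|I^{(b)} - E| \ge |I_{obs} - E|\})/(1 + B)$ around the null
expectation $E = -1/(N-1)$. The local statistic uses
$m_2 = \sum z_i^2 / n$ (population second moment, the classical LISA
scaling, under which $\sum_i I_i = S_0 \cdot I$), conditional permutation
(hold $z_i$, permute the rest), and quadrant classification HH/LL/HL/LH
gated at $\alpha = 0.05$. Whether a one- or two-sided pseudo p is "the"
convention varies across tools; two-sided is this package's documented
choice.

## Preprocessing conventions

Counts become rates per 10,000 population before standardization — the
denominator is a convention, defaulted here because it is customary for
region-level incidence, and exposed as `scale`. Standardization is the
z-score with the *sample* sd ($n-1$), matching mainstream statistical
software; the transform stores $(\mu, \sigma)$ and inverts to machine
precision. A min-max `[0, 1]` normalizer is provided as an alternative,
since both conventions circulate in applied work; the pipeline default is
the z-score. A two-point vector standardizes to $\pm 1/\sqrt 2$ under the
sample-sd convention (it would be $\pm 1$ under the population convention)
— worth knowing when comparing against tools that default differently.

## The isolation index

The composite confinement index contrasts residential with non-residential
activity on a log scale. Six monthly percent-change-from-baseline streams
enter: residential and commercial mobility, residential and commercial
electricity consumption, stay-at-home and between-area movement range.
Each stream $p$ is mapped to level form $X = 1 + p/100$, and

$$I = \ln X_M^R + \ln X_E^R + \ln X_R^R
    - \ln X_M^C - \ln X_E^C - \ln X_R^C.$$

The level-form choice pins the two properties the index needs: a baseline
month contributes exactly zero, and the log argument stays positive for any
percent change above $-100$. Residential streams carry weight $+1$
(staying home indicates confinement) and non-residential streams $-1$, so
exchanging the two groups negates $I$ exactly — an antisymmetry the tests
assert. Seasonal-baseline estimation for electricity is accepted as
precomputed input, out of scope here.

The streams are island-wide, so when the monthly index is used as a
regression covariate it is aggregated to the mean over each calendar year
and applied uniformly across regions. That makes it a *temporal* covariate
only; with region-level streams the same code would yield a genuinely
spatiotemporal covariate.

## Global screening

The OLS baseline reports t statistics on $n - p - 1$ degrees of freedom
(not normal z values — at $n = 39$ the difference is material). VIF is
$1/(1 - R^2_k)$ from projection-based auxiliary regressions, tolerant of
redundancy among the remaining columns and returning `Inf` with a warning
under perfect collinearity. The heteroscedasticity check is the
studentized (Koenker) Breusch-Pagan form, $LM = n R^2_{aux}$ from
regressing squared residuals on the covariates, against
$\chi^2_k$. The LASSO uses the objective
$(1/2n)\lVert y - \beta_0 - X\beta\rVert^2 + \alpha\lVert\beta\rVert_1$
with an unpenalized intercept and `standardize = FALSE` (covariates are
pre-standardized); the penalty is selected by 5-fold cross-validation with
a seeded fold assignment, so selection is reproducible.

## Underreporting scenarios and offsets

If observed counts represent a fraction $(1 - x)$ of the underlying
reporting volume, the adjusted outcome is $Y/(1-x)$. `scenario_analysis()`
refits the model on the adjusted outcome with the covariates and
*bandwidths frozen at baseline*. Freezing matters: with the weighting
scheme unchanged, the refit is linear in $y$, so every local coefficient
scales by exactly $1/(1-x)$ and the baseline sign is retained in 100% of
regions — an algebraic identity, which the acceptance tests verify to
machine precision and then use to check published scenario tables that
follow the same arithmetic. Re-optimizing bandwidths inside each scenario
would break the identity (the AICc surface shifts with the outcome scale)
and conflate reporting assumptions with smoothing choices; if that is
wanted, run the selection manually per scenario.

The offset calculus converts coefficients to an interpretable scale. For a
standardized predictor, the modeled outcome change for a shift
$\Delta X_k$ is $\Delta Y \approx \beta_k \Delta X_k$; the SD-unit shift
that would counterbalance a given $\Delta Y$ is
$\Delta X_k^{offset} = -\Delta Y/\beta_k$. `offset_table()` uses the mean
local coefficient to set $\Delta Y$ at a default step of 0.5 SD, then
computes per-region-year offsets from the *local* coefficients and reports
their median and quartiles; locally zero coefficients are excluded and
counted. These are linear approximations from an observational fit, not
causal effect sizes.

## What the synthetic generator emulates — and what it does not

`sim_region_lattice()` tessellates a 180 x 60 km rectangle (the rough
aspect ratio of a mid-size Caribbean island) into Voronoi cells of jittered
grid points: contiguous, irregular, planar-km polygons resembling police or
administrative regions. `sim_covariate_panel()` draws standardized
covariates from a multivariate normal with exchangeable correlation 0.3
and, by default, one pair correlated at 0.95 — enough to push VIFs into
the 5-7 range typical of regional socioeconomic blocks, so the screening
stage has something real to screen. True coefficient surfaces are linear
in the rescaled east-west coordinate plus a linear time drift,
$\beta_{ik}(t) = a + b\,u + c\,(t - t_0)$; with $a = 0, b = 1$ the surface
runs from $-1$ in the westmost region to $+1$ in the eastmost, emulating
associations that flip sign across an island. Outcome noise is Gaussian;
the default sd of 0.25 makes the signal-to-noise comparable to a
standardized-rate regression with $R^2$ in the 0.5-0.9 range. The
lockdown-pulse component series raises residential streams and depresses
commercial ones by a raised-cosine pulse (default amplitude 30 percentage
points, noise sd 2) inside a configurable window, so the index peak is
forced into the window by construction.

What the generator does *not* emulate: real geography (no coastline,
no population-weighted centroids), municipality-level substructure,
non-Gaussian or overdispersed count noise, region- or time-varying
reporting rates, and any dependence of covariates on the outcome. Passing
the recovery tests therefore shows the estimator recovers smooth
coefficient surfaces under the model's own assumptions — it does not show
that any particular real panel satisfies those assumptions. The Gaussian
outcome noise in particular is the generator's assumption, chosen for
transparency, not a claim about police-report data.

## Validation design and problem sizes

The suite validates each stage against independent oracles: unpivoted
Gaussian elimination for (weighted) normal equations, double-loop
evaluation of the Moran statistic, explicit-formula Pearson correlation,
and closed-form kernel arithmetic. Simulation-based checks use fixed
seeds and desk-scale sizes chosen to keep the default run within minutes:
parameter recovery averages true-vs-estimated surface correlations over
20 panels (13 regions x 3 years, 3 gradient predictors, noise sd 0.25,
AICc-selected bandwidths) and requires mean correlation of at least 0.8
per predictor; permutation-test size and Breusch-Pagan size are each
checked over 500 null replicates against binomial 95% bounds around the
nominal 0.05.

## Numerical choices and degenerate inputs

* Local solves raise a named error identifying the calibration point when
  the weighted design is numerically singular (weights too concentrated).
* Constant vectors are rejected by `zscore()`, `minmax()`,
  `global_moran()` and `component_consistency()` as degenerate rather than
  silently producing NaN.
* Strength bins for mapping coefficients are right-open on the magnitude
  scale — $[0.25, 0.5)$ is "moderate" — and mirrored for negatives, with
  exactly zero classed "none"; the boundary convention is stated because
  prose definitions of such bins commonly overlap at endpoints.
* kNN distance ties break toward the lowest region index; contiguity
  snapping tolerance defaults to $10^{-9}$ km.
* Permutation pseudo p-values are bounded below by $1/(B+1)$ and cannot
  be zero.

## Known limitations

* Fixed (not adaptive) spatial bandwidth and Gaussian/exponential kernels
  only; no mixed (partially global) model; no prediction at unobserved
  locations.
* With 3 annual time points, the temporal bandwidth is weakly identified;
  AICc often selects the grid's upper end, effectively smoothing time
  almost flat. That is a property of the data size, reported honestly by
  the returned AICc surface.
* Moran's I is not confined to $[-1, 1]$ for arbitrary weight matrices;
  the bound holds in the row-standardized contiguity cases tested, and
  violations elsewhere are the statistic's nature, not an error.
* The pipeline treats the panel as complete; imputation is out of scope.
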