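# gtwr

Geographically and temporally weighted regression (GTWR) for small
region-year incidence panels, with the full analysis pipeline around it:
spatial weights from polygon geometries, global and local Moran's I with
permutation inference, a global OLS baseline with multicollinearity and
heteroscedasticity screening, a composite isolation (confinement) index
built from mobility/electricity/movement-range streams, underreporting
sensitivity scenarios, standardized offset calculus, and a synthetic-data
generator with known spatially varying coefficient surfaces for validation.

## Who this is for

Analysts working with administrative incidence counts observed over a
handful of irregular regions and a few annual time points — police-reported
violence, hospitalizations, service utilization — who need to know not just
whether a covariate is associated with the outcome but *where* and *when*.
Global regression averages such structure away; GTWR estimates one
coefficient vector per region-year:

```
y_i(t) = beta_i0(t) + sum_k beta_ik(t) x_ik + e_i
beta_i(t) = (X' W_i X)^-1 X' W_i y
w_ij = exp(-d_ij^2 / (2 b^2)) * exp(-|t_i - t_j| / h)
```

with a fixed Gaussian spatial kernel (bandwidth `b`, km, over region
centroid distances), an exponential temporal kernel (bandwidth `h`, years),
and both bandwidths selected by minimizing the corrected AIC
`2n ln(sigma) + n ln(2pi) + n (n + tr S)/(n - 2 - tr S)` of the implied
linear smoother. See `vignette("gtwr-methods")` for the model, all
conventions and design choices.

## Worked example

Simulate a 13-region, 3-year panel whose true coefficient surfaces are
known (x1 flips sign east to west; x2 drifts over time), select bandwidths,
fit, and compare against the global OLS baseline:

```r
library(gtwr)

regions <- sim_region_lattice(n_regions = 13, seed = 1)
panel <- sim_covariate_panel(regions, years = 2020:2022, seed = 2,
                             k = 3, collinear_pair = FALSE)
spec <- list("(Intercept)" = list(a = 2),
             x1 = list(a = 0,    b = 1),            # east-west sign flip
             x2 = list(a = 0.5,  b = -0.6, c = 0.1),
             x3 = list(a = -0.3, b = 0.4))
surfaces <- sim_coefficient_surfaces(regions, 2020:2022, spec)
panel$y <- sim_outcome(panel, surfaces, noise_sd = 0.25, seed = 3)

sel <- gtwr_select_bandwidths(panel, regions, c("x1", "x2", "x3"), "y")
fit <- gtwr_fit(panel, regions, c("x1", "x2", "x3"), "y", sel$b, sel$h)
fit
#> GTWR fit: n = 39, p = 3, b = 26.49 km, h = 20 yr
#>   R2 = 0.9261, adj R2 = 0.8897, RMSE = 0.1801, AICc = 25.2776, tr(S) = 13.53

ols_fit(as.matrix(panel[, c("x1", "x2", "x3")]), panel$y)
#> OLS fit: n = 39, p = 3, R2 = 0.3311, adj R2 = 0.2738, RMSE = 0.5418, AICc = 74.6949
#>                coef     se       t      p
#> (Intercept)  1.8321 0.0916 20.0052 0.0000
#> x1          -0.0068 0.1041 -0.0654 0.9483
#> x2           0.3997 0.1058  3.7766 0.0006
#> x3          -0.2050 0.0986 -2.0782 0.0451

coefficient_summary(fit)
#>     predictor    mean     sd     min    max pct_significant
#> 1 (Intercept)  1.9274 0.0791  1.7870 2.0955           100.0
#> 2          x1 -0.0612 0.5004 -0.6732 0.8566           100.0
#> 3          x2  0.5339 0.2940 -0.0301 0.9246            92.3
#> 4          x3 -0.2413 0.1651 -0.4588 0.0497            76.9
```

The story the numbers tell: the global OLS slope for `x1` is ~0 with
p = 0.95 — the east-west sign flip cancels in the average — while GTWR
recovers local `x1` coefficients spanning −0.67 to +0.86 (correlation with
the true surface 0.973 on this seed) and nearly triples explained variance
(R² 0.33 → 0.93). Residual spatial autocorrelation after the fit is
compatible with noise:

```r
w <- row_standardize(queen_weights(regions))
residual_moran(fit, w, seed = 9)
#> Moran's I = -0.3502 (E[I] = -0.0833), permutation p = 0.1580 (999 perms)
```

Underreporting robustness and interpretable offsets:

```r
scen <- scenario_analysis(panel, regions, c("x1", "x2", "x3"), "y",
                          sel$b, sel$h, xs = c(0.10, 0.25, 0.40))
head(as.data.frame(scen), 4)
#>     predictor   x mean_baseline mean_scenario pct_same_sign
#> 1 (Intercept) 0.1        1.9274        2.1416           100
#> 2          x1 0.1       -0.0612       -0.0680           100
#> 3          x2 0.1        0.5339        0.5932           100
#> 4          x3 0.1       -0.2413       -0.2681           100

offset_table(fit)
#>   predictor mean_beta mean_pred_change median_offset     p25     p75
#> 1        x1   -0.0612          -0.0306       -0.0541 -0.0768  0.0452
#> 2        x2    0.5339           0.2670       -0.3906 -0.7110 -0.3217
#> 3        x3   -0.2413          -0.1206       -0.3489 -0.6319 -0.2730
```

Refitting an inflated outcome `y/(1-x)` with frozen bandwidths scales every
local coefficient by exactly `1/(1-x)`, so `pct_same_sign` is 100 by
algebra — the point of the scenario table is to verify that mechanism and
report the rescaled magnitudes. The offset table converts mean local
coefficients into the SD-unit predictor shift that would counterbalance a
0.5-SD predicted outcome change.

The end-to-end pipeline (weights → Moran/LISA → OLS screening → GTWR →
sensitivity → offsets, with all tables written to disk) is one call:

```r
report <- run_pipeline(run_config(seed = 1, out_dir = "gtwr-run"))
```

or from the shell, `Rscript inst/scripts/run-study.R --seed 1 --out-dir gtwr-run`.

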