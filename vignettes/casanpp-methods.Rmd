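---
title: "Methods: CASA NPP estimation and spatiotemporal driver analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CASA NPP estimation and spatiotemporal driver analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(casanpp)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what its synthetic-data tests
do and do not establish.

## The CASA light-use-efficiency model

Monthly NPP is the product of absorbed photosynthetically active
radiation and a realized light-use efficiency:

$$NPP(x,t) = APAR(x,t) \times \varepsilon(x,t), \qquad
APAR = FPAR \times SOL \times 0.5,$$

where $SOL$ is total monthly solar radiation (MJ m⁻² month⁻¹) and 0.5
the photosynthetically active fraction. FPAR is estimated twice — a
linear rescale of NDVI between vegetation-class bounds onto
$[0.001, 0.95]$, and the same rescale of the simple ratio
$SR = (1+NDVI)/(1-NDVI)$ — and averaged, because the two estimators
bracket field measurements from opposite sides. NDVI is clipped at
0.997 before the SR transform to keep it finite; negative NDVI receives
the FPAR floor.

The efficiency term factorizes as
$\varepsilon = T_{\varepsilon 1} \times T_{\varepsilon 2} \times
W_\varepsilon \times \varepsilon_{max}$. The source literature for this
model family names these stress scalars without printing closed forms,
so the package adopts the canonical closures used across the regional
CASA literature:

* $T_{\varepsilon 1} = 0.8 + 0.02\,T_{opt} - 0.0005\,T_{opt}^2$,
  floored at 0 and zeroed in months with $T \le -10$ °C;
* $T_{\varepsilon 2} = 1.1814 \, /\, \{[1 + e^{0.2(T_{opt} - 10 - T)}]
  [1 + e^{0.3(-T_{opt} - 10 + T)}]\}$, a double logistic penalizing
  months much colder or hotter than the optimum;
* $T_{opt}$ is the multi-year mean temperature of the calendar month
  with the highest multi-year mean NDVI (earliest month on ties);
* $W_\varepsilon = 0.5 + 0.5\,E/E_p$ clipped to $[0.5, 1]$, with actual
  evapotranspiration $E$ from the Zhou–Zhang regional closure driven by
  monthly precipitation and net radiation, net radiation estimated from
  Thornthwaite potential evapotranspiration and precipitation, and
  $E_p = (E + E_{p0})/2$. Where $E_p = 0$ (frozen or fully arid months)
  the drought floor 0.5 applies. The radiation cube is accepted by
  `water_stress()` for interface symmetry but the closure itself needs
  only precipitation and temperature.

$\varepsilon_{max}$ and the NDVI class bounds are *not* facts the
package can derive; they ship as an editable table
(`default_veg_params()`) following the China calibration common in this
literature, with SR bounds derived from the NDVI bounds through the SR
transform so the two FPAR routes agree at the endpoints. Whether
non-vegetated classes should be masked out of NPP maps is left to the
user (they are not, by default).

Annual NPP is the sum of twelve monthly layers; regional totals convert
as $\mathrm{TgC} = \sum (\text{pixel NPP} \times \text{pixel area m}^2)
\times 10^{-12}$.

## Trend and significance mapping

Per pixel, the interannual trend is the closed-form OLS slope against
the year index, and significance comes from the Mann–Kendall statistic
$S$ with the tie-corrected variance
$[n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)]/18$ (the source text names
only "the variance"; the tie-corrected form is the universal
convention) and the three-branch standardized $Z$. The five-class
legend uses thresholds 1.96 and 2.58. Two boundary conventions had to
be fixed: $|Z| = 2.58$ (unassigned in the published table) maps to the
single-star classes SR/SI, and sign-inconsistent (slope, Z) pairs —
possible with ties — map to NSC, the only class defined without a
slope-sign condition. No multiple-testing correction is applied across
pixels, mirroring standard practice for these maps. NPP grade
proportions use half-open intervals $[0,100), [100,200), \dots$ so a
value on a boundary counts upward.

## Gravity center, partial correlation, land-use ledger

The NPP-weighted centroid uses pixel-center coordinates in the
projected metric CRS (centers, not corners — standard for centroid
statistics) and planar distances, so geographic-coordinate rasters are
rejected outright rather than silently approximated.

Climate attribution uses the second-order partial correlation computed
by the first-order recursion; the test suite proves it equal (to
1e-10) to the independent precision-matrix route, and the `t`-test uses
$df = n - 4$ (two controls), the standard inference for a second-order
partial correlation. Two readings of the "regional coefficient" are
emitted: the mean of per-pixel coefficients and the coefficient of the
regional-mean series; at $n = 20$ years a per-pixel coefficient has a
sampling sd near 0.25, so only regional summaries are tightly testable.

The land-use ledger multiplies each off-diagonal transition area by the
difference of class mean NPP. Published per-class "net increase"
figures in this literature do not pin down an attribution formula, so
both conventions are emitted: destination attribution (conversion
credits the receiving class — this reproduces the narrative in which
restoring unused land to grassland compensates farmland expansion) and
source attribution; their per-class vectors differ but their sums are
identical, which the tests assert. Per-epoch mean NPP defaults to the
epoch-start map.

## The optimal-parameter geographic detector

The q-statistic is computed with population variances so that
$SST = SSW + SSB$ holds exactly and $q$ is exactly the between-strata
variance share (the published text is ambiguous on this point; the
exact decomposition makes $q$ oracle-testable). Strata with fewer than
2 samples are dropped, with a message — the only mechanism that can
produce "weakening" interaction categories. Significance uses the
canonical noncentral-F test with a central-F fallback flag.

Discretization: equal interval, quantile, exact Fisher–Jenks natural
breaks (dynamic program over sorted values; thinned deterministically
above 3000 points, standard for 1-D classification), geometric
interval, and standard-deviation cuts. For the geometric interval the
edges themselves form a geometric progression over the positively
shifted span, which gives the ratio in closed form
$(max/min)^{1/k}$ — no iterative solve is needed under this (common)
definition. The bin-count search covers 3–8; ties break toward fewer
bins, then method order. Scale selection aggregates the response (mean)
and factors (mean/mode) to each candidate scale, optimizes every
factor's $q$, and picks the scale maximizing the 90 % interpolated
quantile of $q$ across factors. Aspect is best passed as a categorical
sector factor rather than discretized as a continuous circular value.

## The synthetic world, and what a green test establishes

The generator states one reference world and the tests recover its
parameters; none of its numbers were tuned to make tests pass:

* **Geometry/time**: 120 × 120 pixels of 500 m, 20 years — small enough
  for CI, large enough for stable regional statistics.
* **NPP trend 2.47 gC m⁻² yr⁻²** and partial-correlation targets
  **(0.30, 0.17, 0.09)** for (precipitation, temperature, radiation) —
  the headline values of the motivating analysis, used here as
  generator inputs whose *recovery* is the test.
* **Correlation structure**: the 4×4 correlation matrix of (NPP,
  drivers) is built from a precision matrix with driver–driver partial
  correlations set to 0, so the NPP–driver partial correlations equal
  the targets exactly (feasible iff the squared targets sum below 1;
  infeasible targets error by name). Linear trends are folded in by
  subtracting the trend outer-product from the noise covariance, so the
  raw series — trend included — carry the prescribed structure. The
  jointly drawn `npp_response` cube is the object with analytically
  known partial correlations; CASA output on the same drivers is *not*
  (its response is nonlinear), which is why the recovery tests use the
  response cube and the CASA chain is tested by its own contracts.
* **Latent strata**: blocky 8-pixel (4 km) strata whose response is
  built as a·(stratum means) + b·(within-stratum-centred noise); the
  centring makes the variance split exact, so `strata_q_target` is
  recovered to machine precision, and the block scale is the one the
  OPGD scale search should (and does) select.
* **Transitions**: planned areas are converted by seeded deterministic
  sampling within the source class, so the recovered matrix equals the
  plan exactly.
* The configured trend field is split into `npp_trend`
  (gC m⁻² yr⁻², recovered from the annual response) and `ndvi_trend`
  (NDVI yr⁻¹, recovered from annual-max NDVI): a single field cannot
  serve both in consistent units. With the NDVI climate response
  active, the realized NDVI trend adds the response-weighted driver
  trends, which the tests account for explicitly.

What the synthetic world does **not** emulate: sensor noise and cloud
artifacts, spatial autocorrelation of the interannual anomalies
(pixels are conditionally independent), nonlinear NPP–climate
responses, and real land-use change processes. A green suite therefore
establishes correctness of the estimators and the pipeline plumbing —
not realism of any particular ecological conclusion.

## Numerical conventions and limitations

* Rasters are plain-text ESRI ASCII grids with a `.crs` sidecar; pixels
  are square; integer layers round-trip exactly, continuous layers are
  written with 15 significant digits. No GDAL-backed package is
  required.
* Masks propagate: any masked operand masks the result; `mean`
  aggregation ignores masked cells; `mode` aggregation breaks ties
  toward the lowest class id.
* Degenerate inputs error early and by name: geographic CRS, zero
  response variance in `q_statistic()`, collinear controls in the
  partial correlation (masked pixel), infeasible correlation targets,
  infeasible transition plans.
* The acceptance suite is scaled to run in minutes on one CPU: oracle
  checks use N ≤ 500, calibration uses 2000 null series, recovery uses
  the 120×120 reference world. Statements about multi-GB satellite
  archives are out of scope by construction.
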