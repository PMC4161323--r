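---
title: "Methods: from line-transect surveys to wind-farm sensitivity maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from line-transect surveys to wind-farm sensitivity maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasens)
```

`seasens` turns segmented at-sea survey data into gridded seabird
sensitivity maps for offshore wind planning. This vignette explains the
statistical machinery, the defaults and why they are set where they are,
what the synthetic-data generator does and does not emulate, and the design
choices that were genuinely open.

## Survey data model

The unit of effort is the **segment**: a short stretch of transect
(roughly a 10-minute recording period for boat surveys at ~300 m strip
half-width; ~1 km for continuously recording aerial surveys) with a
midpoint in a projected planar CRS (metres, OSGB-style easting/northing),
a covered area, and covariates — minimum distance to coast (`cdist`, km,
taken at the midpoint) and water depth (positive metres below sea level,
looked up at the nearest bathymetry cell; segments are small relative to
the raster so a footprint mean buys nothing). Observations carry species,
count, behaviour (sitting/flying), and either an exact perpendicular
distance (boat) or a distance-band index (aerial). Months April–September
are pooled as summer, October–March as winter. Surveys that recorded only
some species (e.g. auk-only surveys) are dropped from the effort base of
any other species, since keeping them would manufacture false zeros.

All geometry is planar Euclidean: grid clipping uses Sutherland–Hodgman
rectangle clipping and shoelace areas, coastline distance is the minimum
point-to-segment distance over the land polygon's boundary. Points on land
get `cdist = 0` with a warning rather than an error, so shoreline-straddling
segments survive ingestion and can be inspected downstream.

## Detection functions

Perpendicular distances are fitted by maximising the conditional
likelihood f(x) = g(x)/∫₀ʷ g, with two key forms and no adjustment terms:
half-normal (one parameter) and hazard-rate (two; shape b > 1 so the
shoulder is integrable). Binned (aerial) data use the interval-censored
multinomial likelihood; the blind strip under the aircraft is handled by
left-truncating at the first band edge, and the searched area excludes it.
Selection is by AIC with ties broken toward fewer parameters. Detection is
pooled per species × platform × behaviour × season; pools under 50
observations return an explicit insufficient-sample result and the species
is routed to presence/relative-density mapping instead. Flying birds on
strip transects are assigned detection probability 1 (`unity_model()`),
matching standard boat-survey snapshot practice; aerial flying birds are
fitted from their band data like sitting birds. Sea state is accepted in
the observation schema but not used as a detection covariate.

Numerics: optimisation is BFGS on log-transformed parameters
(σ = exp(θ₁), b = 1 + exp(θ₂)) from three starting scales (0.5×, 1×, 2× a
moment-based guess) to guard against hazard-rate local optima; the
half-normal ESW uses its closed form, the hazard-rate ESW adaptive
quadrature (rel. tol 1e-9). `cv_p` is the delta-method CV of ESW from the
inverse observed information (central differences, step 1e-4 on the log
scale); a seeded nonparametric bootstrap (`bootstrap_cv_p()`) is provided
as a cross-check. Degenerate inputs (e.g. all distances zero) are flagged
non-convergent rather than fitted.

## Density surface models

Corrected counts n̂ᵢ = nᵢ/p̄ enter a GAM with log link and offset
log(covered area): response family negative binomial (θ profiled by REML)
by default, Tweedie (`tw()`, p profiled in (1.1, 1.9)) for species the
negative binomial fits poorly. Smooths are penalised thin-plate splines,
s(x, y) with basis dimension 30 and s(cdist) with 10 — sized to the
published workflow this package operationalises — with REML smoothing
parameters and the null-space double penalty (`select = TRUE`) for
automatic term selection. An alternative response convention (raw counts
with effective-area offset) is algebraically equivalent for the mean and
was not implemented. Coordinates are centred internally, so predictions
are invariant under translation of the input CRS. Regions (e.g. an
enclosed bay vs. open waters) are fitted independently; the smaller
region's CVs will be higher, which is a feature of the separation, not a
bug.

**Boundary handling.** A soap-film smoother (boundary-respecting spatial
basis) is deliberately not used: it is fragile in automated pipelines
(knot placement on the boundary makes it fail). Instead, land avoidance
comes from three cooperating mechanisms: predictions are restricted to the
sea mask; `cdist` is a covariate, so density structure follows the coast;
and cells outside the convex hull of surveyed locations or outside the
fitted `cdist` range are flagged `extrapolated`. The practical effect —
no confident density leaking across a headland — is checked in the test
suite on a peninsula-free synthetic world by verifying CVs are higher and
flags set where effort is absent.

Collinear covariates are screened before fitting: `compute_vif()` gives
VIF_j = 1/(1−R²_j), and `choose_covariates()` greedily drops the
lower-explanatory-power member of any pair above the threshold (default 5,
a conventional applied-regression cut; configurable). Where depth and
coast distance are strongly collinear, coast distance typically explains
more deviance and survives.

Predictions multiply exp(η) by the cell's sea area (9 km² or less for
coastal cells) and divide back to birds/km². Per-cell CVs come from 200
posterior draws β* ~ N(β̂, V_β) (V_β is the Bayesian covariance; a ridge
is added with a warning if it is numerically indefinite), CV_gam = sd/mean
of the drawn densities, and total CV = √(CV_gam² + cv_p²). Segment
autocorrelation is ignored, as is conventional for these models, so CVs
should be read as minima. The coverage-normalised fallback divides summed
corrected counts by summed covered area per cell; cells without effort are
missing, never zero.

## Species sensitivity indices

Four conservation factors are banded exactly as published (see
`score_directive()`, `score_pct_population()`, `score_survival()`,
`score_bocc()`); their sum is the conservation importance CI ∈ [4, 20].
The collision index e·(f+g+h)/3·CI weights blade-height exposure (a
percentage, 0–100) above the three 1–5 flight factors; the displacement
index i·j·CI/10 combines disturbance susceptibility and habitat
specialisation. Both round half-to-even: the convention is pinned by three
published half-cases (22.5 → 22, 16.5 → 16, 7.5 → 8), and products are
snapped to exact halves within 1e-9 before rounding so floating-point
noise cannot flip a case. The two scales rank species *within* an impact
and are not comparable across impacts.

Risk-class thresholds are not published; the defaults sit inside the gaps
between adjacent published scores so every published label reproduces
(collision: ≥850 Very High, ≥410 High, ≥190 Moderate, ≥50 Low; displacement:
≥20 High, ≥9 Moderate, ≥6 Low) and are configuration-exposed. Displacement
never gets a Very High class — its categories top out at 4 — reflecting
the lower population-level risk of displacement relative to collision; the
overall category per species is the maximum of the two.

Ties in ranked listings keep input-table order (stable sort); scores, not
row order, are the meaningful output.

## Fusion and mapping

Sitting + flying surfaces add; their CVs combine as independent variances.
Boat/aerial fusion per cell: discard candidates with CV > 0.5 (unreliable,
typically far from coverage), then take the maximum density if its
CV < 0.3 (areas with good coverage resolve to CVs ≤ 0.3), else the
lowest-CV candidate. The fused CV is the chosen candidate's, carried for
reporting only — no fused CV is defined. Species layers are
score × ln(density + 1); the log keeps abundant species from swamping the
map. Per-risk maps use the raw index scores (e.g. 1470) by default, while
the overall map uses categorical values (1–5) with each species entering
at max(collision, displacement category); a switch allows categorical
per-risk maps, since either convention is defensible for the per-risk
layers and both are useful. Aggregation sums species treating
species-missing as zero; cells where *no* species had usable data emit
exactly zero with `data_ok = FALSE` — an explicit mask band distinguishing
"no usable data" from "genuinely zero sensitivity". Seasonal maps written
together record a shared min/max in their metadata sidecar so summer and
winter render on one scale.

## The synthetic-data generator

`make_truth()` builds density surfaces as
base × exp(gradient × cdist) + Gaussian hotspots, clipped at zero;
`simulate_survey()` lays parallel transects, places bird groups by an
inhomogeneous Poisson process with the cell's truth density, draws
perpendicular distances uniformly across the strip (the standard
line-transect availability assumption), thins by the true detection
function, and bins aerial detections into bands. Defaults describe a
realistic survey: 300 m boat strips, σ = 120 m half-normal detection,
~1.8 km segments, 6 km transect spacing, 30% of birds flying, group size
fixed at 1 (geometric cluster sizes are available behind a flag, with
size-biased detection deliberately not modelled).

What it does **not** emulate: animal movement and responsive movement to
the platform, spatial autocorrelation beyond the smooth truth surface,
observer heterogeneity, sea-state effects on detection, and cluster-size
bias. Passing tests therefore demonstrate that the estimators recover
known truth under their own assumptions — they do not certify performance
on real surveys, where those violations are live.

The documented validation scenario ("hotspot world") is a 60 × 60 km sea
with a straight western coastline, base density 4 birds/km² with a −0.02/km
coastal gradient and an 18 birds/km² offshore hotspot, surveyed by ~300
boat segments — sized so the full detection → DSM → CV chain runs in
seconds while leaving enough information to recover the truth (rank
correlation > 0.8, totals within sampling error). Determinism is by a
single master seed; pipeline stages derive fixed offsets from it.

## Known limitations

- CVs are minima (no autocorrelation correction; no GAMM option).
- No covariate detection functions, mark–recapture distance sampling, or
  cluster-size regression.
- The boundary-masked smoother approximates, but is not, a soap film:
  within-sea geodesic distances are not used in the 2-D smooth's metric.
- Behaviour-specific seasonal flight-activity scores and macro-avoidance
  are not represented in the sensitivity index — the factor table is a
  snapshot of published evidence, versioned as a data fixture so it can be
  replaced without code changes.
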