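---
title: "Measuring household food-environment exposure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring household food-environment exposure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`foodscape` compares two ways of delineating the spatial area over which a
household is exposed to food outlets — a network buffer around the home and
an activity space built with the daily path area method — and fits the
weighted regression models that relate the resulting exposure indicators to
household characteristics. This vignette documents the model, the tunable
parameters, the numerical choices, and what the synthetic test world does
and does not establish.

## The two exposure measures

**Home buffer.** The service area of the home at 500 m *network* distance:
every point on the street network whose shortest-path distance from the
snapped home location is at most 500 m, polygonized. 500 m is the
conventional walking-scale threshold for the food environment around the
residence. Network buffers (rather than Euclidean discs) respect the street
fabric: a dense center yields a compact, filled buffer; a sparse periphery
a thin, tentacular one.

**Activity space (daily path area).** The household-level union of

1. the 500 m network buffer around the home;
2. a 500 m network buffer around *every* anchor point (a location an adult
   visits at least weekly, reported with its usual transport mode, up to
   two per adult) — including anchors reached by public transit, whose
   visited vicinity is a genuine exposure area even though the route is
   not;
3. a Euclidean corridor along the fastest-path route from home to each
   non-transit anchor: 100 m half-width for walking and cycling (the
   environment a pedestrian or cyclist actually encounters), 300 m for
   car/motorcycle/scooter (the distance at which large road-side outlets
   remain visible and accessible from a main road);
4. the same corridor between the two anchors of an adult who visits both
   with the same non-transit mode.

Public-transit *routes* are excluded (the itinerary between stops is not
the rider's exposure surface, and transit route data are typically
unavailable); only their endpoints' vicinities enter. Anchor points are
deliberately unweighted — we do not rank them by visit duration, since time
spent at a location is a poor proxy for the use of nearby amenities.

Assumptions worth making explicit: all adults involved in food shopping
contribute equally to the household's exposure; "fastest path" is computed
on a single uniform-speed network, so it coincides with the shortest path —
a per-edge speed model would change route *choice* only where modes use
different networks, which they do not here (the implementation exposes edge
weights through the routing layer should such data exist); and 500 m
network buffers are used for *all* anchors, home and non-home alike.

## Geometry without a polygon engine

No polygon-boolean library is assumed. An exposure area is represented
exactly as a union of *capsules* — segments buffered by a radius:

- a service area is the union of its reachable (possibly partial) edges
  buffered by the polygonization half-width `edge_halfwidth_m` (default
  25 m, i.e. a 50 m-wide ribbon per street);
- a route corridor is the union of the route's segments buffered at the
  mode-specific half-width (collinear vertices are merged first, so a
  straight route is a single capsule with the exact closed-form area
  `2wL + πw²`).

This makes point-in-area queries *exact* (point-to-segment distance, with
boundary points counted inside — the closed-region convention), and makes
the activity-space ⊇ home-buffer containment structural: the activity space
carries the home buffer's capsules. Areas of unions are integrated on a
regular grid whose cells are anchored at absolute multiples of the
resolution (default: one sixth of the smallest capsule radius, coarsened to
cap the grid at ~4 × 10⁶ cells), so areas are monotone under containment at
a fixed resolution; single capsules use the closed form. The grid
integrator is validated in the test suite against Monte-Carlo rejection
sampling at 1% tolerance.

Partial edges are truncated at the *exact* residual network distance: an
edge of length L whose endpoints lie at distances d_u, d_v from the origin
contributes the arcs [0, R − d_u] and [L − (R − d_v), L] (merged when they
overlap), and the origin's own edge additionally contributes the direct arc
[a − R, a + R] around the origin's offset a — without this term an origin
in the middle of a long edge would reach nothing.

Homes, anchors and outlets snap to the nearest network point within 30 m
(geocoded addresses should sit next to a street; a larger discrepancy is
treated as an input error). Shortest-path ties are resolved
deterministically by the routing engine, so identical inputs always yield
identical polygons.

## Indicators and coding

Outlets carry one of 8 store categories (butcher, bakery, drive-through
supermarket, fish shop, greengrocer, grocery store, market, supermarket) or
2 restaurant groups (traditional, fast food — cafeterias count as fast
food). Fruit-and-vegetable retailers are drive-through supermarkets,
greengrocers, grocery stores, markets and supermarkets. Per household ×
area: number of stores, number of restaurants, diversity (distinct store
categories present, 0–8), relative density of F&V retailers among stores,
and of fast-food restaurants among restaurants.

Codings for the models:

- **Counts** → sample tertiles, computed on the raw (unweighted)
  distribution *separately per area kind* — the two measures' counts differ
  by an order of magnitude, so pooled tertiles would code the measure, not
  the exposure. Intervals are right-closed; a value equal to a tertile
  boundary goes to the lower class. Degenerate distributions (an empty
  class after tie handling) raise an error unless explicitly tolerated
  (`strict = FALSE`, used by the pipeline for pathological worlds such as a
  city with zero outlets).
- **Diversity** → fixed bands 0–2 / 3–5 / 6–8.
- **Relative densities** → binary at 50%, `ge50` iff ratio ≥ 0.5. A ratio
  undefined because the area has no stores (or no restaurants) is coded
  "less than 50%": absence of stores is certainly not a ≥ 50% exposure.

## Weighting

Weights are calibrated by the raking ratio method (iterative proportional
fitting) to two margins: income per consumption unit (including "refuse to
answer" as its own category — it is a real sample category and must have a
population target) and household composition crossed with the age group of
the household head. Tolerance 10⁻⁶ on every weighted marginal proportion,
at most 200 sweeps, no trimming or bounding (none is standard for raking at
this scale, and the recovered weights stay well inside [0.2, 5] in the
synthetic world). Weights are normalized to mean 1 so the weighted sample
size equals n and model degrees of freedom stay comparable. Raking errors
are explicit: a margin category with positive target but no sample members
cannot be calibrated and raises an error rather than silently producing
infinite weights.

## Models

All models are fitted on the weighted sample:

- **Screening.** Each covariate (age, education, composition, employment,
  income, car ownership, home location) is tested alone against each
  outcome with a weighted likelihood-ratio test; covariates with p < 0.2
  enter the multivariate model. The LR statistic was chosen over Wald or
  score variants for consistency with the multivariate likelihood. Empty
  outcome × covariate cells trigger a lightly ridge-penalised screening fit
  (flagged in the output) rather than a crash.
- **Multinomial logit** (3-class codings), fitted by Newton–Raphson maximum
  likelihood with case weights; baseline class = lowest tertile / lowest
  diversity band, so ORs read as "odds of higher exposure". Wald 95% CIs
  from the observed information. Reference covariate levels follow the
  usual conventions: age < 35, lowest education, employed, one adult,
  lowest income quartile, no car, city-center.
- **Binomial logit** for the binary codings (`ge50` vs `lt50`), via `glm`.
- **Weighted least squares** for the area size (km²), with a Shapiro–Wilk
  statistic on residuals replacing the visual Q-Q-plot normality check.
- **Collinearity**: generalized variance inflation factors from the
  determinant ratio of correlation submatrices of the design;
  adjusted GVIF = GVIF^(1/(2 df)), acceptable below 5.
- **Comparison**: per covariate level, ORs and CIs side by side for the two
  measures and a flag when significance (p < 0.05, no multiple-testing
  correction) holds under one measure but not the other.

Model-based variances are reported, not design-based (sandwich) ones: the
comparison targets studies that report model-based CIs on a raked sample,
and we match that convention. This understates sampling variability
somewhat; it is a faithful limitation, not an oversight.

Under a very strong spatial gradient, tertile × zone tables can contain
empty cells (e.g. no peri-urban household in the top stores tertile) and
the multinomial MLE is then quasi-separated: point estimates drift to the
boundary and Wald CIs degenerate to (0, ∞). The fitting functions detect
this, warn, and fall back to a lightly ridge-penalised fit (λ = 10⁻³) so
the pipeline reports finite, sign-correct estimates; the warning is the
signal to interpret those CIs with care. The default synthetic world's
gradient is strong enough to trigger this for the store-count model — a
deliberate property of the planted world, not a numerical accident.

## The synthetic city: what it states and what it omits

The generator's defaults are the stated world of the package's tests:

- 8 × 8 km city (half-width 4000 m), street grid at 250 m spacing with
  ±40 m node jitter — a walkable-block-scale network, connected and planar.
- Outlets from an inhomogeneous Poisson process with intensity
  60 km⁻² · exp(−d / 2000 m): a dense center, sparse periphery, and decay
  scale equal to half the city extent, the configuration under which the
  center–periphery exposure gradient is planted. The 10-category mix is a
  plausible French urban retail mix (bakeries 25%, restaurants 35%, …).
  Outlets further than 30 m from a street are relocated to front onto the
  nearest street.
- 699 households; zone sampling probabilities 0.19 / 0.41 / 0.40
  (center / pericentral / peri-urban, radii 1000 m and 2500 m); covariate
  marginals follow the population distribution of the study region; car
  ownership conditional on zone (0.55 / 0.80 / 0.92, marginal ≈ 0.81);
  motorised modes only in car-owning households.
- Anchor counts per adult: 0, 1 or 2 with probabilities 0.20 / 0.50 / 0.30.
  No survey reports this distribution, so it is an explicit free parameter
  of the generator — chosen once to make multi-anchor adults common enough
  to exercise inter-anchor corridors — not an estimate.
- Anchor locations concentrate toward the center (exponential weight,
  scale 2000 m), emulating centripetal commuting.
- Covariate associations are deliberately minimal — zone → car ownership →
  modes, everything else independent — so that recovery tests have known
  answers. Real sociodemography is far more entangled; the generator's
  `covariate_params` expose the knobs but the defaults do not attempt to
  model France.

Consequently, a green test suite establishes that the *machinery* is
correct (geometry against brute-force and closed-form oracles, raking
against a hand IPF, models against contingency-table closed forms and
coverage simulations, and the end-to-end sign of the planted gradient). It
does not establish anything about any real city: there is no transit
network, no route deviation from the fastest path, no temporal dimension
(opening hours, visit frequency), no outlet quality, and no spatial
autocorrelation in household covariates beyond the home-location zone.

## Reproducibility

Every generator layer draws from its own RNG stream (`seed + offset`), so
layers can be regenerated independently and the whole pipeline is
bit-reproducible given `(config, seed)`. `run_pipeline()` writes a manifest
with the package version, seed and a hash of all parameters; the hash
changes iff any parameter changes.

```{r example}
library(foodscape)
run <- run_pipeline(city_config(seed = 1), out_dir = "runs/demo")
plot_effects(run$estimates)
```
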