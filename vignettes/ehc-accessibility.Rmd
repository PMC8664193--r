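---
title: "Measuring spatial accessibility to emergency health care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial accessibility to emergency health care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehcaccess)
```

## The problem

Where you live determines how quickly an ambulance reaches you and how
quickly you reach definitive care. Quantifying that at the level of small
population areas requires three things: a routed road network, the locations
of ambulance stations and emergency departments, and a decomposition of the
prehospital timeline into interpretable parts. This package implements that
decomposition, the spatial routing beneath it, and the statistical analyses
that turn per-area times into statements about disparities between places
and population groups.

## The prehospital timeline

For an area $i$ with network travel time $t^{st}_i$ from its nearest
ambulance station and $t^{ed}_i$ to its nearest emergency department:

$$\mathrm{RT}_i = t^{st}_i + a_i, \qquad
  \mathrm{TT}_i = t^{ed}_i, \qquad
  \mathrm{TPT}_i = \mathrm{RT}_i + \mathrm{TT}_i + s_i,$$

where the activation constant $a_i$ (time from call receipt to dispatch) is
1.4 min for urban and densely populated areas and 2.9 min for rural areas,
and the on-scene constant $s_i$ is 13.5 min (urban/dense) or 15.1 min
(rural). These are published prehospital time estimates, exposed as
overridable defaults in `time_constants()`. Both constants attach to the
*area's* type classification; a reasonable alternative would attach them at
the municipality scale, but area-level assignment keeps the composition
identity $\mathrm{TPT}_i - \mathrm{RT}_i - \mathrm{TT}_i = s_i$ exact per
area, which the test suite verifies to $10^{-9}$ minutes.

An area is *within the golden hour* when $\mathrm{TPT}_i < 60$ strictly: the
benchmark is "below one hour", so exactly 60 counts as outside. Each measure
is independently split into rank-based quintiles (`assign_quintiles()`);
quintile 5 — the longest fifth of times — defines the most underserviced
areas, modelled separately. Ties are resolved by stable original order so
group sizes never differ by more than one and results are reproducible.

## Routing

Edge travel time is $(\ell/1000)/v \times 60$ minutes for length $\ell$ (m)
and speed limit $v$ (km/h). The graph is undirected with symmetric times:
one-way restrictions, turn penalties, traffic and weather are out of scope,
so RT and TT use the same shortest paths in opposite directions. Facilities
and area centroids are snapped to the nearest junction (Euclidean, ties to
the lowest node id) so every route traverses whole segments. Closest-facility
queries are multi-source Dijkstra (`igraph::distances`) with facility ties
broken by lowest facility id; the test suite cross-checks them against an
independent Floyd–Warshall implementation on randomly generated graphs.
Areas unreachable from every facility are excluded from the statistical
stages with a warning rather than given infinite times. `build_network()`
accepts an optional set of buffer segments — roads beyond the reporting
boundary kept in the graph to avoid border effects — and flags them so
buffer areas never enter reports.

Area centroids are weighted by population: the centroid is the
population-weighted mean of the grid-cell centers inside the area, falling
back to the geometric centroid (flagged unweighted) when no populated cell
intersects. The alternative reading — the single maximum-population cell —
is defensible; the weighted mean was chosen because it is continuous in the
cell counts and robust to near-ties between cells.

## The synthetic-region generator

Real national road databases, population grids and facility registries are
not openly redistributable, so `generate_region()` produces seeded regions
with the statistical structure the analysis assumes. Design choices:

- **Network**: a perturbed lattice (grid nodes with jittered coordinates,
  ~15% random diagonal shortcuts, speed class sampled per edge from
  50/70/90/110 km/h with weights 0.35/0.30/0.25/0.10). This is planar-like,
  guaranteed connected, and mixes fast and slow roads without real data.
- **Population**: 1 km² cells; a fraction `urban_fraction` (default 0.5) of
  the population is attached to urban core(s) with exponential decay
  (`decay_km`, default 15 km) and the rest is uniform, all scaled by
  multiplicative lognormal noise (sdlog 0.5). Default mean density is held
  at ~85 persons/km² by sizing the extent as
  $\sqrt{n_\mathrm{areas} \cdot \mathrm{pop_per_area} / 85}$ when
  `extent_km` is not given — close to the ~107/km² of a mixed
  urban–rural study region, and it keeps the urban/dense/rural composition
  stable as regions scale.
- **Areas**: seed points sampled proportionally to cell population (so area
  population is roughly constant, like demographic statistical areas of
  ~1,700 residents), polygons as Voronoi cells of the seeds clipped to the
  extent (`deldir`), cells assigned to their nearest seed — consistent with
  the Voronoi partition by construction.
- **Municipalities and classification**: areas are clustered into
  municipalities (k-means on seed points, ~16 areas each). A municipality is
  *rural* when ≥50% of its population lives in low-density cells
  (default cutoff 60 persons/km², about 0.7× the mean density — calibrated
  once so a default region reproduces the qualitative composition of a
  mixed study region: roughly 30% urban, 50% densely populated, 20% rural
  areas); *urban* when <20% rural population **and** the metropolitan
  population (municipalities within 40 km) exceeds 500,000; otherwise
  *densely populated*. The commute-time criterion that real classifications
  also use is accepted as a parameter (`commute_ok_share`) but defaults to
  satisfied, since no commute model is generated.
- **Covariates**: drawn per area type from `covariate_gradients` — by
  default older-adult share 0.17 (urban) vs 0.27 (rural), highly-educated
  share 0.30 vs 0.15, median income 300,000 vs 250,000 per year, densely
  populated areas at the midpoint — emulating the usual remoteness
  gradients (older populations more rural; education and income more
  urban). Shares are truncated to (0, 1).
- **Facilities**: stations and emergency departments are placed at network
  nodes with probability proportional to local population, then jittered
  and snapped back, mirroring how facilities concentrate where people live.
  Default counts (24 stations, 5 emergency departments per 500 areas)
  preserve the areas-per-facility ratios of a realistic regional system
  (≈21 areas per station, ≈100 per emergency department).

Everything is a deterministic function of the config including its seed;
the `truth` element records the generating parameters for cross-checks.

What the generator does **not** emulate: real geography and coastlines,
one-way streets and road hierarchy topology, commute patterns, spatial
autocorrelation of covariates beyond the urban–rural gradient, ambulance
availability and queueing, and temporal variation. Passing tests therefore
demonstrate the correctness and internal consistency of the pipeline and the
detectability of injected effects — not empirical conclusions about any real
region.

## Statistical stages

**Correlation and screening.** RT–TT association uses the Pearson test.
Candidate covariates are screened pairwise: |r| ≥ 0.6 flags a pair and the
member later in a user-supplied priority order is dropped (the choice of
which member to keep is substantive, so it is a parameter, not a heuristic).

**ANOVA and Tukey.** One-way ANOVA separates each measure's variance by
area type; all pairwise contrasts use Tukey's HSD on the studentized range
distribution (`stats::aov` + `stats::TukeyHSD`, verified against explicit
sum-of-squares and `ptukey` computations on hand-worked examples).

**Disparity models.** Each measure is regressed on the covariates with a
negative binomial (NB2) model: $y_i \sim \mathrm{NB}(\mu_i, \alpha)$ with
$\log \mu_i = x_i^\top \beta$ and variance $\mu_i + \alpha \mu_i^2$.
Accessibility minutes are continuous but strongly right-skewed and
overdispersed, which is why a count model is used; minutes are rounded to
the nearest integer before fitting so the count likelihood is well defined
(at the 10–100 minute scale this loses little information). Dispersion is
estimated by maximum likelihood jointly with the coefficients
(`MASS::glm.nb`); when the theta iteration diverges — data at the Poisson
boundary $\alpha \to 0$ — the fit is completed with a pinned large theta and
the dispersion reported at the boundary. Supplying `alpha` fixes the
dispersion, and a tiny fixed value reproduces a Poisson fit (tested to
$10^{-4}$). Coefficient p-values are Wald tests; AIC/BIC count the
dispersion as an estimated parameter, and the identities
$\mathrm{AIC} = 2k - 2\ell$ and $\mathrm{BIC} = k\ln n - 2\ell$ hold exactly.

Reference categories are urban (area type) and the alphabetically first
region. Income enters in raw currency units by default — its coefficient is
then of order $10^{-6}$ and displays as 0.000 at three decimals — with an
`income_scale` flag whose only effect is to rescale that one coefficient
(verified to $10^{-8}$ on the others). In subsets, constant covariates and
aliased terms (e.g. an area type fully determined by region in a small
quintile-5 subset) are dropped automatically; when no urban areas are
present, densely populated becomes the implicit reference.

**Interaction.** The rural × older-adults interaction tests whether older
populations in rural areas are *specifically* underserved. Routed travel
times cannot carry a causal covariate effect (geometry determines them), so
the generator provides `simulate_disparity_times()`, which draws NB2
response minutes from a region's own covariates under chosen true
coefficients. With a true interaction (2.0 on the log scale, within the
range such studies report) and no true rural main effect, at study scale
(2,520 areas) the fitted interaction is positive and significant and the
rural dummy — significant when the interaction is omitted — is rendered
insignificant, the qualitative signature of an interaction-driven disparity.

## Numerical choices and degenerate inputs

- Endpoint merge tolerance in `build_network()` is 1 m (configurable);
  duplicate edges keep the fastest travel time; self-loops are dropped.
- All ties (snapping, closest facility, quintiles) break deterministically
  (lowest id / stable order): reruns are bit-identical.
- Degenerate polygons (zero area) are rejected; polygons with no populated
  cells fall back to geometric centroids.
- Constant NB responses fit at the dispersion boundary with intercept
  $\ln c$; rank-deficient designs are rejected with the collinear terms
  named.
- A constant covariate column makes Pearson r undefined; it is reported
  separately rather than silently dropped.

## Problem sizes

The test suite runs regions of 60–600 areas for unit and property tests,
100 random graphs of ≤50 nodes against the Floyd–Warshall oracle, 100
NB2 replicates at n = 2,000 for coverage/bias, and one study-scale region
(2,520 areas, 118 stations, 25 emergency departments) for quintile
bookkeeping and the interaction pattern. `scripts/acceptance.R` reruns the
study-scale region end to end. These sizes were chosen so the full suite
completes in about a minute while every stage is exercised at a scale where
its statistical behaviour is visible.

## Limitations

Beyond the generator's simplifications listed above: the model assumes an
ambulance is always available at the nearest station; all emergency
departments are treated as equally capable; air ambulances are excluded;
and the quintile and golden-hour classifications inherit the modifiable
areal unit problem — conclusions can shift with the areal subdivision, which
is why the unit of analysis is a first-class, configurable input.
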