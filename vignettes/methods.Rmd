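---
title: "Models and methods behind oroinvade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oroinvade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oroinvade` is a pipeline for macroecological analyses of alien (non-native)
vertebrates in mountain ranges. Its stages mirror the standard workflow of
this literature: spatially explicit alien-status filtering of occurrence
records, per-mountain richness and record-density summaries, biogeographic
realm flow matrices with a resampling null model, protected-area incidence,
derivation of mountain-level predictors, and negative-binomial mixed models
of alien richness. Because the real inputs (occurrence databases, IUCN/eBird
range polygons, the WDPA, a global mountain inventory, gridded climate
series) are large, versioned, and licence-restricted, the package ships a
synthetic-world generator with known ground truth; every stage is tested
against that truth or against brute-force oracles.

## The alien-status filter

A record is *alien* exactly when its point does not fall inside any
native-range polygon of its own species; records inside their species' native
range are discarded. Point-in-polygon uses the even-odd rule with the
boundary counted as inside; a point on a border shared by two mountains is
assigned deterministically to the lexicographically smallest id. Species
missing from the range set are *kept* and flagged `range_known = FALSE`:
their upstream checklist already classed them as alien, and silently
dropping whole taxa seemed worse than letting the user exclude the flagged
rows. Duplicate records (same species, same coordinates) are retained —
record density is an effort-like metric, not a richness metric. Containment
tests run in lon/lat; mountain areas are taken from the inventory attribute
and never recomputed from the polygon.

## Realm flows and their null model

A species with native realms $D$ (all realms its native polygons intersect)
and alien records in recipient realms $R$ adds one count to every cell
$(d, r)$, $d \in D$, $r \in R$; intra-realm flows are legitimate and are
retained. The null model asks whether a flow is larger or smaller than
expected from the donor realm's native pool: for each recipient realm $r$
with $k_r$ observed alien species, each of 999 draws samples $k_r$ species
*without replacement* from the global pool (a species is one entity) and
tallies their native-realm composition, multi-realm natives counting once
towards each native realm, mirroring the observed matrix. The pool is not
purged of recipient-realm natives, since intra-realm flows are part of the
observed matrices. A cell is `higher`/`lower` when the observed count is
*at or beyond* the empirical 97.5%/2.5% order statistic of the draws
("in or beyond" resolved as $\geq$ / $\leq$); a completely degenerate null
equal to the observed count stays `ns`. With integer counts this tie rule is
slightly liberal (the two tails together flag somewhat more than 5% of
truly null flows); the calibration test bounds the realised rate at
5% ± 2%. Per-taxon nulls use the class-restricted pool and are marked as an
extension in the output metadata.

## Protected areas

Kept protected areas are those with status designated/inscribed/established
(case-insensitive) and an assigned IUCN category Ia–VI; WDPA's "Not
Reported"/"Not Assigned"/"Not Applicable" count as unassigned. A record
inside several (e.g. nested) PAs counts once per containing PA; within a
category, species are de-duplicated. Area-corrected densities divide by the
summed PA-within-mountain area, computed by clipping each PA against each
(convex) mountain polygon and evaluating the area on a sinusoidal
(equal-area) projection — the only defensible projection class for km²
sums. Categories whose mountain-portion area is zero report `NA` densities
rather than infinities. The realm of a PA record is the realm containing the
record's point, not the PA centroid.

## Mountain-level predictors

* **Terrain roughness** — max minus min elevation over each cell and its
  eight neighbours; edge cells use the neighbours that exist; missing cells
  stay missing.
* **Geometry class** — from the distribution of a mountain's cell
  elevations: *hourglass* when the dip statistic exceeds 0.01 **and** the
  dip test rejects unimodality at p < 0.05, irrespective of skewness;
  otherwise *pyramid* when moment skewness ≥ 0.5, *inverse pyramid* when
  ≤ −0.5, *diamond* otherwise. Moment skewness (no small-sample correction)
  is used; samples under 30 cells are refused rather than classified.
* **Dip test** — the dip statistic is a clean-room C++ implementation of the
  published iterative convex-minorant/concave-majorant algorithm. P-values
  come from the uniform null — the conventional, asymptotically least
  favourable unimodal calibration — via a shipped plain-text table of null
  quantiles (50,000 Monte-Carlo replicates per tabulated sample size,
  regenerable with `tools/make_dip_table.R`), interpolated on the
  $\sqrt{n}\,\cdot$ dip scale; `dip_pvalue(..., n_mc = )` gives an exact-n
  Monte-Carlo alternative.
* **Climate velocity (gVoCC)** — per cell, the OLS slope of annual mean
  temperature against year (annual aggregation before trend fitting, the
  convention for gradient-based velocities computed from monthly series)
  divided by the magnitude of the spatial gradient of the time-mean field,
  from central (edge: one-sided) differences with latitude-corrected
  east–west cell widths. Cells with gradient below 1 × 10⁻⁶ °C/km are
  *undefined*, not infinite; a mountain's mean velocity averages defined
  cells only and is flagged when fewer than 25% of its cells are defined.
  The variable (minimum vs maximum temperature) is an explicit argument of
  the data layer, not hard-wired.
* **Zonal statistics** use the cell-center rule; distances to cities and
  ports are great-circle minima over the polygon boundary and interior
  (zero inside); elevation range is upper minus lower inventory limits.

## The richness model

Per-mountain alien species counts are modelled as NB2 (variance
$\mu + \mu^2/\theta$) with a log link, fixed effects for the ten predictors
(numeric predictors standardized to mean 0, SD 1 using the sample SD;
geometry categorical with *diamond* as reference), $\log(\text{area})$ as an
offset, and Gaussian nested random intercepts for system ⊂ region ⊂
continent. Numeric predictors are screened for collinearity first:
predictors are removed iteratively — always the one with the largest mean
absolute Pearson correlation to the others, ties by column order — until no
pair exceeds |r| = 0.7.

Estimation uses lme4. The default `method = "profile"` alternates
fixed-dispersion `glmer` fits (negative-binomial family) with maximum-
likelihood updates of $\theta$ until the dispersion stabilises (relative
log-change < 10⁻³), with the fast penalized-likelihood step (`nAGQ = 0`)
for the fixed effects; `nAGQ = 1` (full Laplace) and `method = "glmer.nb"`
are available but 20–150× slower at n ≈ 2000 with nearly identical
estimates (differences ~10⁻³ on standardized coefficients; the σ = 0 case
matches a plain NB regression within 0.004). Wald z statistics and p-values
are reported. Complete-case analysis is used for missing predictors; rows
dropped and the reason are counted in the fit object. Taxon-specific models
refit the same structure on the mountains with at least one alien species
of the class, re-standardizing within each subset (per-subset scaling is a
package choice; reusing cross-taxon constants would make coefficients
non-comparable within each fit). Subsets smaller than 10× the number of
fixed effects are refused. Sensitivity refits (random 80% subsets plus
drop-one-continent) report per-coefficient sign stability and the fraction
of subsets significant at p < 0.05, recording failed refits rather than
dropping them.

## The synthetic world

The generator emulates the statistical structure of the real inputs at desk
scale, with one root seed feeding named sub-streams (so adding a stage never
perturbs another's draws):

* **Realms** are a Voronoi tiling of jittered seed points (six by default),
  grouped into up to three continents; tiles are convex, which the clipping
  code exploits.
* **Mountains** are disjoint convex polygons (convex hulls of random points
  in discs), placed by rejection sampling with a minimum separation, and
  nested into systems/regions/continents by seeded k-means on their
  centers. Default 100 mountains with ≥ ~45 raster cells each.
* **Elevations**: each mountain draws its relative cell elevations from a
  class-specific distribution that *forces* its intended geometry class —
  beta(1.5, 8) (moment skew +1.06) for pyramid, the mirror for inverse
  pyramid, beta(6, 6) for diamond, and an equal mixture of beta(3, 18) and
  beta(18, 3) for hourglass. At ≥ 100 cells these choices force the correct
  class ≥ 98% of the time; the acceptance suite requires ≥ 95% on 400
  constructed samples of 150 cells.
* **Predictor rasters** are smooth random plane-wave fields transformed to
  realistic units (log-normal population/road density, logistic-bounded
  intactness and completeness, completeness trending "north" to emulate the
  hemispheric sampling bias of real inventories).
* **Climate** is a 30-year monthly stack at 0.5° (the resolution of real
  gridded climate series): base + meridional gradient (0.01 °C/km) +
  linear trend (0.02 °C/yr, a realistic contemporary warming rate) + iid
  noise (0.3 °C). A purely meridional gradient makes the closed-form
  velocity check exact under the latitude-corrected gradient estimator.
* **Species** (800 by default, class weights matching the published global
  alien vertebrate pool) get convex native ranges spanning one or two
  realms; **occurrences** are a seeded mixture: with probability
  `alien_fraction` a record is placed inside a random mountain but outside
  its species' native polygons, otherwise inside the native range. The
  generator records per-record truth flags, true flows, true per-mountain
  richness, and the generative GLMM parameters.
* **Counts**: `simulate_richness_counts()` draws NB counts from the linear
  predictor offset(log area) + Xβ + nested Gaussian intercepts, the same
  model the fitting stage assumes.

What the generator does **not** emulate: coastlines and islands, realistic
realm shapes, spatial autocorrelation of occurrence effort within
mountains, taxonomic synonymy, or casual-versus-established status. A green
test therefore establishes computational correctness of each stage's logic
and honest statistical calibration at desk scale — not that the published
effect sizes would be recovered from the real data.

## Numerical and design choices

* Thresholds default to the published constants (dip 0.01, dip-test p 0.05,
  |skewness| 0.5, |r| 0.7, 999 draws, 2.5% tails) and are echoed by the run
  manifest; any override is visible there.
* The pipeline is byte-deterministic: two runs from one config produce
  identical CSVs.
* Boundary points count as inside polygons; shared borders resolve to the
  lexicographically smallest id.
* θ is clamped to [10⁻³, 10⁶] during profiling to keep the NB family
  numerically sane; a fit whose dispersion fails to stabilise is returned
  *flagged*, never silently.
* Random-effect levels with fewer than five groups are fitted but warned
  about (variance weakly identified); boundary (singular) fits are flagged,
  with fixed effects still reported.

## Known limitations

* Polygon clipping (for PA∩mountain areas and realm intersection) is exact
  only against convex clip polygons; the synthetic inventory guarantees
  convexity, real-world use with strongly concave mountains would need a
  general clipper.
* The dip null table covers n = 30…2000 and extrapolates by using the
  nearest tabulated size outside that range.
* `nAGQ = 0` is an approximation to the Laplace fixed-effect step; the
  acceptance suite verifies bias < 0.05 and 90–99% Wald coverage at the
  scales tested, not beyond.
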