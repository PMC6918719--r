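---
title: "Habitual route networks, resource visibility and landscape models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitual route networks, resource visibility and landscape models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Group-living arboreal animals — the motivating case is the black howler
monkey (*Alouatta pigra*), an energy-minimising folivore of Neotropical
rainforests — often travel along *habitual routes*: path segments reused
across many foraging excursions. Two functional hypotheses attach to route
reuse. First, routes placed through tree-rich corridors let animals visually
monitor the phenological state of food trees (FTs) while travelling, trading
movement flexibility for a lighter memory load. Second, route placement may
avoid energetically costly landscape features (canopy gaps, steep ground)
and exploit favourable ones (elevated terrain with long sightlines).

`routescape` implements the full analysis chain needed to test these ideas
from GPS field data: kernel home ranges from scan-sample fixes, habitual
route networks from travel-bout fixes, a complete-spatial-randomness (CSR)
Monte Carlo null for food-tree interception, per-quadrat landscape
covariates including a food-tree visibility index, and
autocorrelation-adjusted mixed models for route placement. Because field
data sets of this kind are rarely deposited, the package also ships a
synthetic-data generator that plants known route networks, tree
distributions and effect sizes, so every stage can be verified against
ground truth. All coordinates are planar metric (x east, y north); CRS
transformation is out of scope.

## Route-network construction

Travel bouts are recorded as GPS fixes roughly every 20 m. Daily paths of
one sampling week are overlaid: a stretch of one path is *the same segment*
as another when it stays within a 10 m buffer of it for at least 15 m of
arc length without the local travel bearings deviating by more than 45
degrees. Bearings are estimated over a centred 10 m window on 1 m resampled
paths and compared modulo 180 degrees, so the same route walked in either
direction matches. Within a week, repeated geometry is collapsed to the
earlier day's line (rainforest food sources can make a group revisit a
stretch within days; counting those repeats would inflate usage). Across
weeks, the deduplicated weekly paths are overlaid chronologically against
the accumulating network, and every stretch of network geometry carries
`weeks_used`, the number of distinct sampling weeks that matched it. The
*habitual network* is the subset with `weeks_used >= 2`; `weeks_used >= 4`
marks high-use segments.

Two numerical choices deserve comment:

* **Representative geometry.** When a week matches an existing segment, the
  segment's stored line is updated to the running average of the matched
  weekly geometries. With independent per-fix GPS noise every weekly line is
  equally noisy; averaging k matched weeks shrinks the representative's
  error like 1/sqrt(k), so later weeks are matched against progressively
  cleaner geometry. At the study noise level this raises the
  week-to-representative match probability from roughly 0.78 to 0.93. The
  alternative (`update_geometry = "keep"`) freezes the earliest week's line.
* **Fragments.** Splitting segments where matched regions start or end can
  leave pieces shorter than 15 m. The minimum-overlap rule expresses how
  long two *paths* must run together, not a property of bookkeeping
  fragments, so a short fragment wholly covered by a matched stretch still
  gains the week; otherwise fragment counts would freeze at their creation
  value.

A travel bout counts as falling *within* the habitual network when at least
half of its 1 m stations match a habitual segment under the same
buffer-and-bearing rule; the half threshold is a package choice (the
operational definition is not fixed by convention).

## Resource metrics

* **Buffer counts and the CSR null.** Trees within 5/10/15/20 m of any
  habitual segment are counted (closed thresholds: a tree exactly at the
  radius is inside). The null scatters the same number of trees uniformly
  over the home range minus canopy gaps 10,000 times (configurable) and
  reports, per radius, the simulated mean, SD and the exceedance fraction —
  the share of simulations with at least the observed count (one-sided, in
  the enrichment direction). Both the observed and the simulated counts
  inside the null use a precomputed 1 m distance raster to the network, so
  the two sides share one discretisation and 10,000 draws stay affordable.
* **Interception rate.** Per habitual segment and buffer radius, trees
  within the radius divided by segment length (trees/m); buffer size is a
  control covariate downstream.
* **Visibility (FT-density) index.** Around each quadrat centre, concentric
  buffers every 5 m up to the 35 m visual detection distance; each buffer's
  cumulative tree count (inner trees counted again, which weights trees
  near the centre) is divided by the total FTs in the home range, and the
  seven buffer values are averaged. The index lives in [0, 1].
* **Clark–Evans Z.** The standard average-nearest-neighbour statistic
  without edge correction. Note the uncorrected statistic carries a
  positive boundary bias under CSR (about +0.8 Z units for 60 points in a
  100 m square, and the bias does not vanish with n); tests assert this
  real behaviour rather than exact standard normality.

## Landscape covariates

A 10 x 10 m quadrat grid covers each home range (cells whose centre falls
inside the 95% isopleth). Per cell: elevation by bilinear interpolation at
the centre; *relative* elevation (centre elevation minus the group minimum)
is the model covariate; slope as the 8-neighbour maximum rate of change
(arctangent of max |dz| per horizontal distance, 10 m orthogonal,
10·sqrt(2) m diagonal); canopy-gap coverage as the percentage of a 25 m
disc overlapped by gap polygons, by regular 0.5 m quadrature; route
presence/absence at the 2- and 4-week thresholds (a segment touching the
closed cell boundary counts); flags for intergroup overlap (cell centre
inside another group's range) and core-area membership (inside the 50%
isopleth).

## Home ranges

The utilization distribution is a bivariate Gaussian product-kernel density
evaluated directly on a grid (5 m default), with the reference bandwidth
`0.5 (sd_x + sd_y) n^(-1/6)` per axis. An isopleth at mass q is the
smallest-area set of cells holding fraction q of the density mass; areas
are counted on the discretized density and outlines traced by contouring,
with no polygon smoothing. The 95% isopleth is the home range, the 50% the
core. The bandwidth rule and grid resolution are conventional defaults;
reported field areas can therefore only be matched qualitatively.

## Mixed models

Three model families mirror the analysis questions:

1. **Interception vs chance** (Gaussian): per group and buffer, the number
   of FTs at observed versus simulated-mean locations,
   `count ~ location type + buffer size`, random intercept and uncorrelated
   random slopes by group.
2. **Interception vs usage** (Gaussian): `log(trees per m) ~ weeks used +
   buffer size` with the same random structure. Zero rates receive
   `log(x + half the minimum positive rate)` by default (row exclusion is
   available); the offset choice only shifts the zero class.
3. **Route placement** (binomial, logit), fitted twice for the 2- and
   4-week responses: `presence ~ sqrt(slope) + gap presence + relative
   elevation * FT density + overlap + core + autocorrelation term`, with
   uncorrelated random slopes by group.

Gaussian models are fitted by maximum likelihood (not REML) so
likelihood-ratio tests between nested fits are valid; binomial models use
the Laplace approximation (`lme4::glmer`). Covariates are z-standardized by
default (raw mode available). Full models are compared to null models
(controls only) by LRT, and per-term inference uses drop1-style LRTs that
respect marginality: an interaction is tested first and its main effects
are not individually tested while it is present. With five or fewer groups
random-effect variances are weakly identified; the model battery can also
fit a fixed-effects check (group as a fixed factor) and flags coefficient
sign disagreements.

**Spatial autocorrelation.** Route presence is spatially patchy beyond what
covariates explain. For observation i the autocorrelation term is the
average of the residuals of all other same-group observations, weighted by
`exp(-d^2 / (2 D^2))`; the focal observation is excluded from its own
average (self-inclusion would leak the residual), and observations alone in
their group get 0. The kernel SD D is chosen on a 1–30 m grid (ties toward
the smallest D) to maximise the log-likelihood of the refitted full model.
The term is computed once from the initial fit's response-scale residuals;
an iterative variant (recompute residuals from the refit and repeat) is
available behind a flag but is not the default, as the single pass is the
conventional construction and iteration rarely moves D. On data simulated
with a Gaussian residual field of 6 m scale the optimised D falls in
[3, 12] m in well over 80% of replicates, though with a mild low bias —
the grid search sees the likelihood, not the field scale itself.

## The synthetic generator

`synthetic_config()` fixes the study conditions; its defaults are the
package's reference scenario: five groups, home ranges of 7.1–15.3 ha
placed as overlapping discs, 134–227 food trees per group, terrain spanning
65–264 m elevation, canopy gaps covering 7% of the extent, 15 sampling
weeks of 4 observation days with 5 travel bouts per day, fixes every 20 m.
Bout target lengths are log-normal with mean 65.3 m and SD 57.5 m, which
also reproduces daily path lengths of a few hundred meters. GPS noise is
isotropic Gaussian per coordinate with SD 6.6·sqrt(2/pi) = 5.27 m, chosen
so the *mean radial* fix error is 6.6 m; a single isotropic Gaussian cannot
simultaneously match an error-magnitude SD of 2.3 m (the Rayleigh
constraint fixes it at 3.45 m), and the mean is the quantity the analysis
is sensitive to. Terrain is a smoothed Gaussian random field rescaled to
the configured relief; gaps are irregular non-overlapping blobs whose
summed area hits the target fraction exactly.

Route graphs are planted per group: nodes by sequential inhibition inside
the home range, a minimum spanning tree plus short chords, and mildly
curved edges (mean edge length ≈ 65 m at the default node count). Trees are
either CSR over the home range minus gaps (the null the analysis tests
against) or placed at exponential distances from the graph (enrichment).
Bouts come in two modes, because one operation cannot deliver both
distributional realism and exact planted usage counts: `"free"` draws
log-normal bout lengths and walks the graph (or, with probability
1 − fidelity, a correlated random walk with wrapped-normal turning angles,
30 degree SD — any walk matching the bout-length distribution suffices,
as no movement model is asserted); `"scheduled"` traverses each edge in
exactly its planted weeks, so weeks-used counts are exact ground truth for
recovery experiments. Scan fixes are sampled uniformly over the home range
shrunk by 10% toward its centroid, compensating the outward inflation of a
95% kernel isopleth by roughly one bandwidth, so the estimated area lands
on the planted area. Every component draws from its own RNG stream derived
from the master seed; identical configurations reproduce bit-identical
tables.

What the generator does *not* emulate: behavioural route emergence (routes
are planted, not learned), feeding bouts, group fission, temporally
correlated GPS error, canopy structure in 3-D. Passing recovery tests
therefore show that the *estimators* work under the stated noise model, not
that the ecological inference from any particular field data set is
correct.

## Verification experiments and problem sizes

The test suite's end-to-end experiments (all seeded, all generated in
code): exact agreement of the path matcher with an exhaustive brute-force
oracle on 200 random path pairs; recovery of planted weekly multiplicities
{1, 2, 4, 7} from noisy bouts over 20 seeds, requiring at least 90% of
planted habitual length to be recovered by a segment whose count is within
±1 (at the study noise level a stretch's *pointwise* distinct-week count is
itself ambiguous near junctions, so recovery asks for a matching strand
with the right count); the visibility index against its per-tree closed
form to 1e-12 on 100 configurations; enrichment detection (exceedance
≤ 0.05 at all radii for trees planted on routes) and null calibration
(mean exceedance in [0.3, 0.7] over 50 CSR tree sets at 1,000 simulations);
sign recovery and CI coverage for planted binomial effects on 5 groups x
2,000 quadrats over 200 replicates; LRT size in [0.03, 0.07] over 1,000
null replicates; autocorrelation-scale recovery over 50 replicates; and
byte-identical outputs from two pipeline runs at the same seed. The smoke
profile used for the determinism check runs two groups, six weeks and 200
CSR simulations with intercept-only random effects — two groups cannot
identify nine variance components — and completes in about half a minute.

## Known limitations

* The matcher's nearest-point search works on 1 m resampled vertices;
  distances are accurate to about half the resampling step.
* Quadrat-level gap coverage uses 0.5 m quadrature (worst-case error well
  under half a percentage point).
* The CSR null's distance raster has 1 m cells; observed and simulated
  counts share the discretisation, so the exceedance comparison is
  internally consistent.
* Wald CIs are reported for mixed-model coefficients; profile or bootstrap
  intervals are out of scope.
* The Clark–Evans statistic is uncorrected for edge effects (see above).
* No graph topology (nodes, betweenness), no directionality analysis, no
  temporal dynamics of route emergence, no viewshed computation on the DEM
  — the visibility index is a buffer construction, not a line-of-sight
  model.
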