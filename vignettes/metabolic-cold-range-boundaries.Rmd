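---
title: "Metabolic constraints on endotherm cold range boundaries: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic constraints on endotherm cold range boundaries: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldrange)
```

## The heat-balance model and its assumptions

Endotherms defend a set-point body temperature `T_b`.  Within the thermal
neutral zone, bounded below by the lower critical temperature `T_lc`,
resting metabolism sits at the basal rate `BMR`.  Below `T_lc`, heat loss
scales with the body-ambient gradient and resting metabolism must rise
linearly along the Scholander-Irving line, whose slope magnitude is the
minimum thermal conductance `C = BMR / (T_b - T_lc)` (the line through
(`T_lc`, `BMR`) extrapolates to zero metabolism at `T_b`).  At the coldest
temperatures a species experiences on its poleward range edge, `T_min`,
the model predicts a required rate `MR_CRB = (T_lc - T_min) C + BMR` and a
required elevation factor — metabolic expansibility —
`ME_CRB = MR_CRB / BMR`.  With derived conductance the factor reduces to
`1 + (T_lc - T_min)/(T_b - T_lc)`: it depends only on the three
temperatures, which is both a useful analytic identity (BMR-invariance,
property-tested in the suite) and a reminder that BMR quality issues enter
only through `T_lc` and conductance.

The model deliberately omits radiative and convective biophysics, wind,
microclimate selection, insulation differences and seasonal acclimation of
`BMR` and `C`.  Estimates are therefore upper bounds on the thermal
conditions actually experienced; species that evade cold (torpor,
hibernation, burrows, subnivean space) will appear to tolerate ambient
conditions they never face, inflating the right tail of the expansibility
distribution.  That inflation is itself informative and is what the trait
models quantify.

All metabolic rates are normalised to ml O2 h^-1 at ingest; records in
watts are converted once, at read time, with the lipid-metabolism factor
179 ml O2 h^-1 W^-1, and the original unit is retained in the table.  When
a measured conductance column is supplied it takes precedence over the
derived value — the schema should admit better data where they exist; the
derivation is the fallback, not the definition.

## Boundary extraction and species filters

Ranges are boolean presence grids aligned to the climate template
(cell-centre coordinates, north-up rows, longitudes in [-180, 180)).
Polygon ranges are rasterised by cell-centre containment, the unambiguous
convention for 5-arc-minute workflows; disjunct multi-polygon ranges are
pooled before extraction.  For every longitudinal band the single
most-poleward occupied cell forms the cold boundary; the species' boundary
temperature is the *median* of the climate values under those cells, and
the SD and mad (normal-consistent constant 1.4826 by default, configurable
to 1) quantify how well the edge tracks an isocline.  The hemisphere of
the cold edge is taken from the range centroid; ranges spanning the
equator are analysed per-hemisphere with a warning, since a single
poleward edge is not defined for them.

Species are dropped, with logged reason codes rather than errors, when
their boundary temperature is not below `T_lc` (no cold constraint is
identifiable inside the thermal neutral zone), when they are flagged as
island-restricted or continentally bounded (their edges are set by
geography, not climate), or when a residency flag marks them as
non-resident.  A run on a mixed-quality table thus succeeds with a
non-empty exclusion log, mirroring how compilation-based analyses actually
proceed.

## Distribution shape inference

The central scientific claim — a metabolic constraint — predicts a peaked,
possibly right-skewed expansibility distribution.  Four tools address it:

* **Kernel-density peak.**  Gaussian kernel, normal-reference ("Silverman",
  `bw.nrd0`) bandwidth, 512 grid points spanning the data plus three
  bandwidths each side.  Small samples can show a shallow dip at the top
  of the density; when two local maxima both reach 95% of the global
  maximum the peak is reported as the mean of the two subpeak locations
  and flagged.  The 5% relative-density criterion is this package's
  operationalisation of "two subpeaks of comparable height" (no standard
  threshold exists); it is configurable, and the raw argmax is always
  reported alongside.
* **D'Agostino skewness test** on the moment coefficient
  `b1 = m3 / m2^{3/2}` with the 1970 normalising transformation.
* **Bonett-Seier kurtosis test** on Geary's metric
  `g = mean|x - mean| / sd_pop` (`sqrt(2/pi) ~ 0.798` under normality,
  smaller for heavy tails), using
  `omega = 13.29 (ln sd - ln meandev)`, `z = sqrt((n+2)/2)(omega - 3)/3.54`.
* **Hartigan's dip test** for unimodality.  The statistic (maximum distance
  between the empirical CDF and the closest unimodal CDF) is computed
  exactly by the greatest-convex-minorant / least-concave-majorant
  algorithm, implemented in the package and verified in the test suite
  against an independent quadratic-programming oracle that encodes the
  definition directly.  The p-value is Monte Carlo against uniform null
  samples of the same size (2000 by default, seedable) rather than
  interpolated tables: reproducible, and conservative for unimodal
  non-uniform data.

All shape statistics require at least eight values and reject
zero-variance input.

The randomization null shuffles the observed boundary temperatures across
species while keeping each species' own physiology, recomputes every
expansibility (values landing inside the thermal neutral zone clamp to 1,
as in the forward model), and summarises each of 1,000 permutations by the
median or mean.  The interval reported is the 2.5-97.5 percentile range of
the replicate statistics; the percentile method is used because the
interval is a description of the permutation distribution, not an estimator
with assumed asymptotics.  An observed statistic outside the interval
indicates that boundary temperatures covary with physiology, as a
metabolic constraint requires.

## Trait models

Expansibility is regressed on log10 body mass, diet category (five-level
controlled vocabulary: granivore, herbivore, invertivore, carnivore,
omnivore; source guilds are collapsed at ingest through an explicit
mapping), nocturnality and torpor/hibernation use (a single binary trait).
Mass enters as log10 grams because metabolic allometry is multiplicative;
an identity scale is available.  Model selection fits every subset of the
candidate terms respecting marginality, ranks by
`AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, and model-averages coefficients
with "full" averaging (zeros substituted where a term is absent) over all
models within 6 AICc units of the best — the conventional defaults where
no specific choice is dictated, both configurable.  A guard refuses term
sets expanding beyond 4,096 models.  Phylogenetic regression is
deliberately out of scope; trait conservatism means phylogeny largely
re-expresses the same predictors.

## Range projection

A species' observed expansibility fixes its predicted lower thermal limit
`T_limit = T_lc - (ME - 1) BMR / C`.  Under any climate, cells strictly
warmer than `T_limit` ("warmer than", so ties are excluded) and carrying
data are thermally habitable.  Habitable cells are grouped into clumps by
8-neighbour (queen) connectivity — matching the default of the classic
raster clump tool; rook connectivity and antimeridian wrap are options,
wrap defaulting off because continental study taxa do not cross the seam.
Clump area is the raw cell count, mirroring the original raster workflow;
a cosine-latitude weighted area is provided and documented as
non-canonical.  Clumps smaller than 5% of the largest are dropped (ties at
exactly 5% are kept — the rule is "less than"), remaining clumps must
intersect the observed latitudinal extent (closed intervals), and the
result is cropped to the observed longitudinal extent, because only the
poleward edge of the projection is meaningful — the method says nothing
about warm-edge contraction, dispersal or biotic interactions.  The
projected cold-edge latitude is the median latitude of the per-longitude
poleward cells of the final mask, and shifts are signed poleward-positive
in both hemispheres (N: future - current; S: current - future).  Empty
projections (a thermal limit warmer than every cell, or no overlapping
clump) are flagged, propagate `NA` shifts, and are excluded from shift
averages.

## The synthetic world

The generator builds the statistical structure the analysis assumes, with
known ground truth, so every stage is testable without downloads:

* **Climate**: `T_min(lat) = 25 - 0.5 |lat| + eps`, `eps ~ N(0, 0.5 degC)`
  cell-wise, on a 180 x 360 grid at 0.5 degrees (one hemisphere, 180
  degrees of longitude).  The future scenario adds a uniform +2 degC to
  the *same* noise realization, so the isocline displacement is exactly
  `2 / 0.5 = 4` degrees.  The 0.5 degC/degree gradient is a realistic
  mid-latitude lapse of minimum winter temperature; the noise SD keeps
  boundary mads near a degree, comparable to real boundary spreads.
* **Physiology**: `T_b ~ N(38, 1)`, `T_lc ~ N(28, 3)` truncated at least
  2 degC below `T_b`, mass log-uniform on 5 g-5 kg, and
  `BMR = 3.5 mass^0.72 e^eta` with `eta ~ N(0, 0.15)` — a standard
  endotherm allometry with realistic scatter.  A quarter of species get a
  summit metabolism near five times BMR.
* **True expansibility**: `ME = 1 + LogNormal(1.0, 0.4) + 1.5 torpor -
  0.5 (log10 mass - centre)`, i.e. a right-skewed baseline (mean near 4,
  skewness near 1.3) plus a positive torpor effect and negative mass
  effect of known size.  Draws below 1.05 or whose isocline leaves the
  grid are redrawn with a bounded retry budget.
* **Ranges**: each species occupies a random longitudinal window and all
  rows equatorward of its thermal-limit isocline, with per-column edge
  jitter of SD 1 cell by default.

All randomness flows from one master seed through named substreams
(climate, physiology, edges), so stages can be regenerated independently
and a fixed seed reproduces the world byte-for-byte.  The default problem
sizes — 100 species on the 0.5-degree grid, 1,000 permutation replicates,
2,000 dip null replicates — run the full pipeline in tens of seconds while
exhibiting every behaviour of interest; the recovery tests use 200 species
where the torpor-effect standard error needs to be small.

What the generator does *not* emulate: continental outlines and coastline
masks, IUCN polygon topology, spatial autocorrelation of climate beyond
the latitudinal gradient, seasonal acclimation, and any correlation
between traits and physiology beyond the built-in effects.  Passing tests
on synthetic worlds therefore demonstrate that the pipeline recovers the
model's quantities when the model's assumptions hold; they do not validate
the biological assumptions on real data.

## Numerical choices and degenerate inputs

* Grids must be regular with square cells; coordinates are cell centres;
  masks are aligned by template equality (resampling is the caller's
  responsibility at ingest).
* ESRI ASCII grids are written with 17 significant digits so write/read
  round-trips are bit-exact; integer tenth-degree climate dialects are
  handled by a read-time scale factor.
* `estimate_conductance` rejects `T_lc >= T_b`; boundary rates with
  `T_min >= T_lc` return BMR plus a within-TNZ flag instead of erroring;
  `thermal_limit` rejects targets below 1.
* The dip statistic is 0 for constant samples and 0.25 for two distinct
  points; Monte Carlo p-values use the add-one estimator
  `(1 + #{D_null >= D})/(1 + B)`.
* Zero-variance samples are rejected by all shape statistics rather than
  returning NaN.
* The kde subpeak rule always reports the unaveraged argmax as well, so a
  downstream consumer can ignore the averaging convention.

## Known limitations

* Only ESRI ASCII rasters and GeoJSON polygons are read natively; other
  formats should be converted upstream.
* Warm-boundary expansibility is a coarse, optional analogue
  (`warm_expansibility`); most species never exceed their upper critical
  temperature at the warm edge, and evaporative-cooling limits are not
  modelled.
* Equator-spanning ranges are handled per-hemisphere; pooling their two
  cold edges into one species-level summary is intentionally not done.
* Clump areas as cell counts overweight poleward cells on geographic
  grids; use the cosine-latitude option when absolute areas matter.
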