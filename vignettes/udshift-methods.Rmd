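---
title: "Quantifying distribution shift with UD overlap: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying distribution shift with UD overlap: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udshift)
```

## The question the package answers

Populations of wide-ranging wildlife — the motivating case is central
mountain woodland caribou monitored by GPS collars — may respond to a
growing industrial footprint (forestry cutblocks, roads, well sites) not by
tolerating it but by shifting where they live. `udshift` measures that
response *spatially*: it estimates seasonal population utilization
distributions (UDs) year by year, treats the footprint's density surface as
a "pseudo-UD" on the same grid, and tracks overlap indices between the
population UD and (i) the footprint, (ii) a baseline-era range, and
(iii) static habitat (the alpine zone), regressing each series on year and
an interannual climate index.

## Utilization distributions

Individual UDs are fixed-kernel density estimates with a product Gaussian
kernel evaluated at the centers of a shared 250-m grid,

$$\hat f(c) = \frac{1}{n\,h_x h_y}\sum_{k=1}^{n}
  \phi\!\Big(\frac{x_c-x_k}{h_x}\Big)\phi\!\Big(\frac{y_c-y_k}{h_y}\Big),$$

with per-axis Sheather–Jones direct plug-in bandwidths
(`KernSmooth::dpik`). Choices that matter:

* **Diagonal bandwidth.** The plug-in is computed independently for the x
  and y marginals. Full 2×2 bandwidth matrices are out of scope; for
  seasonal ranges elongated along a valley axis the diagonal choice is the
  standard home-range workflow.
* **Midpoint rule.** A cell carries the density at its center, not the
  cell-integrated kernel. The discretized mass then differs from 1 by less
  than about 1e-3 whenever `h` is at least the cell size; `kde_ud()`
  *errors* when the grid mass leaves that band (which also catches
  inadequate padding) and deliberately does not renormalize, so grid values
  equal the kernel sum exactly — conversions to unit-sum `mass` surfaces
  renormalize instead.
* **Sample-size rules.** UDs are refused below 50 locations; individuals
  whose collars do not span a season (1-day tolerance at each end) are
  excluded; strata that end up with a single UD are excluded from
  population averaging. All three rules are hard errors or recorded skips,
  not silent drops.
* **Master grid.** One grid per run — the bounding box of all filtered
  fixes padded by 6 km (comfortably more than 3 bandwidths), origin snapped
  to the 250-m lattice shared with the landscape rasters, so every UD,
  habitat mask and disturbance surface is co-registered by construction.
  Co-registration is *checked*, never repaired silently.

Population UDs average the 0–1 rescaled individual UDs (removing
sample-size and fix-rate imbalance between animals) and rescale the mean to
sum to one. The baseline surface applies the same construction to all
individual UDs of the early era (default 1998–2005). Representation tags
(`density`, `mass`, `scaled01`, `proportion`, ...) travel with every raster
and each operation states which representation it requires.

Home ranges are 95% isopleths: cells ranked by mass, shortest prefix
reaching the level. Ties at the boundary value are resolved
deterministically by cell index (minimal home range); a conservative
`ties = "all"` variant includes every tied cell. The minimal-prefix rule is
the one under test: removing the smallest member must drop the mass below
the level, and a uniform 100-cell surface yields exactly 95 cells.

## The disturbance pseudo-UD

The cumulative footprint (features never expire; features predating the
study enter through their earlier creation year) is rasterized at 50 m with
a cell-center rule. Well sites supplied as points are buffered to squares
of 0.0158 km² — the average well-pad footprint — and road centerlines to a
20-m width. A circular moving-window mean with 1-km radius turns the binary
raster into the proportion of disturbed habitat within 1 km; at the raster
edge the mean runs over in-extent cells only, so a fully disturbed
landscape maps to 1 everywhere. The surface is block-mean resampled to the
250-m grid (which conserves the global mean exactly) and rescaled to sum to
one. The moving window is an FFT convolution with a disc kernel; it matches
direct counting to round-off, and a 1e-6 floor separates true zero
proportions from FFT noise when the "any disturbance within 1 km" region is
thresholded.

## Overlap indices

For a population UD $i$ (mass $p_i$, density $f_i = p_i/a$ with $a$ the
cell area) and a region $R$:

* **PHR** $= \sum_{c\in R} p_i(c)$ — directional, in $[0,1]$, monotone in
  the region. Regions: the alpine mask itself, the any-disturbance zone,
  or the baseline UD's 95% isopleth.
* **UDOI** $= A_{ij}\sum_c f_i(c)f_j(c)\,a$ with $A_{ij}$ the intersection
  area of the two supports — symmetric, 0 for disjoint surfaces, exactly 1
  for identical uniform surfaces, and above 1 for coincident peaked ones.
  Because the index is defined on home-range overlap in its source
  literature, a 95%-isopleth variant of $A_{ij}$ is provided
  (`region = "isopleth"`); the support intersection is the default and the
  one used in the pipeline, with sub-1e-12 masses treated as unoccupied.

Baseline comparisons are restricted to the contemporary era (default
2006–2013) because the baseline itself is built from 1998–2005 data.

## Season delineation

Seasons are cut from each individual's daily movement-rate series (path
length per elapsed time, assigned to the later fix's date, in km/day — the
standard activity measure; the rate series is NA where no step ends).
Day-of-year is treated as a circle so a winter season spanning the year end
stays one segment. The partitioner first finds the best *pair* of cuts
exhaustively (a single cut cannot split a circle), then splits arcs
greedily, each split maximizing the SSE reduction of a piecewise-constant
fit; a split must recover at least 5% of the current total SSE
(cost-complexity pruning, configurable) and respect a 14-day minimum
segment. Decisions are invariant to uniform rescaling of the rates. The
exhaustive-pair-then-greedy design was chosen over segmenting a duplicated
two-year series because it has no artificial boundaries at the unroll
points; a linear mode remains available and is held to within 5% of an
exact dynamic-programming segmentation in the tests. Population onsets
aggregate individual onsets by clustering them at the k largest circular
gaps and taking the circular median per cluster (mean available).

## Trend models

Overlap series are regressed on year and the climate index by OLS, one
model per herd × season × index × target. Individual-level metrics
(season-mean movement rate, home-range size, mean elevation at fixes,
conifer/nonforest use, proportion of the home range disturbed) are fitted
with `lme4` linear mixed models, REML, random intercept per individual and
no random slopes. Both report Wald 95% intervals ($\beta \pm 1.96\,SE$) and
flag a term as supported when its interval excludes zero; no
multiple-testing correction is applied, matching the reporting convention
the package mirrors. Supporting rules implemented exactly as stated: the
pairwise VIF screen ($1/(1-r^2) < 3$) that justifies keeping year and the
climate index together despite $r \approx 0.56$; and the home-range-size
outlier rule (drop a record more than double the largest of the others),
generalized to reapply until stable. The climate index of the winter
ending in year $Y$ is joined to all seasons of year $Y$; a lag-1 join is a
configuration away, since the correct alignment is genuinely ambiguous.

## The synthetic study system

Real telemetry for the motivating system is confidential, so the generator
produces a fully ground-truthed stand-in:

* **Landscape.** 40 × 40 km, linear west-to-east elevation ramp 800–2400 m
  with smooth seeded noise, alpine above 1950 m (~28% of the area),
  conifer below a 150-m treeline band, nonforest above.
* **Movement.** Discrete-time mean-reverting (OU-like) walk toward the
  current season's center; six seasons with onsets
  {36, 125, 152, 171, 281, 333} (the six-season calendar of the motivating
  study: late winter, spring, calving, summer, fall, early winter). Winter
  centers sit mid-slope, summer centers near the alpine edge ~10 km
  upslope. Per-step dispersion 600 m per 8-h fix with mean reversion 0.05
  gives a stationary spread ≈ 2 km — individual seasonal ranges of order
  10–100 km², realistic for mountain caribou — and season-specific
  dispersion multipliers make migration seasons measurably faster, which
  is the signal the segmentation module recovers. Between-individual
  center scatter is 4 km; collar deployments default to one calendar year
  (the motivating study followed individuals for at most two), making
  year-to-year population UDs independent, which is what the no-shift
  null expects; the pipeline demo uses two-year deployments so the mixed
  models have repeated measures. DOP values are lognormal with ~90% of
  draws below the 10 cutoff, so the filter is exercised without dominating.
* **Shift.** Winter centers translate uphill by `shift_rate` m/yr — the
  single ground-truth dial the detection machinery must recover (0 under
  the null; 1000 m/yr in the strong-shift scenario, i.e. 15 km over 16
  years, comparable to a documented decadal range displacement).
* **Footprint and climate.** 10 km²/yr of new features placed in the
  lowest 40% of the elevation distribution (cutblocks 300–800 m rectangles,
  0.0158-km² well squares, 1.5–3 km roads); an annual climate index built
  to correlate with year at exactly r = 0.56.

What the generator does *not* emulate — behavioral avoidance of
disturbance, terrain-dependent movement, fix-rate heterogeneity between
collars, collar failure clusters — bounds what passing tests show: they
validate the estimators and the inference chain, not ecological realism.

## Numerical choices and limitations

* Midpoint-rule KDE (above); padding adequacy enforced at 1e-3 of mass.
* Masses below 1e-12 are unoccupied for support determination; FFT-derived
  proportions below 1e-6 are zero.
* Rasterization is cell-center-in-feature at 50 m; union areas and
  percent-within-1-km are therefore rasterized approximations (checked at
  ~1% against closed-form geometry at 10-m resolution in the tests).
* Problem sizes: the end-to-end calibration experiments use 2 herds × 16
  years × 20 individuals/herd on the 40 × 40 km landscape with one focal
  season (late winter), 50 no-shift and 20 strong-shift replicates — a
  replicate count chosen so a binomial check can place the nominal 5%
  type-I rate inside 1–10% and sign recovery above 90%.
* The season partitioner is a greedy approximation; its SSE is checked
  against an exact DP oracle only for small k. Aggregation assumes
  individuals share one calendar; partial migrants would need per-cluster
  membership weights.
* No boundary correction in the KDE; ranges hard against the landscape
  edge would bias densities inward (the generator keeps centers 2 km
  inside the extent).

## Reading the pipeline output

`run_pipeline()` writes, per run: `telemetry.csv`, `seasons.yaml`,
`overlap.csv` (herd, season, year, index, target, value), `metrics.csv`,
`trends_overlap.csv` / `trends_metrics.csv` (tidy coefficient tables with
`supported` flags), GeoJSON footprint, climate CSV, optional `.asc`
rasters, and `manifest.json` recording the config digest, seed, package
version and per-stage record counts — enough to reproduce the run exactly.
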