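---
title: "River-constrained kernel home ranges from crocodile GPS telemetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{River-constrained kernel home ranges from crocodile GPS telemetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adult estuarine crocodiles (*Crocodylus porosus*) are strictly river-bound:
every movement is a path along a branching channel network, never across
land. GPS tags report twice-daily planar fixes, so three things go wrong if
telemetry for such an animal is analysed with generic home-range tools:

1. a two-dimensional kernel utilisation distribution (KUD) spreads mass far
   onto land, overstating the area actually available;
2. straight-line step distances undercut the distance actually travelled
   along a sinuous channel; and
3. behavioural structure — a resident male patrolling a territory versus a
   nomad ranging through the whole catchment, or a female leaving her
   breeding core to nest tens of kilometres away — is invisible in a single
   whole-study range estimate.

`crocspace` implements a pipeline that addresses all three: SDOP quality
filtering, fixed-kernel KUDs whose volume contours are clipped to a
rasterised river channel, along-river (least-cost) movement metrics through
a water-cell graph, cumulative monthly range series with a
stability-based classification into *site-fidelic* and *nomadic* ranging
strategies, and detection of long-range nesting excursions. Because the
original field data were never deposited, the package also contains a
first-class synthetic river and movement simulator, so every stage is
verifiable against ground truth.

## The estimator chain

### SDOP filter

Each fix carries a satellite dilution of precision (SDOP) value; stationary
tag tests put the accuracy of fixes at SDOP ≤ 3 near 12 m. `filter_fixes()`
retains fixes with SDOP ≤ `sdop_max` (default 3) inside the study window
(default 01 September – 28 February) and reports the removed fraction.
Filtering is idempotent and never silently drops a fix: retained plus
removed always equal the in-window total.

### Fixed-kernel KUD and volume contours

`estimate_kde()` uses the fixed-kernel estimator: an isotropic bivariate
Gaussian kernel with a single global bandwidth, evaluated at the centres of
a 50 m grid covering the fix bounding box padded by `4h` (truncated tail
mass < 1e-4), then normalised to unit mass. The Gaussian factorises, so the
surface is a cross-product of per-axis kernel matrices — algebraically
identical to the double loop over cells and fixes (the test suite checks
agreement with a literal double loop at 1e-10 relative error), but it runs
through BLAS.

The default bandwidth is `h = 750` m. Two data-driven selectors are
provided as diagnostics only (`h_lscv()`, `h_ref()`), and neither is a
default on purpose: on a river-bound range least-squares cross-validation
fragments the distribution into disjunct contours that exclude connecting
stretches of river, while the reference bandwidth spreads mass far beyond
the outermost fixes. A fixed intermediate bandwidth keeps the home-range
boundary contiguous along the channel while respecting the outermost
locations.

A level-*p* volume contour (`volume_contour()`) is the smallest cell set
holding at least *p* of the mass: cells accumulated in decreasing density
order, ties broken deterministically by (row, column). Contours are cell
sets, not interpolated isopleths — area is cell count × cell area. This
choice makes the subsequent river clip exact: every grid in the package
(river mask and all KDE surfaces) lives on one global 50 m lattice anchored
at the origin, so `clip_to_river()` is a key intersection, and
`reduction_percent` records how much kernel area fell on land. Clipping is
contour-then-intersect (the density is never re-normalised after clipping);
the 50%-within-95% nesting therefore survives clipping.

### Along-river distances

`rasterize_river()` marks a cell as water iff its centre lies inside the
channel; `build_graph()` connects neighbouring water cells under
8-connectivity with centre-to-centre weights (cell size for rook moves,
√2 × cell size for diagonals), keeping the largest connected component with
a warning if the rasterisation fragments. 4-connectivity is available but
not the default: on a sinuous channel it overestimates distances by up to
41% (the L1/L2 ratio), while 8-connectivity stays within ~8%. Fixes are
snapped to the nearest water-cell centre (`snap_to_river()`, deterministic
(row, col) tie-break, snap distance logged for audit) rather than
discarded. `river_distance()` is then the shortest path through the graph —
symmetric, triangle-obeying, and never less than the straight-line
distance; the tests pin it to a plain Floyd–Warshall oracle exactly.

### Movement metrics

`step_distances()` measures each consecutive-fix pair along the river and
labels the interval by its closing fix: the 08:00 fix closes the 14 h night
interval, the 18:00 fix the 10 h day interval. The day/night boundary is
aligned with the fix schedule because the observation design cannot
attribute movement within an interval any more finely. Rates of movement
divide by the actual interval duration, not a nominal 12 h. Intervals
longer than 36 h (missed fixes) are excluded from ROM means — a gap averaged
over its full span would bias speed downward — but still count toward total
distance. The distance-from-centroid series is measured from the centroid
of the *September* (first-window) river-clipped KUD 50%: the early-season
core is the biologically meaningful origin for "exploratory movement", and
a full-study centroid would be dragged toward any permanent late-season
relocation, masking exactly the excursions the series is meant to reveal.
The centroid is density-weighted (a geometric option exists) and snapped to
water so along-river distances from it are defined.

### Strategy classification

`cumulative_kuds()` re-estimates the KUD over six nested windows (01 Sep to
the end of each month through 28 Feb). `classify_strategy()` calls an
individual site-fidelic iff the relative growth of the clipped cumulative
KUD 95% area over the trailing `k_tail` windows is ≤ `tau` (default 0.15).

The default `k_tail` spans the whole series (growth since the first
window). This was a deliberate design decision taken during simulator
calibration: for a diffusively wandering nomad the growth ratio over a
short trailing tail (e.g. the last three windows) is a scale-free statistic
with enormous spread — around a third of genuinely nomadic simulated tracks
show < 15% growth over the final three windows at *any* speed or
persistence setting, simply because a random wanderer often revisits ground
late in the record. Growth measured from the first window separates the
regimes reliably (≈ 98% correct labels at the default effect sizes, versus
≈ 67% for the three-window tail), and matches the visual criterion the
field actually uses: whether the cumulative range curve has flattened over
the study as a whole. `k_tail` remains a parameter, so the short-tail
variant is one argument away, and every label is reported together with its
`growth_stat`, `tau` and `k_tail`.

Females are classified on the September–November (breeding season) windows
only: their range is expected to be stable during breeding and then to
expand ~30% when nesting movements begin in December, so a full-series
stability test would mislabel every nesting female as nomadic.

### Excursion detection

`detect_excursions()` thresholds the centroid-distance series at
`multiplier` (default 3) × the 95th percentile of the baseline
(September–November) distances. A maximal run of fixes above threshold is
one excursion; it `returned` if the series comes back below threshold
before the record ends. Nesting is deliberately *not* inferred — no nest was
observed — so trips are reported neutrally with start, end, peak distance,
duration and return flag.

### Group summaries

`group_summary()` reports mean ± SE per metric per group, with SE = sample
SD (n−1 denominator) / √n, the standard "mean ± S.E." convention. The
derived `kud50_over_kud95_percent` is computed per individual, then
averaged. The per-individual summary table of the original study is
packaged verbatim (`table1_fixture()`) as the worked example for this
stage, because the underlying telemetry was never deposited; the three
males whose cumulative KUD had not stabilised form the nomadic group.

## The simulator: what it emulates and what it does not

`generate_river()` builds a synthetic stand-in for a branching estuarine
catchment: a meandering main channel of exactly the requested length
(default 150 km), optional tributaries (default 2), and a channel width
tapering from 400 m at the mouth to 150 m upstream. Movement is simulated
in one dimension along the network and mapped to planar coordinates on the
centreline — the defining constraint of the system — and observed through
the study's schedule: fixes at 08:00 and 18:00 (362 per animal over 181
days), isotropic 12 m error for good fixes, and 7% poor fixes at 250 m
error with SDOP drawn above 3. The poor-fix error scale is arbitrary but
deliberately much larger than the good-fix scale, so the SDOP filter
measurably improves accuracy.

The three regimes and their default parameters (frozen after a one-off
calibration whose only aim was clear qualitative regime signatures —
no parameter was tuned to reproduce any published magnitude):

* **site-fidelic male** — mean-reverting (Ornstein–Uhlenbeck-like) walk
  about a territory centre; stationary SD 0.8 km; hourly step SD 250 m/h by
  day, 350 m/h by night. The per-step autocorrelation is solved from the
  step-size mix so the stationary scale is exact, and it mixes in ~half a
  day, so the first monthly window already samples the full territory and
  the cumulative range curve is flat from the start.
* **nomadic male** — persistent directional walk (direction kept with
  probability 0.9 per hour, i.e. ~10 h legs), steps 200/330 m/h, branches
  chosen uniformly at confluences, reflection at channel ends. Over six
  months this wanderer explores a ~40–90 km span of a 217 km network, so
  its cumulative KUD 95% roughly doubles after November while never
  saturating the river.
* **breeding female** — the mean-reverting walk (scale 0.5 km, steps
  50/60 m/h, matching a breeding core under 1 km of river) plus scheduled
  excursions: directed travel at 1.5 km/h to a destination 20–45 km away,
  a dwell (36–72 h for reconnaissance trips), and either a return or a
  permanent stay. The default cohort gives three females a December
  reconnaissance trip followed by a permanent January move to the same
  site, and one female a single permanent January move — the repeated-visit
  pattern reported for wild females.

The default cohort (5 site-fidelic males, 3 nomadic males, 4 females,
01 September – 28 February) mirrors the tracked study group. Territory
centres are spread 20–115 km along the main channel, so simulated
site-fidelic cores are mutually disjoint; the partially overlapping male
territories of the real study are *not* emulated, and neither are tides,
salinity, agent interactions, energetics, or any real-world geography.
Passing tests therefore demonstrate that the estimator chain recovers the
structure this generator encodes — regime-true labels, scheduled trips,
configured error rates — not that it would recover them from data with
tidal drift, habitat preference or socially coupled movement.

## Numerical choices and degenerate inputs

* Grids: one global 50 m lattice anchored at (0, 0); every surface and mask
  aligns to it, so clipping and overlap are exact set operations.
* KDE: at least 5 fixes per surface (below that the estimator refuses —
  a 2-D bandwidth has no meaning for fewer points); all-identical fixes are
  legal and give a single peak. Surfaces sum to 1 within 1e-9.
* Contours: greedy prefix with (row, col) tie-break, so repeated runs are
  byte-identical; removing the last-added cell always drops below the
  level (minimality, tested).
* Shortest paths: Dijkstra on the water graph; unreachable pairs cannot
  occur after largest-component selection and raise an error if forced.
* Windows with < 5 fixes yield `NA` areas with a warning; classification
  returns `unclassified` when the windows it needs are missing.
* All simulation randomness flows through explicit seeds; the
  simulate–observe chain is bit-reproducible, and `run_pipeline()` consumes
  no randomness at all.

## Problem sizes

The shipped analysis and acceptance runs use the default system: a 217 km
network rasterised to ~21,500 water cells (~73,000 graph edges), 12 animals
× 362 fixes, six cumulative windows per animal, and 20 replicate cohorts
for the recovery experiment — the cohorts re-randomise animals and
observation on a fixed river, as replicate field seasons on the same
catchment would. A full cohort pipeline takes ~15 s on one core; the
20-cohort recovery experiment ~5 minutes.

## Known limitations

* The KUD is the plain fixed-kernel estimator; temporal autocorrelation in
  twice-daily fixes is not corrected, and Brownian-bridge or dynamic UD
  models are out of scope.
* Clipping intersects contours with water *after* contouring; mass is not
  re-normalised onto the river, so clipped "areas" are conservative and
  comparable to the published convention, but they are not a UD over the
  network.
* Along-river distance is raster least-cost, not a vector network
  distance; at 50 m cells and 8-connectivity the discretisation error on a
  smooth channel is below 10% (tested by cell-size halving).
* The day/night interval labelling attributes each inter-fix span wholly
  to the interval that closes it; with two fixes a day nothing finer is
  identifiable.
* Body-mass allometry is a pluggable hook with no default coefficients, as
  the conversion used by the original study is not published with it.
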