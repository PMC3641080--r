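# crocspace

River-constrained kernel home ranges and along-river movement metrics from
GPS telemetry of estuarine crocodiles (*Crocodylus porosus*).

Adult *C. porosus* are strictly river-bound, so generic home-range tools
mislead twice over: a two-dimensional kernel utilisation distribution (KUD)
spreads most of its mass onto land, and straight-line step distances
undercut travel along a sinuous channel. This package implements, as a
tested and reusable pipeline, the analysis chain of a GPS-tracking study of
twelve adult crocodiles monitored twice daily through a breeding and
nesting season (01 September – 28 February) in a branching estuarine river:

* **Quality filtering** — fixes with satellite dilution of precision
  (SDOP) ≤ 3 retained (stationary tests put their accuracy near 12 m);
  the removed fraction is reported per individual.
* **Fixed-kernel KUD** — isotropic bivariate Gaussian kernel with a single
  bandwidth *h* = 750 m on a 50 m grid; the 95% and 50% *volume contours*
  are the smallest cell sets holding 95% / 50% of the mass (cells
  accumulated in decreasing density order).
* **River clipping** — contours intersected with a rasterised channel mask
  on the same 50 m lattice; the reduction percentage documents how much
  kernel area fell on inaccessible land (≈ 90% for the KUD 95% here).
* **Along-river metrics** — water cells form a graph (8-connectivity,
  √2-weighted diagonals); the minimum distance between fixes is a shortest
  path through it. Day (08:00→18:00) and night (18:00→08:00) rates of
  movement use the actual 10 h / 14 h durations; each fix's along-river
  distance from the September core (KUD 50%) centroid tracks exploratory
  movement.
* **Strategy classification** — the cumulative monthly KUD 95% series
  stabilises for *site-fidelic* animals and keeps climbing for *nomadic*
  ones; the label is `site_fidelic` iff relative growth of the series is
  ≤ τ = 0.15.
* **Excursion detection** — runs of centroid distances above 3× the 95th
  percentile of breeding-season (Sep–Nov) distances, with a
  returned/permanent flag — the signature of long-range nesting trips.
* **Synthetic study system** — the original telemetry was never deposited,
  so a first-class simulator generates a branching estuarine river and
  three movement regimes (mean-reverting residents, persistent nomads,
  females with scheduled nesting excursions) observed through the study's
  schedule and error model, giving every stage a ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study end to end
(`01_simulate.R` … `06_group_summaries.R`), writing tables under
`results/`. In miniature:

```r
library(crocspace)

river <- generate_river(default_river_spec())   # 150 km main channel + 2 tributaries
mask  <- rasterize_river(river)                 # 50 m water mask, 21,537 cells
sim   <- simulate_cohort(river, seed = 42)      # 12 animals x 362 fixes
res   <- run_pipeline(sim$fixes, mask, metadata = cohort_metadata())

res$summary[res$summary$id %in% c("M1", "M4", "F2"),
            c("id", "night_rom_m_per_h", "kud95_km2", "max_dist_centroid_km", "strategy")]
#>   id night_rom_m_per_h kud95_km2 max_dist_centroid_km     strategy
#>   M1            155.41   27.1725                81.44      nomadic
#>   M4             55.29    1.8350                 3.42 site_fidelic
#>   F2             31.27    2.9150                31.84 site_fidelic
```

The nomadic male M1 ranges 81 km from his September core and his
cumulative KUD 95% grows 144% after November (`res$classification`), while
the site-fidelic M4 stays within ~3 km of his centroid inside a stable
1.8 km² river range — 88% of his unconstrained kernel area lay on land and
was clipped away. Female F2 holds a sub-kilometre breeding core but makes
the two scheduled nesting trips ~32 km downriver, the December one
returning within 58 h, the January one permanent:

```r
res$excursions[res$excursions$id == "F2", c("start_time", "peak_dist_km", "returned")]
#>            start_time peak_dist_km returned
#>   2010-12-12 08:00:00     31.54         TRUE
#>   2011-01-02 08:00:00     31.84        FALSE
```

The published study's group statistics are arithmetic over its printed
per-individual table, which ships as a fixture:

```r
gs <- group_summary(table1_fixture())
group_mean(gs, "nomadic_male", "night_rom_m_per_h")        # 384.3 m/h
group_mean(gs, "site_fidelic_male", "max_dist_centroid_km") # 15.4 km
```

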