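# conemosaic

Spatial statistics for cone photoreceptor mosaics represented as planar
point patterns.

In some retinal degenerations (e.g. the S334ter rat model of retinitis
pigmentosa), surviving cones abandon their even tiling and cluster on the
rims of photoreceptor-free holes — "cone rings". Treatments that loosen the
glial scaffold disperse the rings back into a homogeneous mosaic at
essentially unchanged density. `conemosaic` quantifies that difference from
a plain table of cell coordinates over a rectangular sampling field:

- **Voronoi-domain analysis** — each cell's domain polygon, clipped to the
  window, with boundary-cell exclusion ("edge correction");
- **g1 skewness** of the domain-area distribution,
  `g1 = m3 / m2^(3/2)` with biased (1/n) central moments — the long right
  tail left by empty ring centres;
- **coefficient of clustering (CC)** — the global coefficient of variation
  of domain areas divided by the mean local CV among each cell's Voronoi
  neighbours:
  `CC = (sigma_x / x_bar) / ((1/n) * sum_i sigma_ai / a_bar_i)`.
  CC sits near its random-mosaic baseline (~1.2) for homogeneous fields and
  rises towards ~1.8+ when small and large domains segregate into ring
  patterns;
- **group summaries** — per-group mean ± SEM and two-sample (Student or
  Welch) t-tests with the field/animal as experimental unit;
- **readers** for coordinate tables (CSV/TSV/XLSX) and for "white-dot"
  annotation images (one painted dot per cell body);
- a **seeded synthetic generator** of ring-clustered, hard-core homogeneous
  and Poisson mosaics at matched density, with per-point ground truth.

## Worked example

```r
library(conemosaic)

# a ring-patterned field and a homogeneous field at the same density
ring <- generate_mosaic(synthetic_config("ring", seed = 1))
hom  <- generate_mosaic(synthetic_config("homogeneous", seed = 1))

analyze_field(ring)
#> mosaic_statistics (ring)
#>   cells:     5600 total, 5383 interior (window_touch)
#>   density:   5600.0 cells/mm^2
#>   g1 skew:   2.050
#>   CC:        1.836 (sample SD, neighbours: all)

analyze_field(hom)
#> mosaic_statistics (homogeneous)
#>   cells:     5600 total, 5325 interior (window_touch)
#>   density:   5600.0 cells/mm^2
#>   g1 skew:   0.920
#>   CC:        1.190 (sample SD, neighbours: all)
```

Both fields hold 5,600 cells over 1×1 mm — identical density — yet the ring
mosaic's CC (1.84) and g1 (2.05) are far above the homogeneous values (1.19
and 0.92): the statistics see the arrangement, not the amount. A two-group
comparison across replicate fields:

```r
ring_cc <- sapply(1:3, function(s)
  analyze_field(generate_mosaic(synthetic_config("ring", seed = s)))$cc)
hom_cc <- sapply(1:3, function(s)
  analyze_field(generate_mosaic(synthetic_config("homogeneous", seed = s)))$cc)
compare_groups(ring_cc, hom_cc)
#> a: 1.845 +/- 0.01918 (mean +/- SEM, n = 3)
#> b: 1.193 +/- 0.002042 (mean +/- SEM, n = 3)
#> Student (pooled) t-test: t = 33.85, df = 4, p = 4.543e-06 (significant at alpha = 0.05)
```

Real data enter through `read_coordinates()` (per-field coordinate tables;
`unit_scale` and a window override handle tables recorded in pixels) or
`detect_dots()` (annotated dot-map images). A command-line surface is
installed as `exec/conemosaic` with subcommands `analyze`, `simulate`,
`compare`, `histogram` and `dots2coords`.

See the vignette `vignettes/voronoi-domain-analysis.Rmd` for the model,
conventions, and the calibration of the synthetic generator.

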