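---
title: "Voronoi-domain analysis of cone photoreceptor mosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi-domain analysis of cone photoreceptor mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conemosaic)
```

## The problem

In several retinal degenerations, cone photoreceptors outlive the rods and
then remodel: instead of tiling the retina evenly, they gather on the rims of
roughly circular, photoreceptor-free holes, producing an orderly array of
"cone rings". Interventions that loosen the glial scaffolding let the cones
spread back out into a statistically homogeneous mosaic at essentially
unchanged density. Telling these two arrangements apart quantitatively -- from
nothing more than a table of cell-body coordinates over a sampling window --
is the job of this package.

The raw material is the Voronoi tessellation of the cell positions: each
cell's domain is the set of locations nearer to it than to any other cell,
clipped to the sampling window. Domain areas are the reciprocal of local
density, so a ring mosaic produces a *bimodal, spatially segregated* area
pattern: clusters of small domains on the rims, clusters of large domains
facing the empty hole centres, while a homogeneous mosaic produces a unimodal
area distribution with no spatial sorting.

## The statistics

Three per-field summaries are computed by `analyze_field()`:

**Density.** The count of all cells in the field divided by the window area,
in cells/mm². Boundary exclusion (below) does not apply to density.

**g1 skewness** of the interior domain areas,

$$g_1 = \frac{\tfrac1n\sum_i (x_i-\bar x)^3}
             {\big(\tfrac1n\sum_i (x_i-\bar x)^2\big)^{3/2}},$$

with biased (1/n) moments in both numerator and denominator -- the moment
coefficient of skewness, `skewness_g1()`. Empty ring centres hand their area
to the adjacent cells, creating a long right tail and strongly positive g1.

**Coefficient of clustering (CC)**, `coefficient_of_clustering()`:

$$CC = \frac{\sigma_x/\bar x}{\tfrac1n\sum_i \sigma_{a_i}/\bar a_i},$$

the global coefficient of variation of interior domain areas divided by the
average *local* coefficient of variation, where for each interior cell $i$
the local CV is taken over the areas of its Voronoi neighbours (domains
sharing a polygon edge of positive length; the focal domain is not a member
of its own neighbourhood). When small and large domains segregate into
patches larger than one neighbourhood -- the ring phenotype -- local variation
stays low while global variation is large, and CC rises well above 1.

### Where CC sits for a random mosaic

For a stationary pattern one might expect global and local variation to
coincide, putting CC at 1. In practice the Monte-Carlo reference value for a
uniform (Poisson) mosaic at 5,000 cells/mm² is ≈ 1.20 with the sample-SD
convention (≈ 1.32 with the population convention): a Voronoi cell has only
about six neighbours, the CV of a six-point sample is biased low, and
adjacent domain areas are spatially correlated, which depresses the local CV
further. Both effects are intrinsic to the statistic as defined, so 1.2 --
not 1.0 -- is the practical "no clustering" baseline against which ring
mosaics (≈ 1.8 and above) stand out. The test suite records this calibration
over 20 seeded fields.

### Conventions and options

* `sd_convention`: the skewness formula fixes its own (1/n) convention, but
  the CC definition does not say which SD it means. The default is the
  sample (n−1) SD -- the default of mainstream numerical environments -- with
  `"population"` exposed for sensitivity analysis.
* `cc_neighbors`: neighbourhoods of interior cells may include
  boundary-flagged cells, whose clipped areas are slight underestimates
  (`"all"`, default), or be restricted to interior cells
  (`"interior_only"`), which shrinks some neighbourhoods below the two
  members needed for a CV. Cells whose eligible neighbourhood drops below
  two members are omitted from the local average with a warning.
* Degenerate inputs: fewer than two interior cells, or an exactly regular
  mosaic (zero variance of areas, detected with a 1e-12 relative floor to
  absorb tessellation round-off), raise errors rather than returning
  meaningless ratios.

## Boundary exclusion

Cells near the window border have artificially truncated domains, so they are
flagged and excluded from the area vector, g1 and CC ("edge correction").
Two rules are provided:

* `window_touch` (default): exclude exactly those cells whose clipped polygon
  touches the window boundary. This is the unique parameter-free reading of
  "excluding cells around the boundaries" and is what the rasterized test
  oracle implements independently.
* `hull_peel`: exclude cells on the convex hull of the point set, provided
  for sensitivity analysis.

The tessellation, clipped areas and tile adjacency come from the `deldir`
package (exact polygon clipping, not rasterization); the partition invariant
(clipped areas summing to the window area within 1e-6 relative tolerance) is
verified on every call.

## The synthetic generator

`generate_mosaic()` draws seeded fields in three modes so that the whole
pipeline is testable without any data downloads, with defaults representing
the study conditions: a 1×1 mm window at 5,600 cells/mm² (the density scale
of cone mosaics in the degenerating rat retina).

* **ring** -- the degeneration phenotype. Hole centres are placed by
  sequential inhibition at 2.1× the mean hole radius, radii are normal
  (95 ± 15 µm, truncated), and `rim_fraction` (default 0.70) of the cells
  are placed uniformly on the annuli of width `rim_width` (30 µm) around
  each hole, holes weighted by radius so rim density is even. The remaining
  cells are uniform over the whole window. Every placement respects a hard
  core (`min_spacing`, 5 µm -- soma-diameter scale) by dart throwing.
* **homogeneous** -- the post-treatment phenotype: simple sequential
  inhibition at the same hard core and density.
* **poisson** -- uniform positions, the calibration reference.

Because the background cells are unrestricted, `rim_fraction = 0` reduces
the ring generator exactly to the homogeneous one, and mean CC rises
monotonically with `rim_fraction` -- the generator interpolates between the
two phenotypes with a single dial.

### Calibration of the geometry defaults

The ring geometry is not observable from published summary statistics, so
the defaults were calibrated once against two constraints and then frozen:

1. *Feasibility.* The cells that fit on rims are limited by random
   sequential adsorption: a hard core of $s$ jams near $0.547\cdot 4/(\pi
   s^2)$ points per unit area. Thin rims at high rim fractions demand rim
   densities beyond jamming and stall; the defaults keep rim density at
   roughly 60% of the jamming limit so dart throwing terminates quickly.
2. *Phenotype scale.* With 16 holes of radius 95 ± 15 µm, 30 µm rims and
   rim fraction 0.70, ring fields score mean CC ≈ 1.83 and homogeneous
   fields ≈ 1.19 -- the scale on which control (≈ 1.8) and treated (≈ 1.3)
   retinitis-pigmentosa mosaics are reported. Large holes matter more than
   many holes: local CV mixing at rim edges erodes CC when holes are small
   relative to the rim thickness.

Each generated field carries its generating configuration and a per-point
ground-truth annotation (rim vs background, owning hole), retrievable with
`ground_truth()`, so detection-style experiments can score themselves.

What the generator does *not* emulate: real micrograph artefacts (uneven
staining, missed cells, annotation jitter), gradual density gradients across
the retina, partially merged or irregular ring shapes, and any temporal
dynamics of remodeling. Passing tests on synthetic fields therefore
demonstrate the correctness and discriminating power of the statistics under
idealized geometry, not robustness to annotation noise.

## Group comparison

Per-field statistics are aggregated with `summarize_group()` (mean ± SEM,
sample SD, the field/animal as experimental unit) and compared with
`compare_groups()`, a two-sided two-sample t-test. The default is the
classical pooled-variance Student test; a Welch variant is exposed because
real group SEMs can be very unequal. At the study group size (n = 3 fields
per group) the pooled test holds its nominal size: its type-I error over
10,000 null simulations is checked to lie in 0.05 ± 0.01.

## Problem sizes used in the checks

The bundled validation uses 20 seeded Poisson fields of 5,000 cells for the
CC baseline, 20 replicate two-group experiments of 3 ring + 3 homogeneous
fields at full study conditions (5,600 cells over 1×1 mm each), small
fixtures of ≤ 12 points compared against a 0.5 µm rasterized nearest-point
brute-force oracle, and 200 planted dots for the image reader -- sizes chosen
so the whole suite completes in a few minutes on one core while keeping
Monte-Carlo bands tight.

## Numerical choices and limitations

* Voronoi neighbours require a shared edge longer than 1e-9 µm; degenerate
  contacts at a point do not count. The same threshold defines duplicate
  points, which are dropped with a warning.
* Coordinates are processed at full double precision (`deldir`'s default
  rounding is disabled).
* Collinear point sets have no two-dimensional tessellation and are
  rejected; two-point fields tessellate but both cells touch the boundary,
  so no interior statistics exist.
* Published coordinate tables seldom state their units; `read_coordinates()`
  exposes `unit_scale` and a window override instead of guessing, and g1 and
  CC are invariant to the choice (density scales as the inverse square).
* CC needs a healthy interior: below 10 interior cells the function warns,
  below 2 it refuses. At the study density a 1×1 mm field keeps ≈ 5,300 of
  5,600 cells interior, so boundary loss is immaterial there; it bites on
  windows below a few hundred micrometres.
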