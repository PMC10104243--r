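# filarch

Quantitative architecture analysis for cytoskeletal filament networks
traced from cryo-electron tomograms, built for the β-cell cortex: how
actin filaments orient relative to the plasma membrane (PM), how tightly
they bundle, how PM-anchored filaments arrange into "netlike" versus
"blooming" architectures, and how close actin and microtubules (MTs) come
to insulin secretory granules (ISGs). It also reimplements the 2D
fluorescence meshwork skeleton metrics (total length and junction counts
per subsection) used to track actin remodeling at lower resolution, and
ships a synthetic scene generator with exact ground truth so every
analysis stage is testable without tomographic data.

The package is written tidyverse-style: analysis functions take and
return tibbles, so record sets pipe straight into `dplyr`/`ggplot2`.

## Who it is for

Groups that already have filament centerlines (e.g. cylinder-template
tracing exports), PM/organelle masks (MRC), or SIM/TIRF meshwork images,
and need the downstream quantification: orientation distributions,
pairwise distance–angle structure, anchoring statistics, proximity
histograms, and condition-level comparisons with defensible defaults.

## The metrics

With each filament reduced to its end-to-end unit chord **u** and
resampled at Δ = 4 nm arc-length spacing:

- **Orientation to the PM**: θ = arcsin |u·n̂| ∈ [0°, 90°], with n̂ the
  tomogram z axis (the PM proxy). θ < 45° is *parallel*, θ ≥ 45°
  *quasi-orthogonal*.
- **Pairwise structure**: for every resampled point, the distance to the
  nearest point on any other filament, paired with the undirected angle
  arccos |u₁·u₂| between the two chords. Bundles appear as the density
  peak near (0–15°, 12–13 nm).
- **Anchoring**: a filament is anchored when an end node lies within
  60 nm of the PM surface (the tracing unit length). Anchored neighbors —
  same PM component, PM-near ends closer than 120 nm — contribute the
  directed angle arccos(v₁·v₂) ∈ [0°, 180°] between their near-to-far
  vectors; mass at 60–90° marks a netlike, mass below 30° a blooming
  architecture.
- **Proximity**: per-point Euclidean distances to the nearest ISG surface
  (via an exact 3D distance transform; 200 nm reporting cutoff) and to
  the nearest MT centerline, with per-filament minima ("shortest MT
  distance").
- **Meshwork (2D)**: IsoData threshold → morphological thinning → branch
  decomposition; total skeleton length (orthogonal steps 1 px, diagonal
  √2, calibrated by the 31.3 nm pixel) and merged junction count, with
  branches of ≤ 1 px discarded.

## Worked example

```r
library(filarch)
library(dplyr)

g   <- generate_scene(scene_spec(seed = 7))   # basal-like synthetic scene
res <- run_scene(g$scene)

res$summary %>%
  select(n_actin, parallel_fraction, quasi_orthogonal_fraction,
         anchored_count, anchored_percentage, periphery_height)
#> # A tibble: 1 × 6
#>   n_actin parallel_fraction quasi_orthogonal_fraction anchored_count
#>     <int>             <dbl>                     <dbl>          <int>
#> 1     120             0.967                    0.0333            108
#>   anchored_percentage periphery_height
#>                 <dbl>            <dbl>
#> 1                  90              200

classify_architecture(res$neighbor_records)
#> $label     "netlike"
#> $mass_60_90 0.41
#> $mass_0_30  0.14
```

120 actin filaments were generated with a 3% quasi-orthogonal fraction,
90% anchored to the lower PM slab of a 200 nm periphery, in netlike mode
— and each measured quantity recovers its generating value: 96.7%
parallel, 108/120 anchored (90%), height 200 nm, and the anchored-angle
mass concentrated at 60–90° so the scene classifies as netlike. The same
functions run unchanged on real scenes assembled from
`read_filaments()` / `read_amira_ascii()` traces and `read_mask()` MRC
volumes via `scene_bundle()`.

For the 2D module:

```r
mw <- generate_meshwork(1432, 6, seed = 2)    # target scale of one subsection
skeletonize_and_measure(binarize(mw$image), mw$image$pixel_size)
#> <skeleton_stats: total length 4851.5 nm, 6 junction(s), 17 branch(es)>
```

the junction count is recovered exactly and the measured length equals
the generator's analytic skeleton length.

A thin command-line front end (`inst/scripts/filarch`) exposes
`simulate`, `analyze`, `compare`, and `meshwork` subcommands over the
same functions.

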