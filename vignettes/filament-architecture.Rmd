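---
title: "Quantifying filament network architecture: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filament network architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filarch)
library(dplyr)
```

## The measurement model

The package treats a tomogram as a *scene*: a set of traced filament
centerlines (ordered 3D nodes, nanometres, classed actin or microtubule),
at most one voxel mask per role (plasma membrane, secretory granules),
and a physical extent. Everything downstream is defined on two derived
objects:

* the **chord** of a filament — the unit vector between its two end
  nodes. All angle statistics use chords, not local tangents, because a
  single direction per filament is what the upstream tracing (60 nm actin
  templates, 100 nm MT templates) supports; short traced segments make
  local tangents mostly noise. A length-weighted mean-of-segments
  direction is available (`filament_chords(direction = "mean")`) for
  sensitivity checks but is not the default and carries no claim of
  equivalence.
* the **resampled point chain** — points at arc lengths 0, Δ, 2Δ, … with
  Δ = 4 nm. The terminal node is appended when the residual arc is at
  least Δ/2, so the chain covers the full length without inflating point
  counts; total length is preserved to within one interval.

Angles come in three flavours, all in degrees:

* elevation out of the reference plane, `arcsin |u·n̂|` ∈ [0, 90], with
  n̂ = ẑ by default. This is the "orientation relative to the PM" proxy:
  in these tomograms the membrane is near-parallel to the image plane.
  It is the one statistic that is *not* invariant under arbitrary rigid
  motions of a scene, because the reference stays fixed; everything else
  (pair distances, pair angles, mask distances) is.
* undirected inter-chord angle `arccos |u₁·u₂|` ∈ [0, 90], used for the
  pairwise network structure where filament polarity is unknowable.
* directed angle `arccos(v₁·v₂)` ∈ [0, 180] between anchored filaments'
  near-to-far vectors, where polarity *is* defined by the membrane.

The 45° class boundary (parallel below, quasi-orthogonal at or above)
is closed on the right: a chord at exactly 45° is quasi-orthogonal. A
1e-9 degree guard absorbs `arcsin` round-off so constructed 45° fixtures
land on the intended side.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| resampling interval Δ | 4 | nm | standard fit interval for filament distance analyses |
| anchoring threshold | 60 | nm | one actin tracing-unit length |
| neighbor threshold | 120 | nm | twice the tracing unit; strict `<` |
| proximity cutoff | 200 | nm | myosin-V reach argument; applied at reporting only |
| pair-distance bins | 10 | nm | figure convention |
| anchored-angle bins | 15 | deg | figure convention |
| actin/MT–ISG bins | 75 / 100 | nm | figure convention |
| cylinder radii | 4 / 7.5 | nm | tracing template diameters 8 / 15 nm |
| meshwork pixel | 31.3 | nm | SIM lateral sampling |
| branch filter | 1 | px | drops isolated-pixel artifacts |

The anchoring threshold is inclusive (`≤ 60`), the neighbor separation
exclusive (`< 120`), matching the respective "within"/"less than"
conventions. The 200 nm cutoff trims histograms, never the raw record
tables, so sensitivity analyses can re-cut without recomputation. The
bundle criterion (`bundle_flags()`: pair angle ≤ 15°, distance 8–17 nm)
is an explicit operationalization of the observed density peak near
12–13 nm and 0–15°, not a derived physical bound; both box edges are
configuration, echoed into provenance.

## Numerical machinery

* **Nearest neighbors.** Pairwise and actin–MT distances use an exact
  uniform-grid search (C++): candidate cells are scanned in expanding
  shells until no unscanned cell can beat the best hit. Distance ties
  break deterministically to the lowest filament id (string order), then
  the lowest point index — the same order an exhaustive scan visits, so
  accelerated and brute-force results are bit-identical, which the test
  suite asserts on dozens of scenes.
* **Mask distances.** Distance-to-surface uses an exact separable
  Euclidean distance transform of the voxel grid, sampled at each
  point's enclosing voxel; this matches direct nearest-boundary-voxel
  search to within one voxel diagonal. Filament *end points* — where the
  60 nm anchoring decision lives — instead use the direct exact search
  against boundary-voxel centers, so threshold cases do not depend on
  voxel sampling. Points inside a mask are at distance 0 (contact);
  signed interior distances are never used. Points outside the grid are
  clamped and flagged.
* **Components and height.** "Same PM" means the same 26-connected mask
  component. Periphery height is the difference in mean boundary-voxel
  z between the uppermost and lowermost PM components — exact for
  parallel slabs, and documented (and tested) to read `gap / cos(tilt)`
  for tilted ones. The original measurement procedure is not specified
  anywhere we could follow; this definition is one defensible choice and
  is recorded in provenance.
* **2D skeletons.** Thresholding uses IsoData (iterative intermeans) —
  the "default" auto-threshold of the common tools — followed by
  Zhang–Suen thinning. Branch length counts inter-pixel steps (1 px
  orthogonal, √2 diagonal) plus the attachment step from a branch end to
  an adjacent junction cluster; junction clusters (8-adjacent pixels with
  ≥ 3 skeleton neighbors, merged) additionally contribute their internal
  spanning length. Without those two terms a grid of crossing lines
  under-measures by several pixels per junction, which is why
  `skeleton_stats` reports `junction_length` separately rather than
  forcing totals to equal the filtered branch sum alone.
* **Determinism.** Record tables serialize numeric columns at 17
  significant digits (bit-exact round trips; readers use C `strtod`).
  Rerunning any pipeline stage with the same inputs and configuration
  yields byte-identical files; configurations are identified by a stable
  hash in every output's provenance sidecar.

## What the synthetic generator emulates — and what it does not

`generate_scene()` builds the study conditions: two PM voxel slabs
separated by the periphery height (200 nm default, center-to-center);
anchored filaments placed as clusters at PM anchor sites with controlled
mutual directed angles — pairs drawn at 60–88° in *netlike* mode,
triplets within a 13° cone in *blooming* mode — with cluster classes kept
homogeneous so the quasi-orthogonal count is exact by construction
(`round(f · n)` filaments at elevation ≥ 45°); parallel bundles at
12.5 nm lateral spacing with configurable jitter; dispersed and
reoriented filaments; gently curved MT polylines; and spherical granules
(radius 150 ± 25 nm — a plausible granule scale, not a measured value)
rasterized into a labeled mask. Each component draws from its own
seed-derived stream, so adding granules never perturbs the filament
layout.

Defaults are one-time choices: 1000 × 1000 × 250 nm extent at 2.5 nm
voxels (coarser than the ~1.3 nm binned tomogram pixel; mask quantization
stays two orders of magnitude below the 60 nm anchoring threshold while
keeping grids tractable), 120 actin filaments (matching the anchored
surface density implied by a few hundred anchored filaments over a few
square micrometres), 90% anchored, 3% quasi-orthogonal, netlike — i.e. a
basal-like cortex; the second-phase condition is reached by raising the
quasi-orthogonal fraction to 0.15, lowering anchoring to 0.71, and
switching to blooming.

Honest limitations: filaments are near-straight three-node polylines, not
curved fibers; anchor-site neighborhoods are only softly separated, so
neighbor graphs include cross-cluster pairs whose angles are roughly
uniform — the netlike/blooming contrast rests on the constructed
intra-cluster pairs, as in `classify_architecture()`'s mass comparison of
[60, 90) against [0, 30); membranes are flat slabs, so the z-plane
orientation proxy is exact here while real membranes curve (a local
PM-plane fit would be the extension point); and no imaging physics is
simulated — passing tests demonstrates that the *measurement code*
recovers known geometry, not that it is robust to segmentation noise in
real tomograms. Likewise the 2D generator draws axis-aligned line grids
(junctions = lines crossings, length analytic) rendered 3 px wide with
1 px tapered tips — tapering avoids the ~2 px end erosion that
morphological thinning inflicts on blunt wide ends, and keeps noiseless
recovery exact; real meshworks are neither straight nor axis-aligned.

## Statistics wiring

`group_compare()` is deliberately thin plumbing: one-way ANOVA with
Tukey HSD for ≥ 3 groups, pooled-variance t-test and variance-ratio
F-test for 2, with group means ± SEM always attached, and broom-style
`tidy()`/`glance()` methods. `compare_conditions()` applies it per scalar
metric across per-scene summaries, describing (but excluding from tests)
conditions with a single scene and metrics with zero within-group
variance. For 2D density maps, `kde_at_points()` standardizes both axes
to unit variance first — nanometres and degrees are incommensurate — and
evaluates a Gaussian product kernel at the data points with Scott's
bandwidth `n^(-1/6)`; densities are reported on the standardized scale
with the bandwidth recorded, since the original maps' bandwidth and
scaling are unstated and exact visual reproduction is not claimed.

## Problem sizes used by the test suite

The suite validates at desk scale, chosen once: oracle equality on 20
scenes of ≤ 10 filaments; orientation recovery on 100 seeds per fraction
at n = 400 filaments (10 nm voxels, no granules); architecture
discrimination on 100 netlike + 100 blooming scenes at n = 80; bundle
spacing pooled over 6 bundle-heavy scenes; meshwork recovery on 24
noiseless grids; type-I control over 100 repeated identical-condition
comparisons with per-scene filament counts drawn from 110–190 (the
generator's exact-count construction would otherwise make equal-sized
scenes literally identical in fraction, leaving a t-test nothing to
estimate). The published per-condition numbers from real tomograms are
not reproduction targets: those data are not deposited, and the
generator makes no attempt to mimic their noise structure.
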