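---
title: "Quantifying microvessel morphology, permeability and leukocyte extravasation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvessel morphology, permeability and leukocyte extravasation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

## Scope

`vesselquant` implements the quantification stack used in microfluidic
self-assembled microvessel studies: confocal z-stacks of fluorescently
labelled endothelial networks are reduced to binary projection masks, the
masks to skeleton graphs and morphometric statistics; dextran time-lapse
series yield an apparent permeability; leukocyte (PMN) time-lapses yield
per-cell speeds and extravasation fates; and the resulting measurement
tables are normalized and compared with the study's statistical tests. A
synthetic phantom generator with exact ground truth validates every stage,
since raw microscopy from such studies is typically not deposited.

## Preprocessing

The segmentation chain is fixed, mirroring common ImageJ macro practice:

1. **Maximum-intensity projection** over z.
2. **Outlier removal**: a pixel is replaced by the median of its disc
   neighbourhood (radius 2 px) only when it deviates from that median by
   more than a threshold. The radius matches the macro convention; the
   deviation threshold is not specified by the protocol this mirrors, so it
   defaults to 50 on the image's native intensity scale and is recorded in
   the mask provenance.
3. **Gaussian smoothing**, sigma 2 px, kernel truncated at 4 sigma,
   reflective boundaries (avoids darkened borders that would bias coverage).
4. **Binarization**: Otsu's threshold on a 256-bin histogram by default —
   parameter-free and reproducible; a fixed threshold can be supplied. The
   realized threshold is always recorded.

All arithmetic is floating point; the mask is the only quantized product.
Each operator is tested against a brute-force counterpart (explicit loops,
dense convolution) on small random images.

## Skeleton morphometry

Masks are thinned to 1-px centerlines by sequential simple-point thinning
with four directional sub-cycles per iteration. A pixel is deleted only when
it is a *simple point* (removal preserves 8-connected foreground and
4-connected background topology, decided by a 256-entry lookup table) and
not a line endpoint. The directional sub-cycles freeze their candidate set
before deleting, which peels one boundary layer per side and keeps the
centerline centred; this avoids two classic failure modes of parallel
two-subiteration thinning (staircase residue that reads as spurious
junctions, and complete end-erosion of two-pixel-wide diagonal bands).

Skeleton pixels are classified by 8-neighbour count: 1 = endpoint, >= 3 =
junction; adjacent junction pixels merge into one junction node. The
**connectivity ratio** is junctions/endpoints — 0 for an unbranched segment,
1/3 for a Y, higher for well-connected networks; pure loops (junctions or
neither) are flagged rather than silently divided.

Two measurement corrections matter for accuracy and are applied by default:

* **Branch length** is the anchored polyline length — Euclidean distance
  summed between every 5th skeleton pixel along a branch. The plain chain
  metric (1 px per orthogonal step, sqrt(2) per diagonal) over-measures
  oblique straight lines by up to 8.2% (worst near 22.5 degrees), which
  would dominate the error budget; anchoring removes that bias while
  leaving axis-aligned and 45-degree lines exact. The chain-metric value is
  retained per branch as `length_px_steps`.
* **Junction refinement and cap extension.** Thinning displaces a junction
  into the widest part of the tube union (by roughly one radius),
  lengthening child branches at the parent's expense, and retracts rounded
  tube ends by up to a few radii at unfavourable orientations. Junctions are
  relocated to the least-squares intersection of the incident branches'
  tangent lines (fitted just outside the junction zone, relocations farther
  than twice the junction radius are rejected); terminal branches are
  extended or trimmed by ray-marching from the tip along the outward tangent
  to the mask boundary and subtracting the local tube radius. On randomly
  oriented phantom trees these corrections keep individual branch lengths
  within about 4% of the generating polylines (tested at 5% over 10 seeded
  networks).

**Diameters** use the maximal-inscribed-ball convention: twice the Euclidean
distance transform at skeleton pixels, averaged per branch over interior
pixels and weighted by branch pixel count overall. Measured over random
orientations and sub-pixel phases this is unbiased to about a quarter pixel;
tubes rasterized exactly on the integer grid are the worst case (about one
pixel wide of truth). Absolute diameters from any EDT convention depend on
segmentation fill; comparisons across conditions are the intended use.

Terminal spurs shorter than `min_branch_px` (default 5 px) attached to a
junction are pruned, and skeleton components smaller than that are dropped —
thinning artifacts otherwise inflate endpoint counts, and ImageJ-style
analyses do the same implicitly.

## Apparent permeability

With intensity linear in tracer concentration, negligible flux across the
imaging boundary, and constant transendothelial flux, the permeability of
the vessel wall to the tracer is

$$P = \frac{A_T\,(I_{Tf} - I_{T0})}{p_v\, t\,(I_{V0} - I_{T0})}\ \mathrm{cm\,s^{-1}},$$

where $p_v$ is the vessel perimeter (cm) and $A_T$ the extravascular tissue
area (cm²) from the binary vessel outline at $t = 0$, $I_{V0}$ and $I_{T0}$
the mean intravascular/extravascular intensities at $t = 0$, and $I_{Tf}$
the mean extravascular intensity at time $t$.

* The mask comes from the dextran channel's maximum projection at $t = 0$;
  intensities are measured on the same projections for internal consistency.
* $p_v$ is estimated by Moore-neighbour contour tracing with the geodesic
  step metric plus $\pi$ px per closed contour: the traced contour runs
  through boundary-pixel centres, half a pixel inside the true boundary, and
  offsetting a closed convex curve outward by half a pixel adds exactly
  $\pi$. Pixel-edge counting would overestimate smooth boundaries by up to
  sqrt(2); the chain metric itself still carries its digital-line bias (up
  to ~7%) on oblique straight boundaries. Because the forward model and the
  estimator share the same perimeter measure, permeability recovery is
  insensitive to this bias.
* Multi-frame series produce one estimate per interval from $t = 0$; the
  reported $P$ is their mean. Two assumption monitors attach flags:
  extravascular intensity falling below its initial value beyond the noise
  floor, and intravascular mean drifting more than 5% (boundary-flux /
  reservoir violation).

The phantom forward model writes the same linear intensity rise into the
extravascular region ($I_{T0} + P\,p_v\,t\,(I_{V0}-I_{T0})/A_T$) and
refuses parameters whose modelled tissue intensity would reach $I_{V0}$
within the series, where the constant-flux approximation is broken. The
leakage phantom geometry (a small bifurcated network, ~5% coverage at
1 µm/px) keeps $p_v/A_T$ near 70 cm⁻¹ so that the fastest grid point
($10^{-5}$ cm s⁻¹ over 15 min) stays inside the valid regime. Recovery is
exact (to rounding) noise-free and has median relative error below ~5% at
5%-of-contrast Gaussian noise, because the mean over ~60 000 background
pixels suppresses noise by two orders of magnitude.

## Leukocyte tracking and fates

Detection thresholds each frame and reports intensity-weighted centroids of
8-connected components of at least `min_spot_px` pixels (a stand-in for
interactive spot tracking in commercial software). Linking is greedy mutual
nearest-neighbour under a displacement gate: candidate pairs are taken in
order of increasing distance, ties broken by detection index, so the result
is deterministic. There is no gap closing; a missed detection terminates a
track.

Fate is scored from the final frame only, matching endpoint scoring of
fixed samples: with $d$ the distance-transform distance to the opposite
phase at the (rounded) final position, a track is **transmigrating** when
$d \le$ `contact_dist_px` (touching the vessel boundary from either side),
otherwise **intravascular** inside or **extravasated** outside the mask.
`contact_dist_px` defaults to 2 px; no numeric contact criterion exists in
the protocols this mirrors, so the value is an explicit, configurable
operationalization. The motion phantom realizes fates with the same
geometry plus a one-pixel safety margin so sub-pixel detection error cannot
flip a class; straight paths with exact per-frame displacement
(speed × frame interval) are placed by seeded rejection sampling, and start
points are kept 12 px apart so cohorts are non-crossing by construction.
Tracking is 2D on projections; studies using 3D spot tracking measure the
same endpoints (speed, % fates) up to projection effects.

## Statistics

The replication unit is the device: field-of-view values are averaged per
device before testing (three fields per device in the emulated design).
Normalization divides every value by the mean of its *own experiment's*
control condition, making each experiment's control mean exactly 1 before
pooling; pooled normalization is available but off. Cytokine-style panels
are min-max scaled per analyte to [0, 1]; constant analytes cannot be
scaled and are emitted at the 0.5 mid-level with a flag. Group comparison
uses one-way ANOVA with Tukey HSD contrasts, or t-tests where a design
calls for them — Welch by default for unpaired comparisons (no equal
variance assumption is documented for the studies this mirrors), paired on
device where stated. A 1000-replicate simulated global null keeps the ANOVA
type-I error inside [0.03, 0.07] at alpha = 0.05 and Tukey's family-wise
error at or below 0.07.

## What the phantoms do and do not emulate

The generator produces: tubular networks of known topology and radii
rasterized by exact point-to-segment distance (so the footprint, area
fraction and centerline are analytic ground truth); a leakage channel
following the constant-flux forward model; and Gaussian-spot particles with
known kinematics and fates. Defaults are chosen to be realistic for this
assay class at 1 µm/px: tube radii 4–6 px (8–12 µm vessels), branch lengths
50–110 px, vessel/background contrast 180 a.u. on a 16-bit-like scale,
additive Gaussian noise clipped at zero, 3 × 5 min leakage intervals and
5 × 2 min PMN intervals.

They do **not** emulate optical point-spread blur, photobleaching, uneven
illumination, 3D tortuosity, vessel wall thickness, or cell-shape changes
during transmigration. Passing the phantom suite therefore demonstrates
that the measurement code is correct and unbiased on geometry it can see,
not that segmentation parameters transfer to arbitrary real microscopy;
on real data the preprocessing thresholds are the quantities to revisit,
and every mask records them in its provenance for that reason.

## Numerical choices and degenerate inputs

* Problem sizes: validation uses 256 × 256 fields, 10 networks for
  morphometry, 20 seeds per noise condition for permeability, cohorts of 10
  particles over 5 frames, and 1000 replicates for test calibration —
  enough for the tolerances tested while keeping the whole suite under a
  minute per module on one CPU.
* Empty masks skeletonize to empty graphs (not an error); empty graphs give
  flagged connectivity and absent diameters. Otsu on a constant image is an
  error that points to the fixed-threshold mode. Empty and full masks are
  rejected by the permeability partition (no perimeter / no tissue).
* Determinism: every generator takes an explicit integer seed and restores
  the caller's RNG state; identical spec + seed gives bit-identical output.
  Linking breaks ties by distance then index.
* A worked example with concrete numbers is in the README; the
  `analysis/` scripts reproduce all tables under `results/`.

## Known limitations

* Absolute diameters inherit segmentation bias (about ±1 px at worst
  orientation/phase); between-condition contrasts are robust, absolute
  values should be read with that grain of salt.
* The perimeter chain metric biases $p_v$ on oblique smooth boundaries by
  up to ~7%; this cancels in phantom recovery and affects absolute
  permeability by the same bounded factor on real data.
* Greedy nearest-neighbour linking has no motion model; it is adequate for
  the low densities and short series emulated here, not for dense crossing
  cohorts.
* The fate contact distance is an operational definition; observer-scored
  "touching the endothelium" in real studies has no unique pixel
  equivalent.
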