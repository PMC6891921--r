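# vesselquant

Quantification of self-assembled microvessel networks from confocal
microscopy: network morphometry from binary projections, apparent
permeability from dextran time-lapses, and leukocyte (PMN) tracking with
extravasation fate classification — validated end to end against a synthetic
phantom generator with exact ground truth.

It is written for researchers running microfluidic vasculogenesis assays
(endothelial–stromal cocultures in fibrin gels and similar systems) who
quantify their cultures by confocal imaging and need the measurement chain
to be reproducible and testable, rather than a collection of one-off
ImageJ macros and manual scoring.

## What it computes

**Morphometry.** A confocal stack is maximum-projected, despeckled
(conditional median, radius 2 px), Gaussian-smoothed (sigma 2 px) and
binarized (Otsu by default). The mask is thinned to a 1-px skeleton graph
from which the package reports: % area coverage, branch count and lengths,
junction and endpoint counts, the connectivity ratio (junctions ÷
endpoints), and mean vessel diameter (twice the Euclidean distance
transform along the skeleton).

**Apparent permeability.** For a vessel network perfused with fluorescent
dextran, with intensity linear in concentration, negligible flux across the
imaging boundary and constant transendothelial flux:

```
P = A_T (I_Tf − I_T0) / (p_v · t · (I_V0 − I_T0))   [cm/s]
```

where `p_v` is the vessel perimeter and `A_T` the extravascular tissue area
from the binary vessel outline at t = 0, `I_V0`/`I_T0` the mean
intravascular/extravascular intensities at t = 0, and `I_Tf` the mean
extravascular intensity at time t. Multi-frame series yield one estimate
per interval and their mean, with assumption monitors flagged.

**Tracking.** PMN-like particles are detected per frame (thresholded
components, intensity-weighted centroids), linked by greedy mutual nearest
neighbours, and classified from their final position against the vessel
mask: in the extravascular space = extravasated, within a contact distance
of the boundary = transmigrating, else intravascular. Cohorts are summarized
as mean speed (µm/min) and % per fate.

**Statistics.** Measurement tables (experiment / device / condition) are
normalized per experiment to the control mean, cytokine-style panels are
min–max scaled to [0, 1], and groups are compared by one-way ANOVA with
Tukey contrasts or t-tests, with the device as replication unit.

**Phantoms.** Every stage is validated against generated ground truth:
tubular networks of known topology and radii, leakage series with known P,
and particle cohorts with known paths and fates. See
`vignettes/methods.Rmd` for the models, corrections and their accuracy.

## Worked example

```r
library(vesselquant)

# a noisy phantom field with known topology (3 junctions, 5 endpoints)
net <- random_vessel_network(c(256, 256), n_splits = 3, radius_px = 5, seed = 9)
ph  <- generate_network_phantom(phantom_spec(branches = net, noise_sigma = 9, seed = 9))

mask <- segment_vessels(ph$stack, "EC", sigma_px = 1)
mask
#> <binary_mask> 256x256, 7.6% foreground, pixel 1 um

morphometry_record(mask, field_id = "net09")
#> <morphometry_record> coverage 7.55%, 7 branches (mean 70.0 um),
#>   3 junctions / 5 endpoints (ratio 0.600), mean diameter 9.9 um
```

The record matches the generator: 3 junctions, 5 endpoints, coverage
7.55%, and tube diameter 10 µm (radius 5 px at 1 µm/px) read as 9.9 µm.

```r
# dextran leakage at a known permeability of 1e-6 cm/s, 3 x 5 min intervals
leak <- generate_network_phantom(phantom_spec(
  branches = random_vessel_network(n_splits = 1, radius_px = 5, seed = 77),
  seed = 77))
ser <- simulate_leakage_series(leak$truth, leakage_spec(
  P_true = 1e-6, frame_interval_s = 300, n_frames = 4, noise_sigma = 9, seed = 1))

m0 <- binarize(ser$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
permeability_series(ser, m0, channel = "dextran")
#> <permeability_result> P = 1.001e-06 cm/s (mean of 3 intervals)
```

The extravascular mean rises 20 → 24.9 → 29.6 → 34.4 a.u. over the three
intervals and the estimator returns P within 0.1% of the value the series
was generated with.

The `analysis/` directory contains the numbered workflow scripts
(`01_generate_phantoms.R` … `05_stats.R`); each prints what it found and
writes its tables under `results/`.

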