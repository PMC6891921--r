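#!/usr/bin/env Rscript
# Generate the three phantom families used throughout the analysis:
# (a) branched vessel networks with known topology for morphometry,
# (b) a dextran-leakage time-lapse with known permeability,
# (c) a migrating leukocyte cohort with known speeds and fates.
# Writes example images plus their ground truth under results/phantoms/.

suppressMessages(library(vesselquant))
out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# (a) ten branched networks, radius 5 px (10 um diameter vessels at 1 um/px)
truth_rows <- list()
for (s in 1:10) {
  br <- random_vessel_network(c(256, 256), n_splits = 3, radius_px = 5,
                              seed = s)
  ph <- generate_network_phantom(phantom_spec(branches = br, seed = s))
  if (s <= 2) write_phantom(ph, out, sprintf("network_%02d", s))
  truth_rows[[s]] <- data.frame(
    field_id = sprintf("net%02d", s),
    n_branches = length(br),
    n_junctions = ph$truth$n_junctions,
    n_endpoints = ph$truth$n_endpoints,
    area_fraction = ph$truth$area_fraction)
}
truth_tab <- do.call(rbind, truth_rows)
write.csv(truth_tab, file.path(out, "network_truth.csv"), row.names = FALSE)
cat("networks: junction counts",
    paste(truth_tab$n_junctions, collapse = " "), "\n")

# (b) leakage series at P = 1e-6 cm/s, 3 x 5 min intervals after t = 0
ph_leak <- generate_network_phantom(phantom_spec(
  branches = random_vessel_network(n_splits = 1, radius_px = 5, seed = 77),
  seed = 77))
ser <- simulate_leakage_series(ph_leak$truth, leakage_spec(
  P_true = 1e-6, frame_interval_s = 300, n_frames = 4,
  noise_sigma = 0.05 * 180, seed = 1))
a <- ser$channels$dextran
invisible(tiff::writeTIFF(
  lapply(seq_len(dim(a)[3]), function(k) a[, , k] / max(a)),
  file.path(out, "leakage_series.tif")))
cat("leakage series: extravascular means",
    paste(sprintf("%.2f", vapply(1:4, function(k)
      mean(a[, , k][!ph_leak$truth$mask]), numeric(1))), collapse = " "),
    "(rising in t)\n")

# (c) cohort of 10 cells over 5 x 2 min frames
ph_tr <- generate_network_phantom(phantom_spec(
  branches = parallel_tube_network(n_tubes = 3, radius_px = 6, seed = 11),
  seed = 11))
sim <- simulate_pmn_motion(ph_tr$truth, motion_spec(
  speeds_um_min = c(2.5, 3, 4, 2, 5, 3.5, 4.5, 6, 5.5, 4),
  fates = c(rep("intravascular", 4), rep("transmigrating", 3),
            rep("extravasated", 3)),
  seed = 5))
b <- sim$stack$channels$PMN
invisible(tiff::writeTIFF(
  lapply(seq_len(dim(b)[3]), function(k) b[, , k] / max(b)),
  file.path(out, "pmn_series.tif")))
true_tracks <- do.call(rbind, lapply(sim$tracks, function(tr)
  cbind(track_id = tr$track_id, fate = tr$fate, tr$positions)))
write.csv(true_tracks, file.path(out, "pmn_true_tracks.csv"),
          row.names = FALSE)
cat("cohort:", length(sim$tracks), "true tracks written\n")
cat("done; outputs in", out, "\n")
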