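#!/usr/bin/env Rscript
# Apparent-permeability estimation: recover P across three decades from
# noise-free and noisy leakage series, and verify the estimator is centred
# on zero for an impermeable vessel.

suppressMessages(library(vesselquant))
dir.create("results", showWarnings = FALSE)

ph <- generate_network_phantom(phantom_spec(
  branches = random_vessel_network(n_splits = 1, radius_px = 5, seed = 77),
  seed = 77))

rows <- list()
for (P in c(1e-7, 1e-6, 1e-5)) {
  ser <- simulate_leakage_series(ph$truth, leakage_spec(
    P_true = P, frame_interval_s = 300, n_frames = 4))
  m <- binarize(ser$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
  res <- permeability_series(ser, m, channel = "dextran")
  errs <- vapply(1:20, function(s) {
    sern <- simulate_leakage_series(ph$truth, leakage_spec(
      P_true = P, frame_interval_s = 300, n_frames = 4,
      noise_sigma = 0.05 * 180, seed = s))
    mn <- binarize(sern$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
    abs(permeability_series(sern, mn, channel = "dextran")$P_cm_per_s - P) / P
  }, numeric(1))
  rows[[length(rows) + 1]] <- data.frame(
    P_true = P, P_recovered_noisefree = res$P_cm_per_s,
    rel_err_noisefree = abs(res$P_cm_per_s - P) / P,
    median_rel_err_noisy = median(errs))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/permeability_recovery.csv", row.names = FALSE)
print(tab, digits = 3)

P0 <- vapply(1:20, function(s) {
  ser <- simulate_leakage_series(ph$truth, leakage_spec(
    P_true = 0, frame_interval_s = 300, n_frames = 4,
    noise_sigma = 0.05 * 180, seed = 200 + s))
  m <- binarize(ser$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
  permeability_series(ser, m, channel = "dextran")$P_cm_per_s
}, numeric(1))
cat(sprintf("null estimator: mean %.2e cm/s, s.e. %.2e (|z| = %.2f)\n",
            mean(P0), sd(P0) / sqrt(20),
            abs(mean(P0)) / (sd(P0) / sqrt(20))))
cat("table written to results/permeability_recovery.csv\n")
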