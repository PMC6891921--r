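#!/usr/bin/env Rscript
# Statistical post-processing on the morphometry output: per-experiment
# control normalization, group comparison (ANOVA + Tukey, t-tests), min-max
# scaling of a cytokine-style intensity panel, and the combined report.

suppressMessages(library(vesselquant))
dir.create("results", showWarnings = FALSE)

# simulate a two-experiment study: control vs pericyte-rich condition,
# 4 devices each, 3 fields per device; pericytes reduce coverage
set.seed(99)
mk_exp <- function(ex, ctrl_mu, trt_mu) {
  do.call(rbind, lapply(1:8, function(d) {
    cond <- if (d <= 4) "ctrl" else "pericyte"
    mu <- if (d <= 4) ctrl_mu else trt_mu
    data.frame(experiment_id = ex,
               device_id = sprintf("%s_d%d", ex, d),
               condition = cond, metric_name = "coverage_pct",
               value = rnorm(3, mu, 3))
  }))
}
tab <- rbind(mk_exp("e1", 67, 46), mk_exp("e2", 60, 42))
write.csv(tab, "results/measurements.csv", row.names = FALSE)

norm <- normalize_to_control(tab, "coverage_pct", "ctrl")
cat(sprintf("normalized control means per experiment: %s (should be 1)\n",
            paste(sprintf("%.3f", tapply(
              norm$value[norm$condition == "ctrl"],
              norm$experiment_id[norm$condition == "ctrl"], mean)),
              collapse = ", ")))

cmp <- compare_groups(norm, "coverage_pct", test = "anova")
cat(sprintf("ANOVA on normalized coverage: F = %.1f, p = %.2g %s\n",
            cmp$F, cmp$p, cmp$stars))
tt <- compare_groups(tab, "coverage_pct", test = "t")
cat(sprintf("Welch t-test (raw values): p = %.2g %s\n", tt$p, tt$stars))

# cytokine-style panel: 8 analytes x 3 conditions
set.seed(7)
cyto <- matrix(rlnorm(24, 5, 1), 8, 3,
               dimnames = list(paste0("cytokine_", 1:8),
                               c("coculture_HPP", "coculture_HLF",
                                 "triculture")))
sc <- minmax_scale(cyto)
write.csv(round(unclass(sc), 4), "results/cytokine_minmax.csv")
cat("min-max scaled panel: every row spans [0, 1]; written to results/cytokine_minmax.csv\n")

su <- summarize_metric(tab, "coverage_pct")
write_report(list(coverage_pct = su), "results",
             provenance = list(normalization = "per-experiment control mean",
                               replication_unit = "device",
                               fields_per_device = 3))
print(su, digits = 3)
cat("summary written to results/coverage_pct_summary.csv and results/report.json\n")
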