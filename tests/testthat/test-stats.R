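test_that("control normalization divides by each experiment's control mean", {
  tab <- data.frame(
    experiment_id = "e1", device_id = paste0("d", 1:4),
    condition = c("ctrl", "ctrl", "trt", "trt"),
    metric_name = "m", value = c(2, 4, 3, 6))
  out <- normalize_to_control(tab, "m", "ctrl")
  expect_equal(out$value[out$condition == "trt"], c(1, 2))
  expect_equal(mean(out$value[out$condition == "ctrl"]), 1)
})

test_that("normalization is per experiment and matches a division oracle", {
  tab <- example_table()
  out <- normalize_to_control(tab, "diameter", "ctrl")
  oracle <- tab$value
  for (ex in unique(tab$experiment_id)) {
    sel <- tab$experiment_id == ex
    cm <- mean(tab$value[sel & tab$condition == "ctrl"])
    oracle[sel] <- tab$value[sel] / cm
  }
  expect_equal(out$value, oracle)
  # each experiment's control mean is exactly 1 after normalization
  for (ex in unique(out$experiment_id))
    expect_equal(mean(out$value[out$experiment_id == ex &
                                  out$condition == "ctrl"]), 1)
  # missing control names the experiment
  bad <- tab[!(tab$experiment_id == "e2" & tab$condition == "ctrl"), ]
  expect_error(normalize_to_control(bad, "diameter", "ctrl"), "e2")
})

test_that("min-max scaling maps rows onto [0, 1] elementwise", {
  expect_equal(as.numeric(minmax_scale(matrix(c(10, 20, 30), 1))),
               c(0, 0.5, 1))
  set.seed(9)
  m <- matrix(rnorm(60), 10, 6)
  sc <- minmax_scale(m)
  oracle <- t(apply(m, 1, function(r) (r - min(r)) / (max(r) - min(r))))
  expect_equal(unclass(sc)[, ], oracle, ignore_attr = TRUE)
  expect_true(all(sc >= 0 & sc <= 1))
  # order preserved within each cytokine
  for (i in 1:10) expect_identical(order(sc[i, ]), order(m[i, ]))
  # row maxima map to 1
  expect_true(all(apply(sc, 1, max) == 1))
  # constant rows emit the 0.5 mid-level and are flagged
  cst <- minmax_scale(rbind(c(1, 1, 1), c(0, 1, 2)))
  expect_equal(cst[1, ], rep(0.5, 3))
  expect_identical(attr(cst, "flagged_rows"), 1L)
})

test_that("group comparison reproduces the stated tests", {
  tab <- example_table()
  res <- compare_groups(tab, "diameter", test = "anova")
  fit <- stats::aov(value ~ condition,
                    data = aggregate_by_device(tab))
  expect_equal(res$F, summary(fit)[[1]][["F value"]][1])
  expect_equal(res$p, summary(fit)[[1]][["Pr(>F)"]][1])
  expect_identical(nrow(res$tukey), 1L)
  # identical groups: t-test p near 1, F near 0
  same <- data.frame(experiment_id = "e", device_id = paste0("d", 1:8),
                     condition = rep(c("a", "b"), each = 4),
                     metric_name = "m", value = rep(c(1, 2, 3, 4), 2))
  t0 <- compare_groups(same, "m", test = "t")
  expect_gt(t0$p, 0.99)
  a0 <- compare_groups(same, "m", test = "anova")
  expect_lt(a0$F, 1e-20)
  # fully separated groups with tiny jitter: tiny p
  sep <- data.frame(experiment_id = "e", device_id = paste0("d", 1:8),
                    condition = rep(c("a", "b"), each = 4),
                    metric_name = "m",
                    value = c(0, 1e-4, -1e-4, 2e-5, 10, 10.0001, 9.9999, 10))
  expect_lt(compare_groups(sep, "m", test = "t")$p, 1e-6)
  # degenerate groups are named
  deg <- sep[-(1:3), ]
  expect_error(compare_groups(deg, "m"), "a")
})

test_that("paired t-test pairs on device within condition", {
  tab <- data.frame(experiment_id = "e", device_id = rep(paste0("d", 1:5), 2),
                    condition = rep(c("pre", "post"), each = 5),
                    metric_name = "m",
                    value = c(1, 2, 3, 4, 5, 2.2, 3.1, 4.3, 5.2, 6.4))
  res <- compare_groups(tab, "m", test = "paired_t")
  oracle <- stats::t.test(c(2.2, 3.1, 4.3, 5.2, 6.4), c(1, 2, 3, 4, 5),
                          paired = TRUE)
  expect_equal(res$p, oracle$p.value)
})

test_that("ANOVA type-I error is calibrated under a simulated global null", {
  set.seed(2024)
  rejections <- 0L
  n_reps <- 1000L
  for (i in seq_len(n_reps)) {
    v <- rnorm(15)
    g <- rep(c("a", "b", "c"), each = 5)
    p <- summary(stats::aov(v ~ g))[[1]][["Pr(>F)"]][1]
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Tukey family-wise error under the global null stays near alpha", {
  set.seed(77)
  fw <- 0L
  n_reps <- 1000L
  for (i in seq_len(n_reps)) {
    d <- data.frame(v = rnorm(15), g = rep(c("a", "b", "c"), each = 5))
    fit <- stats::aov(v ~ g, data = d)
    an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (an_p < 0.05 && any(stats::TukeyHSD(fit)$g[, "p adj"] < 0.05))
      fw <- fw + 1L
  }
  expect_lte(fw / n_reps, 0.07)
})

test_that("summaries report mean and s.e.m. with single-value flags", {
  tab <- data.frame(experiment_id = "e", device_id = c("d1", "d2", "d3", "d4"),
                    condition = c("a", "a", "a", "b"),
                    metric_name = "m", value = c(1, 2, 3, 7))
  su <- summarize_metric(tab, "m")
  a <- su[su$condition == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sem, sd(c(1, 2, 3)) / sqrt(3))
  b <- su[su$condition == "b", ]
  expect_true(is.na(b$sem))
  expect_identical(b$flag, "single_value")
})

test_that("device aggregation averages fields before testing", {
  tab <- data.frame(experiment_id = "e",
                    device_id = rep(c("d1", "d2"), each = 3),
                    condition = "a", metric_name = "m",
                    value = c(1, 2, 3, 10, 11, 12))
  agg <- aggregate_by_device(tab)
  expect_identical(nrow(agg), 2L)
  expect_equal(sort(agg$value), c(2, 11))
})

test_that("written reports round-trip", {
  dir <- withr::local_tempdir()
  tab <- example_table()
  su <- summarize_metric(tab, "diameter")
  write_report(list(diameter = su), dir, provenance = list(sigma_px = 2))
  back <- utils::read.csv(file.path(dir, "diameter_summary.csv"))
  expect_equal(back$mean, su$mean)
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$provenance$sigma_px, 2)
  expect_equal(js$summaries$diameter$mean, su$mean)
})
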