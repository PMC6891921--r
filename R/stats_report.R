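# Statistical post-processing of morphometry / permeability / tracking
# measurements: per-experiment control normalization, min-max scaling of
# cytokine panels, and group comparison by one-way ANOVA with Tukey
# contrasts or t-tests. The replication unit is the device: field-of-view
# measurements are averaged per device before testing.

#' Validate a measurement table
#'
#' A measurement table is a data frame with columns `experiment_id`,
#' `device_id`, `condition`, `metric_name`, `value`.
#'
#' @param table data frame
#' @return the table, invisibly, after validation
#' @export
validate_measurement_table <- function(table) {
  need <- c("experiment_id", "device_id", "condition", "metric_name", "value")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  if (!is.numeric(table$value)) stop("value column must be numeric")
  invisible(table)
}

#' Normalize measurements to each experiment's control mean
#'
#' Every value is divided by the mean of the control condition within its
#' own experiment, so the control group's normalized mean is exactly 1 per
#' experiment. This removes between-experiment scale variability before
#' pooling.
#'
#' @param table measurement table (see [validate_measurement_table()])
#' @param metric metric to normalize (`metric_name` value)
#' @param control_label `condition` label of the control group
#' @return the table rows for `metric` with `value` replaced by the
#'   normalized value
#' @export
normalize_to_control <- function(table, metric, control_label) {
  validate_measurement_table(table)
  tab <- table[table$metric_name == metric, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for metric ", metric)
  out <- tab
  for (ex in unique(tab$experiment_id)) {
    sel <- tab$experiment_id == ex
    ctrl <- tab$value[sel & tab$condition == control_label]
    if (length(ctrl) == 0)
      stop("experiment ", ex, " has no control ('", control_label, "') rows")
    out$value[sel] <- tab$value[sel] / mean(ctrl)
  }
  out
}

#' Min-max scale a cytokine intensity matrix to \[0, 1\]
#'
#' Each row (cytokine) is scaled by `(x - min) / (max - min)` across its
#' columns (conditions), mapping the row maximum to 1 and minimum to 0.
#' Constant rows cannot be scaled; they are emitted as the mid-level 0.5 and
#' listed in the `"flagged_rows"` attribute.
#'
#' @param mat numeric matrix, cytokines in rows
#' @return matrix of the same shape in \[0, 1\], with attribute
#'   `flagged_rows` (integer indices of constant rows)
#' @export
minmax_scale <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  out <- mat
  flagged <- integer(0)
  for (i in seq_len(nrow(mat))) {
    rng <- range(mat[i, ])
    if (diff(rng) == 0) {
      out[i, ] <- 0.5
      flagged <- c(flagged, i)
    } else {
      out[i, ] <- (mat[i, ] - rng[1]) / (rng[2] - rng[1])
    }
  }
  structure(out, flagged_rows = flagged)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

#' Average field-of-view measurements per device
#'
#' The device is the replication unit: repeated measurements within one
#' device are averaged before group testing.
#'
#' @param table measurement table
#' @return one row per (experiment, device, condition, metric)
#' @export
aggregate_by_device <- function(table) {
  validate_measurement_table(table)
  agg <- stats::aggregate(
    value ~ experiment_id + device_id + condition + metric_name,
    data = table, FUN = mean)
  agg
}

#' Compare groups with ANOVA/Tukey or t-tests
#'
#' `test = "anova"`: one-way ANOVA across conditions with Tukey HSD pairwise
#' contrasts. `test = "t"`: Welch two-sample t-test (two groups).
#' `test = "paired_t"`: paired t-test, pairing on sorted `device_id` within
#' condition. Significance stars use the 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param table measurement table
#' @param metric metric to test
#' @param test `"anova"`, `"t"` or `"paired_t"`
#' @param by_device average fields per device first (default TRUE)
#' @return object of class `group_comparison`: for ANOVA, `F`, `p`,
#'   `tukey` (data frame of pairwise contrasts with adjusted p and stars);
#'   for t-tests, `statistic`, `p`, `stars`
#' @export
compare_groups <- function(table, metric, test = c("anova", "t", "paired_t"),
                           by_device = TRUE) {
  test <- match.arg(test)
  validate_measurement_table(table)
  tab <- table[table$metric_name == metric, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for metric ", metric)
  if (by_device) tab <- aggregate_by_device(tab)
  counts <- table(tab$condition)
  bad <- names(counts)[counts < 2]
  if (length(bad))
    stop("degenerate groups (< 2 values): ", paste(bad, collapse = ", "))
  tab$condition <- factor(tab$condition)
  if (test == "anova") {
    fit <- stats::aov(value ~ condition, data = tab)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$condition
    tukey <- data.frame(
      contrast = rownames(tk), diff = tk[, "diff"],
      p_adj = tk[, "p adj"], stars = significance_stars(tk[, "p adj"]),
      row.names = NULL)
    res <- list(test = "anova", F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                stars = significance_stars(an[["Pr(>F)"]][1]), tukey = tukey)
  } else {
    lv <- levels(tab$condition)
    if (length(lv) != 2) stop("t-tests require exactly 2 groups")
    x <- tab$value[tab$condition == lv[1]]
    y <- tab$value[tab$condition == lv[2]]
    if (test == "paired_t") {
      ox <- order(tab$device_id[tab$condition == lv[1]])
      oy <- order(tab$device_id[tab$condition == lv[2]])
      if (length(x) != length(y))
        stop("paired t-test requires equal group sizes")
      ht <- stats::t.test(x[ox], y[oy], paired = TRUE)
    } else {
      ht <- stats::t.test(x, y) # Welch
    }
    res <- list(test = test, statistic = unname(ht$statistic),
                p = ht$p.value, stars = significance_stars(ht$p.value))
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test == "anova") {
    cat(sprintf("<group_comparison> one-way ANOVA F = %.3f, p = %.4g %s\n",
                x$F, x$p, x$stars))
    print(x$tukey, row.names = FALSE)
  } else {
    cat(sprintf("<group_comparison> %s: statistic = %.3f, p = %.4g %s\n",
                x$test, x$statistic, x$p, x$stars))
  }
  invisible(x)
}

#' Per-condition summary (mean and s.e.m.)
#'
#' @param table measurement table
#' @param metric metric to summarize
#' @param by_device average fields per device first (default TRUE)
#' @return data frame: condition, n, mean, sem (`NA` with flag column when
#'   n = 1)
#' @export
summarize_metric <- function(table, metric, by_device = TRUE) {
  validate_measurement_table(table)
  tab <- table[table$metric_name == metric, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for metric ", metric)
  if (by_device) tab <- aggregate_by_device(tab)
  conds <- unique(tab$condition)
  do.call(rbind, lapply(conds, function(cc) {
    v <- tab$value[tab$condition == cc]
    data.frame(condition = cc, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               flag = if (length(v) > 1) NA_character_ else "single_value",
               stringsAsFactors = FALSE)
  }))
}

#' Write a combined analysis report
#'
#' Writes per-condition summary tables as CSV and a JSON bundle with the
#' summaries plus any provenance supplied.
#'
#' @param summaries named list of data frames (e.g. from
#'   [summarize_metric()])
#' @param dir output directory
#' @param provenance list of preprocessing/analysis parameters to record
#' @return `dir`, invisibly
#' @export
write_report <- function(summaries, dir, provenance = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(summaries)) {
    utils::write.csv(summaries[[nm]],
                     file.path(dir, paste0(nm, "_summary.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(summaries = summaries, provenance = provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
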