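# Shared fixture builders; everything is generated in code.

# single straight tube with sub-pixel centre (realistic phase)
tube_phantom <- function(p1 = c(60.4, 128.3), p2 = c(200.4, 128.3),
                         radius = 5, shape = c(256, 256), seed = 3,
                         noise = 0) {
  generate_network_phantom(phantom_spec(
    shape, branches = list(list(points = rbind(p1, p2), radius_px = radius)),
    noise_sigma = noise, seed = seed))
}

# Y-shaped thin mask (already 1 px wide), arms of length `arm`
y_mask <- function(arm = 9) {
  m <- matrix(FALSE, 4 * arm, 4 * arm)
  c0 <- 2 * arm
  m[c0, (c0 - arm):c0] <- TRUE
  for (i in 1:arm) {
    m[c0 - i, c0 + i] <- TRUE
    m[c0 + i, c0 + i] <- TRUE
  }
  m
}

# standard leakage phantom geometry used across permeability tests: a small
# bifurcated network whose p_v/A_T keeps the constant-flux assumption valid
# across the whole P grid
leakage_phantom <- function(seed = 7) {
  br <- random_vessel_network(c(256, 256), n_splits = 1, radius_px = 5,
                              seed = seed)
  generate_network_phantom(phantom_spec(branches = br, seed = seed))
}

# cohort phantom for tracking: parallel tubes leave room for separated paths
cohort_phantom <- function(seed = 11) {
  br <- parallel_tube_network(c(256, 256), n_tubes = 3, radius_px = 6,
                              seed = seed)
  generate_network_phantom(phantom_spec(branches = br, seed = seed))
}

cohort_fates <- c(rep("intravascular", 4), rep("transmigrating", 3),
                  rep("extravasated", 3))
cohort_speeds <- c(2.5, 3, 4, 2, 5, 3.5, 4.5, 6, 5.5, 4)

# match each estimated track to the true track starting nearest to it
match_tracks <- function(estimated, truth) {
  vapply(estimated, function(tr) {
    p <- tr$positions
    which.min(vapply(truth, function(t0)
      (t0$positions$x_px[1] - p$x_px[1])^2 +
        (t0$positions$y_px[1] - p$y_px[1])^2, numeric(1)))
  }, integer(1))
}

# match skeleton branches to generator branches by midpoint proximity
match_branches <- function(graph, branches) {
  tmid <- t(vapply(branches, function(b) colMeans(b$points), numeric(2)))
  smid <- t(vapply(graph$branches, function(b) {
    p <- b$path[ceiling(nrow(b$path) / 2), ]
    c(p[2], p[1]) # (x, y)
  }, numeric(2)))
  unname(apply(outer(smid[, 1], tmid[, 1], `-`)^2 +
                 outer(smid[, 2], tmid[, 2], `-`)^2, 1, which.min))
}

# measurement table with two experiments for the stats module
example_table <- function() {
  data.frame(
    experiment_id = rep(c("e1", "e2"), each = 6),
    device_id = paste0("d", 1:12),
    condition = rep(c("ctrl", "ctrl", "ctrl", "trt", "trt", "trt"), 2),
    metric_name = "diameter",
    value = c(2, 4, 3, 3, 6, 9, 10, 10, 10, 5, 15, 25)
  )
}
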