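test_that("empty network gives zero coverage and empty topology", {
  ph <- generate_network_phantom(phantom_spec(branches = list(), seed = 1))
  expect_identical(ph$truth$area_fraction, 0)
  expect_identical(ph$truth$n_junctions, 0L)
  expect_identical(ph$truth$n_endpoints, 0L)
  expect_true(all(ph$stack$channels$EC == 20))
})

test_that("single tube footprint matches a direct distance-to-segment count", {
  p1 <- c(60, 128); p2 <- c(160, 128); r <- 5
  ph <- tube_phantom(p1, p2, radius = r, seed = 1)
  # oracle: count pixel centres within r of the segment
  cnt <- 0L
  for (y in 118:138) for (x in 50:170) {
    tpar <- max(0, min(1, ((x - p1[1]) * (p2[1] - p1[1]) +
                             (y - p1[2]) * (p2[2] - p1[2])) /
                         sum((p2 - p1)^2)))
    d2 <- (x - (p1[1] + tpar * (p2[1] - p1[1])))^2 +
      (y - (p1[2] + tpar * (p2[2] - p1[2])))^2
    if (d2 <= r^2) cnt <- cnt + 1L
  }
  expect_identical(sum(ph$truth$mask), cnt)
  expect_equal(ph$truth$area_fraction, cnt / (256 * 256))
  expect_identical(ph$truth$n_junctions, 0L)
  expect_identical(ph$truth$n_endpoints, 2L)
  expect_length(ph$truth$branch_lengths_px, 1)
})

test_that("identical spec and seed give bit-identical phantoms", {
  sp <- phantom_spec(branches = parallel_tube_network(seed = 2),
                     noise_sigma = 8, seed = 99)
  a <- generate_network_phantom(sp)
  b <- generate_network_phantom(sp)
  expect_identical(a$stack$channels$EC, b$stack$channels$EC)
  expect_identical(a$truth$mask, b$truth$mask)
})

test_that("out-of-bounds polylines are rejected naming the branch", {
  br <- list(list(points = rbind(c(10, 10), c(300, 10)), radius_px = 4))
  expect_error(phantom_spec(branches = br), "branch 1")
})

test_that("truth area fraction equals mask pixel count over total pixels", {
  for (s in 1:3) {
    ph <- generate_network_phantom(phantom_spec(
      branches = random_vessel_network(n_splits = 2, seed = s), seed = s))
    expect_identical(ph$truth$area_fraction,
                     sum(ph$truth$mask) / length(ph$truth$mask))
  }
})

test_that("thin 3D stack mode projects back to the 2D phantom", {
  sp <- phantom_spec(branches = parallel_tube_network(seed = 3),
                     n_slices = 5, seed = 5)
  ph <- generate_network_phantom(sp)
  expect_identical(dim(ph$stack$channels$EC)[3], 5L)
  proj <- max_project(ph$stack, "EC")
  expect_identical(proj > 100, ph$truth$mask)
})

test_that("noise-free leakage series follows the forward model exactly", {
  ph <- leakage_phantom()
  lk <- leakage_spec(P_true = 1e-6, frame_interval_s = 300, n_frames = 4)
  ser <- simulate_leakage_series(ph$truth, lk)
  a <- ser$channels$dextran
  geom <- region_partition(ph$truth$mask, 1)
  m <- ph$truth$mask
  # frame 0 extravascular exactly I_T0; intravascular exactly I_V0
  expect_equal(mean(a[, , 1][!m]), 20)
  expect_true(all(a[, , 1][m] == 200))
  # slope of extravascular mean vs t equals P * p_v * contrast / A_T
  tms <- (0:3) * 300
  means <- vapply(1:4, function(k) mean(a[, , k][!m]), numeric(1))
  slope <- stats::coef(stats::lm(means ~ tms))[2]
  expected <- 1e-6 * geom$p_v_cm * 180 / geom$A_T_cm2
  expect_lt(abs(slope - expected) / expected, 1e-9)
})

test_that("zero-permeability leakage series stays at I_T0", {
  ph <- leakage_phantom()
  ser <- simulate_leakage_series(ph$truth, leakage_spec(P_true = 0))
  a <- ser$channels$dextran
  for (k in seq_len(dim(a)[3]))
    expect_true(all(a[, , k][!ph$truth$mask] == 20))
})

test_that("leakage series rejects parameters that break constant flux", {
  ph <- leakage_phantom()
  expect_error(simulate_leakage_series(
    ph$truth, leakage_spec(P_true = 1e-3, n_frames = 4)),
    "constant-flux")
})

test_that("stationary particles and straight kinematics are exact", {
  ph <- cohort_phantom()
  mo <- motion_spec(speeds_um_min = 0, fates = "intravascular", seed = 1)
  sim <- simulate_pmn_motion(ph$truth, mo)
  p <- sim$tracks[[1]]$positions
  expect_equal(var(p$x_px), 0)
  expect_equal(var(p$y_px), 0)
  # 2.5 um/min at 2-min frames and 1 um/px = 5 px per frame
  mo2 <- motion_spec(speeds_um_min = 2.5, fates = "intravascular", seed = 2)
  p2 <- simulate_pmn_motion(ph$truth, mo2)$tracks[[1]]$positions
  steps <- sqrt(diff(p2$x_px)^2 + diff(p2$y_px)^2)
  expect_equal(steps, rep(5, 4), tolerance = 1e-12)
})

test_that("generated fates satisfy their geometric definitions", {
  ph <- cohort_phantom()
  mo <- motion_spec(speeds_um_min = cohort_speeds, fates = cohort_fates,
                    seed = 4)
  sim <- simulate_pmn_motion(ph$truth, mo)
  for (i in seq_along(sim$tracks)) {
    tr <- sim$tracks[[i]]
    expect_identical(classify_track(tr, ph$truth$mask, 2), cohort_fates[i])
  }
})

test_that("impossible fates raise an error", {
  # a mask filling (almost) the frame leaves no extravascular space
  m <- matrix(TRUE, 64, 64); m[1, 1] <- FALSE
  truth <- generate_network_phantom(phantom_spec(
    c(64, 64), branches = list(), seed = 1))$truth
  truth$mask <- m
  expect_error(simulate_pmn_motion(
    truth, motion_spec(3, "extravasated", seed = 1)),
    "impossible|constrained")
})

test_that("phantom round-trips through TIFF and JSON on disk", {
  dir <- withr::local_tempdir()
  ph <- tube_phantom(seed = 6)
  write_phantom(ph, dir, "t")
  img <- read_tiff_stack(file.path(dir, "t.tif"))
  expect_equal(dim(img), dim(ph$stack$channels$EC))
  msk <- read_tiff_stack(file.path(dir, "t_mask.tif"))
  expect_identical(msk > 0.5, ph$truth$mask)
  tr <- jsonlite::read_json(file.path(dir, "t_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$area_fraction, ph$truth$area_fraction)
})
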