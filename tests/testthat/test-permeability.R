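test_that("region partition matches square geometry and is additive", {
  px_cm <- 1e-4
  sq <- matrix(FALSE, 60, 60); sq[20:39, 20:39] <- TRUE
  rp <- region_partition(sq, pixel_size_um = 1)
  expect_lt(abs(rp$perimeter_px - 4 * 20), 1) # within one pixel-equivalent
  expect_equal(rp$A_T_cm2, (60 * 60 - 400) * px_cm^2)
  # two disjoint squares: perimeters add
  one <- matrix(FALSE, 60, 60); one[5:14, 5:14] <- TRUE
  two <- one; two[40:49, 40:49] <- TRUE
  expect_equal(perimeter_px(two), 2 * perimeter_px(one))
})

test_that("tube perimeter is within 5% of the analytic capsule boundary", {
  # axis-aligned and 45-degree capsules, where the contour chain metric is
  # exact on the straight sides (oblique boundaries carry the chain metric's
  # inherent digital-line bias of up to ~7%, see the methods vignette)
  for (r in c(4, 6)) {
    ph <- tube_phantom(c(50.2, 120.7), c(190.2, 120.7), radius = r,
                       seed = r + 1)
    analytic <- 2 * 140 + 2 * pi * r
    expect_lt(abs(perimeter_px(ph$truth$mask) - analytic) / analytic, 0.05)
    ph45 <- tube_phantom(c(50.2, 50.7), c(150.2, 150.7), radius = r,
                         seed = r + 2)
    analytic45 <- 2 * 100 * sqrt(2) + 2 * pi * r
    expect_lt(abs(perimeter_px(ph45$truth$mask) - analytic45) / analytic45,
              0.05)
  }
})

test_that("region partition rejects empty and full masks", {
  expect_error(region_partition(matrix(FALSE, 8, 8)), "empty")
  expect_error(region_partition(matrix(TRUE, 8, 8)), "full")
})

test_that("mean intensities recover construction values", {
  m <- matrix(FALSE, 20, 20); m[8:12, 4:16] <- TRUE
  fr <- matrix(20, 20, 20); fr[m] <- 200
  ser <- array(fr, c(20, 20, 2))
  ints <- mean_intensities(ser, m)
  expect_identical(ints$I_V0, 200)
  expect_identical(ints$I_T0, 20)
  # leakage phantom: frame 0 and final frame match the forward model
  ph <- leakage_phantom()
  lk <- leakage_spec(P_true = 2e-6, frame_interval_s = 300, n_frames = 4)
  ser2 <- simulate_leakage_series(ph$truth, lk)
  geom <- region_partition(ph$truth$mask, 1)
  ints2 <- mean_intensities(ser2$channels$dextran, ph$truth$mask)
  expect_equal(ints2$I_T0, 20)
  model_final <- 20 + 2e-6 * geom$p_v_cm * 900 * 180 / geom$A_T_cm2
  expect_lt(abs(ints2$I_Tf[4] - model_final) / model_final, 1e-9)
  expect_error(mean_intensities(ser2$channels$dextran,
                                matrix(FALSE, 4, 4)), "shape")
})

test_that("the permeability formula reproduces hand arithmetic", {
  # A_T = 2e-4 cm^2, p_v = 0.1 cm, t = 300 s, contrast 100, rise 3
  res <- permeability(A_T = 2e-4, p_v = 0.1, t = 300,
                      I_V0 = 120, I_T0 = 20, I_Tf = 23)
  expect_equal(res$P_cm_per_s, 2e-7)
  # no leakage: exactly zero
  expect_identical(permeability(A_T = 2e-4, p_v = 0.1, t = 300, I_V0 = 120,
                                I_T0 = 20, I_Tf = 20)$P_cm_per_s, 0)
  expect_error(permeability(A_T = 2e-4, p_v = 0.1, t = 300,
                            I_V0 = 20, I_T0 = 20, I_Tf = 25), "contrast")
  expect_error(permeability(A_T = 2e-4, p_v = 0.1, t = -1,
                            I_V0 = 120, I_T0 = 20, I_Tf = 25), "t must")
})

test_that("permeability is invariant to common intensity scaling", {
  r1 <- permeability(A_T = 3e-4, p_v = 0.05, t = 600,
                     I_V0 = 150, I_T0 = 30, I_Tf = 38)
  r2 <- permeability(A_T = 3e-4, p_v = 0.05, t = 600,
                     I_V0 = 1500, I_T0 = 300, I_Tf = 380)
  expect_equal(r1$P_cm_per_s, r2$P_cm_per_s)
})

test_that("pixel and cm unit paths agree", {
  ph <- tube_phantom(seed = 20)
  m <- ph$truth$mask
  rp <- region_partition(m, pixel_size_um = 2)
  px_cm <- 2e-4
  expect_equal(rp$p_v_cm, rp$perimeter_px * px_cm, tolerance = 1e-12)
  expect_equal(rp$A_T_cm2, rp$tissue_px * px_cm^2, tolerance = 1e-12)
})

test_that("noise-free series recover P_true within 1% at each interval", {
  ph <- leakage_phantom()
  for (P in c(1e-7, 1e-6, 1e-5)) {
    ser <- simulate_leakage_series(ph$truth, leakage_spec(
      P_true = P, frame_interval_s = 300, n_frames = 4))
    m <- binarize(ser$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
    res <- permeability_series(ser, m, channel = "dextran")
    expect_lt(abs(res$P_cm_per_s - P) / P, 0.01)
    expect_true(all(abs(res$per_interval$P_cm_per_s - P) / P < 0.01))
    # constant-flux phantom: intervals agree with each other within 2%
    expect_lt(diff(range(res$per_interval$P_cm_per_s)) / P, 0.02)
  }
})

test_that("a two-frame series reduces to the single-interval formula", {
  ph <- leakage_phantom()
  ser <- simulate_leakage_series(ph$truth, leakage_spec(
    P_true = 5e-7, frame_interval_s = 300, n_frames = 2))
  m <- binary_mask(ph$truth$mask, 1)
  res <- permeability_series(ser, m, channel = "dextran")
  geom <- region_partition(m)
  ints <- mean_intensities(ser$channels$dextran, m)
  single <- permeability(A_T = geom$A_T_cm2, p_v = geom$p_v_cm, t = 300,
                         I_V0 = ints$I_V0, I_T0 = ints$I_T0,
                         I_Tf = ints$I_Tf[2])
  expect_equal(res$P_cm_per_s, unname(single$P_cm_per_s))
})

test_that("noisy series recover P with median relative error under 10%", {
  ph <- leakage_phantom()
  for (P in c(1e-7, 1e-6, 1e-5)) {
    errs <- vapply(1:20, function(s) {
      ser <- simulate_leakage_series(ph$truth, leakage_spec(
        P_true = P, frame_interval_s = 300, n_frames = 4,
        noise_sigma = 0.05 * 180, seed = s))
      m <- binarize(ser$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
      res <- permeability_series(ser, m, channel = "dextran")
      abs(res$P_cm_per_s - P) / P
    }, numeric(1))
    expect_lt(median(errs), 0.10)
  }
})

test_that("null permeability estimates centre on zero", {
  ph <- leakage_phantom()
  Ps <- vapply(1:20, function(s) {
    ser <- simulate_leakage_series(ph$truth, leakage_spec(
      P_true = 0, frame_interval_s = 300, n_frames = 4,
      noise_sigma = 0.05 * 180, seed = 100 + s))
    m <- binarize(ser$channels$dextran[, , 1], "otsu", pixel_size_um = 1)
    permeability_series(ser, m, channel = "dextran")$P_cm_per_s
  }, numeric(1))
  se <- sd(Ps) / sqrt(length(Ps))
  expect_lt(abs(mean(Ps)), 2 * se)
})

test_that("assumption monitors flag decreasing tissue signal", {
  m <- matrix(FALSE, 30, 30); m[12:18, 5:25] <- TRUE
  ser <- array(20, c(30, 30, 3))
  for (k in 1:3) { fr <- matrix(c(25, 22, 18)[k], 30, 30); fr[m] <- 200
                   ser[, , k] <- fr }
  res <- permeability_series(ser, binary_mask(m, 1), frame_interval_s = 300)
  expect_true("decreasing_extravascular" %in% res$flags)
})
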