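test_that("area coverage is exact on constructed masks", {
  m <- matrix(FALSE, 10, 10)
  expect_identical(area_coverage(m), 0)
  m[1:5, ] <- TRUE
  expect_identical(area_coverage(m), 50)
  ph <- tube_phantom(seed = 2)
  expect_identical(area_coverage(ph$truth$mask),
                   100 * ph$truth$area_fraction)
})

test_that("already-thin lines skeletonize to themselves", {
  line <- matrix(FALSE, 20, 120); line[10, 10:110] <- TRUE
  g <- skeletonize(line, min_branch_px = 0)
  expect_identical(g$skeleton, line)
  expect_identical(g$n_junctions, 0L)
  expect_identical(g$n_endpoints, 2L)
  expect_length(g$branches, 1)
  expect_equal(branch_lengths(g), 100)
  # diagonal line: 10 steps of sqrt(2)
  d <- matrix(FALSE, 30, 30)
  for (i in 0:10) d[10 + i, 10 + i] <- TRUE
  expect_equal(branch_lengths(skeletonize(d, min_branch_px = 0)),
               10 * sqrt(2))
})

test_that("a Y-shaped mask yields one junction, three endpoints, three branches", {
  g <- skeletonize(y_mask(9), min_branch_px = 0)
  expect_identical(g$n_junctions, 1L)
  expect_identical(g$n_endpoints, 3L)
  expect_length(g$branches, 3)
  expect_equal(connectivity_ratio(g), 1 / 3)
})

test_that("connectivity ratio handles degenerate graphs with flags", {
  seg <- skeletonize(matrix(c(rep(FALSE, 20), rep(TRUE, 10), rep(FALSE, 20)),
                            5, 10), min_branch_px = 0)
  expect_identical(as.numeric(connectivity_ratio(seg)), 0)
  empty <- skeletonize(matrix(FALSE, 8, 8))
  cr <- connectivity_ratio(empty)
  expect_identical(as.numeric(cr), 0)
  expect_identical(attr(cr, "flag"), "empty")
  # a ring has no nodes at all: loops-only sentinel
  ring <- matrix(FALSE, 40, 40)
  for (a in seq(0, 2 * pi, length.out = 200))
    ring[round(20 + 12 * sin(a)), round(20 + 12 * cos(a))] <- TRUE
  g <- skeletonize(ring, min_branch_px = 0)
  if (g$n_endpoints == 0 && g$n_junctions == 0) {
    expect_length(g$branches, 1)
    expect_identical(attr(connectivity_ratio(g), "flag"), "empty")
  }
})

test_that("node counts equal a brute-force neighbour-count classification", {
  for (s in c(3, 8, 13)) {
    ph <- generate_network_phantom(phantom_spec(
      branches = random_vessel_network(n_splits = 2, seed = s), seed = s))
    g <- skeletonize(ph$truth$mask)
    sk <- g$skeleton
    deg <- matrix(0L, nrow(sk), ncol(sk))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      sh <- matrix(FALSE, nrow(sk), ncol(sk))
      ys <- seq_len(nrow(sk)) - dy; xs <- seq_len(ncol(sk)) - dx
      oky <- ys >= 1 & ys <= nrow(sk); okx <- xs >= 1 & xs <= ncol(sk)
      sh[oky, okx] <- sk[ys[oky], xs[okx]]
      deg <- deg + sh
    }
    expect_identical(g$n_endpoints, sum(sk & deg == 1))
    jcl <- vesselquant:::label_components(sk & deg >= 3, 8)
    expect_identical(g$n_junctions, max(jcl))
  }
})

test_that("skeleton pixels always lie inside the source mask", {
  for (s in 1:3) {
    ph <- generate_network_phantom(phantom_spec(
      branches = random_vessel_network(n_splits = 3, seed = s), seed = s))
    g <- skeletonize(ph$truth$mask)
    expect_true(all(ph$truth$mask[g$skeleton]))
  }
})

test_that("dilation never decreases area coverage", {
  ph <- tube_phantom(seed = 4)
  m <- ph$truth$mask
  dil <- EBImage::dilate(m * 1, EBImage::makeBrush(5, "disc")) > 0
  expect_gte(area_coverage(dil), area_coverage(m))
})

test_that("micrometre outputs scale with pixel size; ratios do not", {
  ph <- generate_network_phantom(phantom_spec(
    branches = random_vessel_network(n_splits = 2, seed = 5), seed = 5))
  g1 <- skeletonize(ph$truth$mask, pixel_size_um = 1)
  g2 <- skeletonize(ph$truth$mask, pixel_size_um = 2)
  expect_equal(branch_lengths(g2), 2 * branch_lengths(g1))
  expect_identical(connectivity_ratio(g1), connectivity_ratio(g2))
  d1 <- diameter_profile(ph$truth$mask, g1)$mean_diameter_um
  d2 <- diameter_profile(ph$truth$mask, g2)$mean_diameter_um
  expect_equal(d2, 2 * d1)
  expect_identical(area_coverage(binary_mask(ph$truth$mask, 1)),
                   area_coverage(binary_mask(ph$truth$mask, 2)))
})

test_that("diameters follow the maximal-ball distance-transform convention", {
  # integer-centred disc: EDT at the centre is sqrt(r^2 + 1) ~ r
  disc <- matrix(FALSE, 41, 41)
  for (y in 1:41) for (x in 1:41)
    if ((y - 21)^2 + (x - 21)^2 <= 100) disc[y, x] <- TRUE
  edt <- vesselquant:::edt_mask(disc)
  expect_equal(edt[21, 21], sqrt(101), tolerance = 1e-6)
  expect_lt(abs(2 * edt[21, 21] - 20), 0.2)
  # 11-px-tall bar reads its height within one pixel
  bar <- matrix(FALSE, 31, 60); bar[10:20, 5:55] <- TRUE
  g <- skeletonize(bar)
  dp <- diameter_profile(bar, g)
  expect_lt(abs(dp$mean_diameter_um - 11), 1.01)
  # phantom tubes of radii 4 and 8 px within 10% of diameters 8 and 16
  for (r in c(4, 8)) {
    ph <- tube_phantom(c(50.3, 100.6), c(210.3, 140.6), radius = r, seed = r)
    g <- skeletonize(ph$truth$mask)
    dp <- diameter_profile(ph$truth$mask, g)
    expect_lt(abs(dp$mean_diameter_um - 2 * r) / (2 * r), 0.1)
  }
})

test_that("morphometry record composes the individual statistics", {
  ph <- tube_phantom(seed = 14)
  mask <- binary_mask(ph$truth$mask, 1)
  g <- skeletonize(mask)
  rec <- morphometry_record(mask, g)
  expect_equal(rec$coverage_pct, area_coverage(mask))
  expect_equal(rec$mean_branch_length_um, mean(branch_lengths(g)))
  expect_identical(rec$n_junctions, g$n_junctions)
  expect_identical(rec$n_endpoints, g$n_endpoints)
  expect_equal(rec$mean_diameter_um,
               diameter_profile(mask, g)$mean_diameter_um)
  df <- as.data.frame(rec)
  expect_identical(nrow(df), 1L)
  # empty mask: flagged, zero counts
  e <- morphometry_record(binary_mask(matrix(FALSE, 16, 16), 1))
  expect_identical(e$coverage_pct, 0)
  expect_identical(e$branch_count, 0L)
  expect_identical(e$connectivity_flag, "empty")
  expect_true(is.na(e$mean_diameter_um))
})
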