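# Synthetic confocal-like phantoms with exact ground truth. Three
# generators: fluorescent tubular networks of known topology and radii,
# dextran leakage time-lapses with a known permeability, and migrating
# leukocyte-like particles with known paths and fates. Every generator is
# deterministic given its spec and seed.

#' Specify a tubular-network phantom
#'
#' The network is a list of branches; each branch is a polyline of control
#' points with a tube radius. A pixel belongs to a branch iff its centre
#' lies within `radius_px` (Euclidean) of the polyline, which makes the
#' rasterized footprint analytically checkable. Coordinates are continuous
#' pixel positions `(x, y)` with `(1, 1)` at the top-left pixel centre.
#'
#' @param image_shape `c(H, W)` in pixels
#' @param pixel_size_um micrometres per pixel
#' @param branches list of `list(points = n x 2 matrix of (x, y),
#'   radius_px = r)`
#' @param vessel_intensity,background_intensity fluorescence levels (a.u.);
#'   vessel must exceed background
#' @param noise_sigma additive Gaussian noise s.d. (a.u.), clipped at 0
#' @param n_slices if > 1, an optional thin 3D mode: the 2D footprint is
#'   replicated across z with independent per-slice noise (for projection
#'   testing)
#' @param seed integer RNG seed
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(image_shape = c(256, 256), pixel_size_um = 1,
                         branches = list(), vessel_intensity = 200,
                         background_intensity = 20, noise_sigma = 0,
                         n_slices = 1, seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8),
            pixel_size_um > 0, noise_sigma >= 0, n_slices >= 1)
  if (vessel_intensity <= background_intensity)
    stop("vessel_intensity must exceed background_intensity")
  H <- image_shape[1]; W <- image_shape[2]
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    if (is.null(b$points) || is.null(b$radius_px))
      stop("branch ", i, " must have points and radius_px")
    if (b$radius_px < 1) stop("branch ", i, ": radius_px must be >= 1")
    p <- b$points
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 2)
      stop("branch ", i, ": points must be an n x 2 matrix, n >= 2")
    r <- b$radius_px
    if (any(p[, 1] < 1 + r) || any(p[, 1] > W - r) ||
        any(p[, 2] < 1 + r) || any(p[, 2] > H - r))
      stop("branch ", i, " polyline (with its radius) exceeds image bounds")
  }
  structure(list(image_shape = image_shape, pixel_size_um = pixel_size_um,
                 branches = branches, vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, n_slices = n_slices,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize one branch: logical H x W, TRUE where the pixel centre is within
# radius of the polyline.
rasterize_branch <- function(points, radius, H, W) {
  out <- matrix(FALSE, H, W)
  for (s in seq_len(nrow(points) - 1)) {
    p1 <- points[s, ]; p2 <- points[s + 1, ]
    xmin <- max(1L, floor(min(p1[1], p2[1]) - radius))
    xmax <- min(W, ceiling(max(p1[1], p2[1]) + radius))
    ymin <- max(1L, floor(min(p1[2], p2[2]) - radius))
    ymax <- min(H, ceiling(max(p1[2], p2[2]) + radius))
    xs <- xmin:xmax; ys <- ymin:ymax
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    gy <- matrix(ys, length(ys), length(xs))
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    L2 <- vx^2 + vy^2
    tpar <- if (L2 == 0) matrix(0, length(ys), length(xs)) else
      pmin(1, pmax(0, ((gx - p1[1]) * vx + (gy - p1[2]) * vy) / L2))
    d2 <- (gx - (p1[1] + tpar * vx))^2 + (gy - (p1[2] + tpar * vy))^2
    out[ys, xs] <- out[ys, xs] | (d2 <= radius^2)
  }
  out
}

# Topology of a branch list from the incidence of polyline terminals:
# terminals within 0.5 px are one node; degree-1 nodes are endpoints,
# degree >= 3 are junctions.
network_topology <- function(branches) {
  if (length(branches) == 0)
    return(list(n_junctions = 0L, n_endpoints = 0L, nodes = NULL))
  ends <- do.call(rbind, lapply(branches, function(b)
    rbind(b$points[1, ], b$points[nrow(b$points), ])))
  n <- nrow(ends)
  node <- integer(n)
  nid <- 0L
  for (i in seq_len(n)) {
    if (node[i] > 0L) next
    nid <- nid + 1L
    d <- sqrt((ends[, 1] - ends[i, 1])^2 + (ends[, 2] - ends[i, 2])^2)
    node[d <= 0.5] <- nid
  }
  deg <- tabulate(node, nid)
  list(n_junctions = sum(deg >= 3L), n_endpoints = sum(deg == 1L),
       nodes = data.frame(x = tapply(ends[, 1], node, mean),
                          y = tapply(ends[, 2], node, mean),
                          degree = deg))
}

#' Generate a tubular-network phantom image with exact ground truth
#'
#' Rasterizes each branch as a tube of its radius, fills the footprint with
#' `vessel_intensity` over `background_intensity`, and adds seeded Gaussian
#' noise (clipped at 0). The returned truth holds the exact footprint mask,
#' the network topology implied by the branch list, per-branch polyline
#' lengths and radii, and the exact area fraction. Identical spec and seed
#' give bit-identical output.
#'
#' @param spec a `phantom_spec`
#' @return list with `stack` (an `image_stack`, channel `"EC"`) and `truth`
#'   (class `phantom_truth`: `mask`, `n_junctions`, `n_endpoints`,
#'   `branch_lengths_px`, `branch_radii_px`, `area_fraction`,
#'   `pixel_size_um`)
#' @export
generate_network_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  mask <- matrix(FALSE, H, W)
  for (b in spec$branches)
    mask <- mask | rasterize_branch(b$points, b$radius_px, H, W)
  topo <- network_topology(spec$branches)
  img <- with_seed(spec$seed, {
    base <- matrix(spec$background_intensity, H, W)
    base[mask] <- spec$vessel_intensity
    if (spec$n_slices > 1) {
      a <- array(0, c(H, W, spec$n_slices))
      for (k in seq_len(spec$n_slices)) {
        a[, , k] <- base
        if (spec$noise_sigma > 0)
          a[, , k] <- pmax(a[, , k] + matrix(
            stats::rnorm(H * W, 0, spec$noise_sigma), H, W), 0)
      }
      a
    } else {
      if (spec$noise_sigma > 0)
        base <- pmax(base + matrix(stats::rnorm(H * W, 0,
                                                spec$noise_sigma), H, W), 0)
      base
    }
  })
  truth <- structure(list(
    mask = mask,
    n_junctions = topo$n_junctions,
    n_endpoints = topo$n_endpoints,
    branch_lengths_px = vapply(spec$branches, function(b) {
      d <- diff(b$points)
      sum(sqrt(d[, 1]^2 + d[, 2]^2))
    }, numeric(1)),
    branch_radii_px = vapply(spec$branches, `[[`, numeric(1), "radius_px"),
    area_fraction = sum(mask) / length(mask),
    pixel_size_um = spec$pixel_size_um,
    spec = spec
  ), class = "phantom_truth")
  list(stack = image_stack(list(EC = img),
                           pixel_size_um = spec$pixel_size_um),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", length(x$branch_lengths_px), " branches, ",
      x$n_junctions, " junctions, ", x$n_endpoints, " endpoints, ",
      sprintf("area fraction %.3f\n", x$area_fraction), sep = "")
  invisible(x)
}

# Minimum distance between two segments (each 2 x 2 matrix of (x, y) rows).
segment_distance <- function(a, b) {
  pts <- function(p1, p2, n = 25) {
    tt <- seq(0, 1, length.out = n)
    cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
  }
  pa <- pts(a[1, ], a[2, ]); pb <- pts(b[1, ], b[2, ])
  min(sqrt(outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2))
}

#' Random vessel-tree network of known topology
#'
#' Grows a binary tree of straight tube segments: a trunk, then up to
#' `n_splits` bifurcations. Every split turns one endpoint into a degree-3
#' junction and adds two endpoints, so the resulting topology is known by
#' construction (J junctions, J + 2 endpoints for J successful splits).
#' Candidate segments are rejected when they leave the usable field or pass
#' within `2 * radius + clearance` pixels of a non-adjacent segment, so
#' distinct tubes never merge and skeleton analysis sees the constructed
#' topology. Branch lengths, radii and bifurcation angles default to values
#' typical of microvascular networks imaged at ~1 um/px (tube radii 4-6 px,
#' branches 50-110 px).
#'
#' @param image_shape `c(H, W)`
#' @param n_splits bifurcations to attempt
#' @param radius_px tube radius (one value for the whole network)
#' @param length_range branch length range, px
#' @param angle_range child deviation from the parent direction, radians
#' @param clearance extra separation between non-adjacent tubes, px
#' @param seed integer seed
#' @return list of branches suitable for [phantom_spec()]
#' @export
random_vessel_network <- function(image_shape = c(256, 256), n_splits = 3,
                                  radius_px = 5, length_range = c(50, 110),
                                  angle_range = c(pi / 6, pi / 3),
                                  clearance = 6, seed = 1L) {
  H <- image_shape[1]; W <- image_shape[2]
  r <- radius_px
  lo <- 1 + r + 2; hiX <- W - r - 2; hiY <- H - r - 2
  in_bounds <- function(p) p[1] >= lo && p[1] <= hiX && p[2] >= lo && p[2] <= hiY
  with_seed(seed, {
    segs <- list()   # list of list(p1, p2, parent_node)
    ok_segment <- function(p1, p2, adjacent_pts) {
      if (!in_bounds(p1) || !in_bounds(p2)) return(FALSE)
      for (s in segs) {
        # segments sharing an endpoint with the candidate are adjacent
        shared <- any(vapply(adjacent_pts, function(q)
          sqrt(sum((q - s$p1)^2)) < 0.5 || sqrt(sum((q - s$p2)^2)) < 0.5,
          logical(1)))
        if (shared) next
        if (segment_distance(rbind(p1, p2), rbind(s$p1, s$p2)) <
            2 * r + clearance) return(FALSE)
      }
      TRUE
    }
    # trunk
    trunk <- NULL
    for (try in 1:200) {
      p1 <- c(stats::runif(1, lo + 20, hiX - 20),
              stats::runif(1, lo + 20, hiY - 20))
      th <- stats::runif(1, 0, 2 * pi)
      L <- stats::runif(1, length_range[1], length_range[2])
      p2 <- p1 + L * c(cos(th), sin(th))
      if (in_bounds(p2)) { trunk <- list(p1 = p1, p2 = p2, dir = th); break }
    }
    if (is.null(trunk)) stop("could not place trunk segment")
    segs[[1]] <- list(p1 = trunk$p1, p2 = trunk$p2)
    active <- list(list(pt = trunk$p2, dir = trunk$dir))
    splits_done <- 0L
    while (splits_done < n_splits && length(active) > 0) {
      tip <- active[[1]]; active <- active[-1]
      placed <- FALSE
      for (try in 1:60) {
        a1 <- stats::runif(1, angle_range[1], angle_range[2])
        a2 <- -stats::runif(1, angle_range[1], angle_range[2])
        L1 <- stats::runif(1, length_range[1], length_range[2])
        L2 <- stats::runif(1, length_range[1], length_range[2])
        c1 <- tip$pt + L1 * c(cos(tip$dir + a1), sin(tip$dir + a1))
        c2 <- tip$pt + L2 * c(cos(tip$dir + a2), sin(tip$dir + a2))
        if (!ok_segment(tip$pt, c1, list(tip$pt))) next
        segs_tmp <- segs
        segs[[length(segs) + 1L]] <- list(p1 = tip$pt, p2 = c1)
        if (!ok_segment(tip$pt, c2, list(tip$pt)) ||
            segment_distance(rbind(tip$pt + 0.3 * (c1 - tip$pt), c1),
                             rbind(tip$pt + 0.3 * (c2 - tip$pt), c2)) <
            2 * r + clearance) {
          segs <- segs_tmp
          next
        }
        segs[[length(segs) + 1L]] <- list(p1 = tip$pt, p2 = c2)
        active <- c(active, list(list(pt = c1, dir = tip$dir + a1),
                                 list(pt = c2, dir = tip$dir + a2)))
        placed <- TRUE
        break
      }
      # a tip that cannot host a bifurcation stays a plain endpoint and is
      # not revisited
      if (placed) splits_done <- splits_done + 1L
    }
    lapply(segs, function(s)
      list(points = rbind(s$p1, s$p2), radius_px = r))
  })
}

#' Parallel-tube network
#'
#' A simple perfused-field geometry: `n_tubes` horizontal tubes evenly
#' spaced across the field with sub-pixel jitter in their vertical position.
#' Useful when downstream stages need guaranteed room around each vessel
#' (e.g. particle cohorts with separated, non-crossing paths).
#'
#' @param image_shape `c(H, W)`
#' @param n_tubes number of tubes
#' @param radius_px tube radius
#' @param margin_px gap kept free at the left/right field edges
#' @param seed integer seed (sub-pixel jitter)
#' @return list of branches for [phantom_spec()]
#' @export
parallel_tube_network <- function(image_shape = c(256, 256), n_tubes = 3,
                                  radius_px = 6, margin_px = 24, seed = 1L) {
  H <- image_shape[1]; W <- image_shape[2]
  ys <- seq(H / (n_tubes + 1), H * n_tubes / (n_tubes + 1),
            length.out = n_tubes)
  with_seed(seed, {
    lapply(ys, function(y0) {
      y <- y0 + stats::runif(1, -0.45, 0.45)
      list(points = rbind(c(margin_px, y), c(W - margin_px, y)),
           radius_px = radius_px)
    })
  })
}

#' Specify a dextran-leakage time-lapse
#'
#' Forward model of transendothelial tracer flux at a known permeability:
#' the extravascular intensity rises linearly in time at the rate implied by
#' `P_true` while the intravascular intensity stays at `I_V0`.
#'
#' @param P_true permeability, cm/s (>= 0)
#' @param frame_interval_s seconds between frames
#' @param n_frames number of frames (>= 2), frame 1 at t = 0
#' @param I_V0,I_T0 intravascular / extravascular intensities at t = 0;
#'   `I_V0 > I_T0`
#' @param noise_sigma additive Gaussian noise s.d., clipped at 0
#' @param seed integer seed
#' @return object of class `leakage_spec`
#' @export
leakage_spec <- function(P_true, frame_interval_s = 300, n_frames = 4,
                         I_V0 = 200, I_T0 = 20, noise_sigma = 0, seed = 1L) {
  stopifnot(P_true >= 0, n_frames >= 2, frame_interval_s > 0,
            noise_sigma >= 0)
  if (I_V0 <= I_T0) stop("I_V0 must exceed I_T0")
  structure(list(P_true = P_true, frame_interval_s = frame_interval_s,
                 n_frames = n_frames, I_V0 = I_V0, I_T0 = I_T0,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "leakage_spec")
}

#' Simulate a dextran-leakage time-lapse over a phantom network
#'
#' At frame k (time `t_k = (k - 1) * frame_interval_s`), intravascular
#' pixels hold `I_V0` and extravascular pixels hold
#' `I_T0 + P_true * p_v * t_k * (I_V0 - I_T0) / A_T`, with `p_v` and `A_T`
#' measured from the truth mask in cm. Noise is seeded and added last. If
#' the modelled tissue intensity would reach `I_V0` within the series the
#' constant-flux approximation is broken and an error is raised (shorten the
#' series or lower `P_true`).
#'
#' @param truth a `phantom_truth` with nonempty mask
#' @param leak a `leakage_spec`
#' @return an `image_stack` with channel `"dextran"` (H x W x n_frames) and
#'   `frame_interval_s` set
#' @export
simulate_leakage_series <- function(truth, leak) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(leak, "leakage_spec"))
  mask <- truth$mask
  if (!any(mask)) stop("truth mask is empty")
  geom <- region_partition(mask, truth$pixel_size_um)
  H <- nrow(mask); W <- ncol(mask)
  contrast <- leak$I_V0 - leak$I_T0
  rate <- leak$P_true * geom$p_v_cm * contrast / geom$A_T_cm2  # a.u. per s
  times <- (seq_len(leak$n_frames) - 1) * leak$frame_interval_s
  tissue <- leak$I_T0 + rate * times
  if (any(tissue >= leak$I_V0))
    stop("modelled tissue intensity reaches I_V0 within the series; ",
         "the constant-flux approximation is broken (shorten the series ",
         "or lower P_true)")
  a <- with_seed(leak$seed, {
    out <- array(0, c(H, W, leak$n_frames))
    for (k in seq_len(leak$n_frames)) {
      fr <- matrix(tissue[k], H, W)
      fr[mask] <- leak$I_V0
      if (leak$noise_sigma > 0)
        fr <- pmax(fr + matrix(stats::rnorm(H * W, 0, leak$noise_sigma),
                               H, W), 0)
      out[, , k] <- fr
    }
    out
  })
  image_stack(list(dextran = a), pixel_size_um = truth$pixel_size_um,
              frame_interval_s = leak$frame_interval_s)
}

#' Specify a cohort of migrating leukocyte-like particles
#'
#' @param speeds_um_min per-particle mean speed, um/min (>= 0)
#' @param fates per-particle fate label: `"intravascular"`,
#'   `"transmigrating"` or `"extravasated"`
#' @param frame_interval_s seconds between frames (default 120, i.e. 2-min
#'   intervals)
#' @param n_frames frames in the series (default 5)
#' @param contact_dist_px contact distance defining the transmigrating zone
#'   around the vessel boundary (default 2)
#' @param spot_sigma_px,spot_amplitude,background,noise_sigma rendering
#'   parameters for the Gaussian spots
#' @param seed integer seed
#' @return object of class `motion_spec`
#' @export
motion_spec <- function(speeds_um_min, fates, frame_interval_s = 120,
                        n_frames = 5, contact_dist_px = 2,
                        spot_sigma_px = 1.5, spot_amplitude = 150,
                        background = 10, noise_sigma = 0, seed = 1L) {
  fates <- match.arg(fates, c("intravascular", "transmigrating",
                              "extravasated"), several.ok = TRUE)
  stopifnot(length(speeds_um_min) == length(fates),
            length(speeds_um_min) >= 1,
            all(speeds_um_min >= 0), n_frames >= 2, frame_interval_s > 0)
  structure(list(n_particles = length(fates), speeds_um_min = speeds_um_min,
                 fates = fates, frame_interval_s = frame_interval_s,
                 n_frames = n_frames, contact_dist_px = contact_dist_px,
                 spot_sigma_px = spot_sigma_px,
                 spot_amplitude = spot_amplitude, background = background,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "motion_spec")
}

#' Simulate migrating particles over a phantom network
#'
#' Each particle follows a straight path with a per-frame displacement of
#' exactly `speed * frame_interval`, constructed so that its final position
#' realizes the requested fate geometrically: intravascular particles stay
#' more than `contact_dist_px` inside the vessel for the whole series;
#' transmigrating particles end at the vessel boundary (within
#' `contact_dist_px` of it); extravasated particles end strictly outside,
#' farther than `contact_dist_px` from the boundary. A safety margin of one
#' pixel beyond each bound keeps detection/rounding from flipping the class.
#' Paths are found by seeded rejection sampling; an error is raised when a
#' fate is geometrically impossible on the given mask.
#'
#' Particles are rendered as Gaussian spots on a dark background; start
#' points are kept mutually separated so tracks do not cross.
#'
#' @param truth a `phantom_truth` with nonempty mask
#' @param motion a `motion_spec`
#' @return list with `stack` (an `image_stack`, channel `"PMN"`,
#'   H x W x n_frames) and `tracks` (list of `particle_track` with true
#'   positions and `fate`)
#' @export
simulate_pmn_motion <- function(truth, motion) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(motion, "motion_spec"))
  mask <- truth$mask
  if (!any(mask)) stop("truth mask is empty")
  H <- nrow(mask); W <- ncol(mask)
  d_in <- edt_mask(mask)                       # 0 outside
  d_out <- edt_mask(!mask)                     # 0 inside
  bdist <- ifelse(mask, d_in, d_out)           # distance to the other side
  cd <- motion$contact_dist_px
  margin <- 1
  deep <- mask & bdist > cd + margin
  trans_zone <- bdist <= max(cd - margin, 1)
  extra_zone <- !mask & bdist > cd + margin
  zone_of <- list(intravascular = deep, transmigrating = trans_zone,
                  extravasated = extra_zone)
  pick_px <- function(zone) {
    idx <- which(zone)
    if (!length(idx)) return(NULL)
    i <- idx[sample.int(length(idx), 1)]
    c((i - 1L) %% H + 1L, (i - 1L) %/% H + 1L) # (y, x)
  }
  px <- truth$pixel_size_um
  dt_min <- motion$frame_interval_s / 60
  n_steps <- motion$n_frames - 1

  with_seed(motion$seed, {
    placed <- list()
    tracks <- vector("list", motion$n_particles)
    for (i in seq_len(motion$n_particles)) {
      fate <- motion$fates[i]
      step_px <- motion$speeds_um_min[i] * dt_min / px
      travel <- n_steps * step_px
      zone <- zone_of[[fate]]
      if (!any(zone))
        stop("fate '", fate, "' is geometrically impossible on this mask")
      path <- NULL
      for (try in 1:800) {
        fin <- pick_px(zone)
        fin <- fin + stats::runif(2, -0.25, 0.25)
        if (travel == 0) {
          start <- fin
        } else {
          th <- stats::runif(1, 0, 2 * pi)
          start <- fin - travel * c(sin(th), cos(th)) # (y, x)
        }
        ys <- start[1] + (0:n_steps) / max(n_steps, 1) * (fin[1] - start[1])
        xs <- start[2] + (0:n_steps) / max(n_steps, 1) * (fin[2] - start[2])
        if (any(ys < 2 | ys > H - 1 | xs < 2 | xs > W - 1)) next
        ryx <- cbind(pmin(pmax(round(ys), 1), H), pmin(pmax(round(xs), 1), W))
        if (fate == "intravascular") {
          if (!all(deep[ryx])) next
        } else {
          # start deep inside the vessel, as perfused cells would
          if (travel > 0 && !deep[ryx[1, 1], ryx[1, 2]]) next
        }
        # non-crossing cohort: keep whole paths well separated
        sep_ok <- TRUE
        for (p0 in placed) {
          if (min(sqrt(outer(ys, p0$y, `-`)^2 + outer(xs, p0$x, `-`)^2)) <
              12) { sep_ok <- FALSE; break }
        }
        if (!sep_ok) next
        path <- list(y = ys, x = xs)
        break
      }
      if (is.null(path))
        stop("could not realize fate '", fate,
             "' geometrically (mask too constrained)")
      placed[[length(placed) + 1L]] <- path
      tracks[[i]] <- particle_track(
        t_s = (0:n_steps) * motion$frame_interval_s,
        x_px = path$x, y_px = path$y, track_id = i, fate = fate)
    }
    # render
    a <- array(0, c(H, W, motion$n_frames))
    gx <- matrix(seq_len(W), H, W, byrow = TRUE)
    gy <- matrix(seq_len(H), H, W)
    s2 <- 2 * motion$spot_sigma_px^2
    for (k in seq_len(motion$n_frames)) {
      fr <- matrix(motion$background, H, W)
      for (tr in tracks) {
        fr <- fr + motion$spot_amplitude *
          exp(-((gx - tr$positions$x_px[k])^2 +
                  (gy - tr$positions$y_px[k])^2) / s2)
      }
      if (motion$noise_sigma > 0)
        fr <- pmax(fr + matrix(stats::rnorm(H * W, 0, motion$noise_sigma),
                               H, W), 0)
      a[, , k] <- fr
    }
    list(stack = image_stack(list(PMN = a), pixel_size_um = px,
                             frame_interval_s = motion$frame_interval_s),
         tracks = tracks)
  })
}

#' Write a phantom to disk
#'
#' Writes the image as a multi-page TIFF, the truth mask as a 0/255 TIFF and
#' the remaining ground truth as JSON.
#'
#' @param phantom result of [generate_network_phantom()]
#' @param dir output directory (created if missing)
#' @param name file stem
#' @return `dir`, invisibly
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- phantom$stack$channels[[1]]
  scale <- max(img)
  pages <- if (length(dim(img)) == 3)
    lapply(seq_len(dim(img)[3]), function(k) img[, , k] / scale)
  else list(img / scale)
  tiff::writeTIFF(pages, file.path(dir, paste0(name, ".tif")))
  tiff::writeTIFF(phantom$truth$mask * 1.0,
                  file.path(dir, paste0(name, "_mask.tif")))
  tr <- phantom$truth
  jsonlite::write_json(
    list(n_junctions = tr$n_junctions, n_endpoints = tr$n_endpoints,
         branch_lengths_px = tr$branch_lengths_px,
         branch_radii_px = tr$branch_radii_px,
         area_fraction = tr$area_fraction,
         pixel_size_um = tr$pixel_size_um,
         intensity_scale = scale),
    file.path(dir, paste0(name, "_truth.json")), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
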