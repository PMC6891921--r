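# Detection, linking and fate classification of leukocyte-like particles in
# time-lapse frames. Detection stands in for interactive spot tracking:
# thresholded connected components reported by intensity-weighted centroid,
# linked frame-to-frame by greedy mutual nearest neighbours. Fate is scored
# from the final frame against the vessel mask, mirroring endpoint scoring
# of fixed samples: in the extravascular space = extravasated, touching the
# vessel boundary = transmigrating, otherwise intravascular.

#' Construct a particle track
#'
#' @param t_s timestamps in seconds, strictly increasing
#' @param x_px,y_px centroid positions in pixels
#' @param track_id identifier
#' @param fate optional fate label
#' @return object of class `particle_track`
#' @export
particle_track <- function(t_s, x_px, y_px, track_id = NA_integer_,
                           fate = NA_character_) {
  stopifnot(length(t_s) == length(x_px), length(x_px) == length(y_px))
  if (length(t_s) > 1 && any(diff(t_s) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(
    positions = data.frame(t_s = t_s, x_px = x_px, y_px = y_px),
    track_id = track_id, fate = fate
  ), class = "particle_track")
}

#' @export
print.particle_track <- function(x, ...) {
  cat("<particle_track ", x$track_id, "> ", nrow(x$positions), " positions",
      if (!is.na(x$fate)) paste0(", fate: ", x$fate), "\n", sep = "")
  invisible(x)
}

#' Detect particles in one frame
#'
#' Connected components (8-connectivity) of pixels above
#' `intensity_threshold` with at least `min_spot_px` pixels, reported by
#' intensity-weighted centroid.
#'
#' @param frame 2D numeric matrix
#' @param intensity_threshold detection threshold (a.u.)
#' @param min_spot_px minimum component area in pixels
#' @return data frame with `x_px`, `y_px`, `area_px`, `total_intensity`
#'   (zero rows when nothing is detected)
#' @export
detect_particles <- function(frame, intensity_threshold, min_spot_px = 3) {
  stopifnot(is.matrix(frame))
  above <- frame > intensity_threshold
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), total_intensity = numeric(0))
  if (!any(above)) return(empty)
  lab <- label_components(above, 8)
  nlab <- max(lab)
  out <- empty
  nr <- nrow(frame)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    if (length(idx) < min_spot_px) next
    w <- frame[idx]
    ys <- (idx - 1L) %% nr + 1L
    xs <- (idx - 1L) %/% nr + 1L
    out <- rbind(out, data.frame(
      x_px = sum(xs * w) / sum(w), y_px = sum(ys * w) / sum(w),
      area_px = length(idx), total_intensity = sum(w)))
  }
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking: between consecutive frames,
#' candidate pairs closer than `max_disp_px` are linked in order of
#' increasing distance (ties broken by lowest detection index), each
#' detection used at most once. Unmatched detections start new tracks;
#' unmatched track heads terminate. Deterministic given the input.
#'
#' @param detections list with one detection data frame per frame (as from
#'   [detect_particles()])
#' @param max_disp_px maximum frame-to-frame displacement, px
#' @param frame_interval_s seconds between frames (for timestamps)
#' @return list of `particle_track`
#' @export
link_tracks <- function(detections, max_disp_px, frame_interval_s = 1) {
  stopifnot(is.list(detections), length(detections) >= 2)
  nT <- length(detections)
  # active tracks: list of list(rows = data.frame, last = c(x, y), open)
  tracks <- list()
  active <- integer(0)
  d0 <- detections[[1]]
  for (i in seq_len(nrow(d0))) {
    tracks[[length(tracks) + 1L]] <- data.frame(
      frame = 1L, t_s = 0, x_px = d0$x_px[i], y_px = d0$y_px[i])
    active <- c(active, length(tracks))
  }
  for (k in 2:nT) {
    dk <- detections[[k]]
    nA <- length(active); nD <- nrow(dk)
    assigned_tr <- rep(FALSE, nA); assigned_de <- rep(FALSE, nD)
    if (nA > 0 && nD > 0) {
      last <- t(vapply(active, function(ti) {
        r <- tracks[[ti]]
        c(r$x_px[nrow(r)], r$y_px[nrow(r)])
      }, numeric(2)))
      D <- sqrt(outer(last[, 1], dk$x_px, `-`)^2 +
                  outer(last[, 2], dk$y_px, `-`)^2)
      cand <- which(D <= max_disp_px, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(D[cand], cand[, 1], cand[, 2])
        for (ci in ord) {
          a <- cand[ci, 1]; b <- cand[ci, 2]
          if (assigned_tr[a] || assigned_de[b]) next
          assigned_tr[a] <- TRUE; assigned_de[b] <- TRUE
          ti <- active[a]
          tracks[[ti]] <- rbind(tracks[[ti]], data.frame(
            frame = k, t_s = (k - 1) * frame_interval_s,
            x_px = dk$x_px[b], y_px = dk$y_px[b]))
        }
      }
    }
    new_active <- active[assigned_tr]
    if (nD > 0) for (b in which(!assigned_de)) {
      tracks[[length(tracks) + 1L]] <- data.frame(
        frame = k, t_s = (k - 1) * frame_interval_s,
        x_px = dk$x_px[b], y_px = dk$y_px[b])
      new_active <- c(new_active, length(tracks))
    }
    active <- new_active
  }
  lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]
    tr <- particle_track(r$t_s, r$x_px, r$y_px, track_id = i)
    tr$positions$frame <- r$frame
    tr
  })
}

#' Mean speed of a track
#'
#' Sum of step displacements (micrometres) divided by the total elapsed time
#' (minutes).
#'
#' @param track a `particle_track`
#' @param pixel_size_um micrometres per pixel
#' @return speed in um/min; `NA` with attribute `flag = "single_position"`
#'   for one-point tracks
#' @export
mean_speed <- function(track, pixel_size_um = 1) {
  stopifnot(inherits(track, "particle_track"))
  p <- track$positions
  if (nrow(p) < 2)
    return(structure(NA_real_, flag = "single_position"))
  steps_um <- sqrt(diff(p$x_px)^2 + diff(p$y_px)^2) * pixel_size_um
  total_min <- (p$t_s[nrow(p)] - p$t_s[1]) / 60
  sum(steps_um) / total_min
}

#' Classify a track's fate against the vessel mask
#'
#' Scored from the final position only: strictly outside the mask and
#' farther than `contact_dist_px` from the boundary = `"extravasated"`;
#' within `contact_dist_px` of the boundary (either side) =
#' `"transmigrating"`; otherwise `"intravascular"`. Distance to the boundary
#' is the Euclidean distance transform to the nearest pixel of the opposite
#' phase, evaluated at the rounded final position.
#'
#' @param track a `particle_track`
#' @param vessel_mask `binary_mask` or logical matrix aligned to the frames
#' @param contact_dist_px contact distance, px (default 2)
#' @return fate label
#' @export
classify_track <- function(track, vessel_mask, contact_dist_px = 2) {
  stopifnot(inherits(track, "particle_track"))
  m <- if (inherits(vessel_mask, "binary_mask")) vessel_mask$data
       else vessel_mask
  p <- track$positions[nrow(track$positions), ]
  y <- round(p$y_px); x <- round(p$x_px)
  if (y < 1 || y > nrow(m) || x < 1 || x > ncol(m))
    stop("final track position lies outside the image bounds")
  bdist <- if (m[y, x]) edt_mask(m)[y, x] else edt_mask(!m)[y, x]
  if (bdist <= contact_dist_px) "transmigrating"
  else if (m[y, x]) "intravascular"
  else "extravasated"
}

#' Summarize a classified cohort of tracks
#'
#' @param tracks list of `particle_track` with fates assigned (see
#'   [classify_track()]); tracks with `NA` fate are rejected
#' @param pixel_size_um micrometres per pixel for speeds
#' @return object of class `extravasation_summary`: `n_tracks`,
#'   `pct_extravasated`, `pct_transmigrating`, `pct_intravascular`,
#'   `mean_speed_um_min`, `sem_speed_um_min`, `speeds_um_min`
#' @export
summarize_tracks <- function(tracks, pixel_size_um = 1) {
  stopifnot(length(tracks) >= 1)
  fates <- vapply(tracks, `[[`, character(1), "fate")
  if (any(is.na(fates))) stop("all tracks must be classified first")
  speeds <- vapply(tracks, mean_speed, numeric(1),
                   pixel_size_um = pixel_size_um)
  n <- length(tracks)
  sp <- speeds[!is.na(speeds)]
  structure(list(
    n_tracks = n,
    pct_extravasated = 100 * sum(fates == "extravasated") / n,
    pct_transmigrating = 100 * sum(fates == "transmigrating") / n,
    pct_intravascular = 100 * sum(fates == "intravascular") / n,
    mean_speed_um_min = mean(sp),
    sem_speed_um_min = if (length(sp) > 1) stats::sd(sp) / sqrt(length(sp))
                       else NA_real_,
    speeds_um_min = speeds
  ), class = "extravasation_summary")
}

#' @export
print.extravasation_summary <- function(x, ...) {
  cat("<extravasation_summary>", x$n_tracks, "tracks:",
      sprintf("%.1f%% extravasated, %.1f%% transmigrating,",
              x$pct_extravasated, x$pct_transmigrating),
      sprintf("mean speed %.2f um/min\n", x$mean_speed_um_min))
  invisible(x)
}

#' Track a PMN time-lapse end to end
#'
#' Detection, linking, speed and fate classification in one call.
#'
#' @param series H x W x T array or `image_stack` (channel `"PMN"`)
#' @param vessel_mask `binary_mask` or logical matrix
#' @param intensity_threshold,min_spot_px see [detect_particles()]
#' @param max_disp_px see [link_tracks()]
#' @param contact_dist_px see [classify_track()]
#' @param channel channel label for `image_stack` input
#' @return list of classified `particle_track`
#' @export
track_pmn_series <- function(series, vessel_mask, intensity_threshold,
                             min_spot_px = 3, max_disp_px = 15,
                             contact_dist_px = 2, channel = NULL) {
  a <- if (inherits(series, "image_stack")) get_channel(series, channel)
       else series
  dt <- if (inherits(series, "image_stack")) series$frame_interval_s else 1
  px <- if (inherits(series, "image_stack")) series$pixel_size_um else 1
  dets <- lapply(seq_len(dim(a)[3]), function(k)
    detect_particles(a[, , k], intensity_threshold, min_spot_px))
  tracks <- link_tracks(dets, max_disp_px, frame_interval_s = dt)
  lapply(tracks, function(tr) {
    tr$fate <- classify_track(tr, vessel_mask, contact_dist_px)
    tr$mean_speed_um_min <- mean_speed(tr, pixel_size_um = px)
    tr
  })
}
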