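# Apparent-permeability estimation from a dextran time-lapse. The vessel
# footprint at t = 0 partitions the field into intravascular and
# extravascular regions; with intensity linear in tracer concentration,
# negligible flux across the imaging boundary and constant transendothelial
# flux, the permeability (cm/s) follows from the rise of the mean
# extravascular intensity:
#
#   P = A_T * (I_Tf - I_T0) / (p_v * t * (I_V0 - I_T0))
#
# with p_v the vessel perimeter (cm) and A_T the extravascular tissue
# area (cm^2).

# Moore-neighbour boundary trace of a single connected component.
# Returns the chain length through boundary-pixel centres (1 per orthogonal
# step, sqrt(2) per diagonal step) over one full clockwise cycle.
trace_contour_length <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  idx0 <- which(comp)[1] # column-major: topmost pixel of first occupied column
  if (sum(comp) == 1) return(0)
  y0 <- (idx0 - 1L) %% nr + 1L
  x0 <- (idx0 - 1L) %/% nr + 1L
  fg <- function(y, x) y >= 1 && y <= nr && x >= 1 && x <= nc && comp[y, x]
  # NEIGH8 is clockwise from north; backtrack of the start is its west
  # neighbour (background by choice of start pixel)
  cy <- y0; cx <- x0; bdir <- 7L
  len <- 0
  state0 <- NA_real_
  repeat {
    found <- FALSE
    for (k in 1:8) {
      dir <- (bdir + k - 1L) %% 8L + 1L
      ny <- cy + NEIGH8[dir, "dy"]; nx <- cx + NEIGH8[dir, "dx"]
      if (fg(ny, nx)) {
        prev_dir <- (bdir + k - 2L) %% 8L + 1L
        len <- len + unname(step_length(NEIGH8[dir, "dy"], NEIGH8[dir, "dx"]))
        # backtrack direction seen from the new pixel: towards the last
        # background neighbour inspected
        by <- cy + NEIGH8[prev_dir, "dy"]; bx <- cx + NEIGH8[prev_dir, "dx"]
        cy <- ny; cx <- nx
        bdir <- which(NEIGH8[, "dy"] == (by - cy) & NEIGH8[, "dx"] == (bx - cx))
        found <- TRUE
        break
      }
    }
    if (!found) return(0) # isolated pixel (already handled) or degenerate
    state <- ((cx - 1) * nr + cy) * 8 + bdir
    if (is.na(state0)) {
      state0 <- state
      len0 <- len
    } else if (state == state0) {
      return(len - len0)
    }
    if (len > 8 * nr * nc) stop("contour tracing failed to close")
  }
}

#' Vessel perimeter of a binary mask, in pixels
#'
#' Boundary length by Moore-neighbour contour tracing with the geodesic step
#' metric (1 orthogonal, sqrt(2) diagonal). The traced contour runs through
#' boundary-pixel centres, i.e. half a pixel inside the true foreground
#' boundary; a closed convex curve offset outward by half a pixel gains
#' exactly pi pixels of length, so pi is added per contour. Outer contours
#' of every 8-connected component and the contours of enclosed holes are both
#' counted (both are vessel wall).
#'
#' @param mask a `binary_mask` or logical matrix
#' @return perimeter in pixel units
#' @export
perimeter_px <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  if (!any(m)) stop("empty mask: no perimeter")
  lab <- label_components(m, 8)
  total <- 0
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    total <- total + trace_contour_length(comp) + pi
  }
  # holes: background 4-components not touching the image border
  bg <- !m
  blab <- label_components(bg, 4)
  border_labels <- unique(c(blab[1, ], blab[nrow(blab), ],
                            blab[, 1], blab[, ncol(blab)]))
  hole_labels <- setdiff(seq_len(max(blab)), border_labels[border_labels > 0])
  for (l in hole_labels) {
    total <- total + trace_contour_length(blab == l) + pi
  }
  total
}

#' Partition a vessel mask into perimeter and tissue area
#'
#' From the binary vessel outline at t = 0: the vessel perimeter `p_v` in cm
#' and the extravascular tissue area `A_T` in cm^2.
#'
#' @param mask a `binary_mask` (pixel size is taken from it) or logical
#'   matrix with `pixel_size_um` supplied
#' @param pixel_size_um pixel size override in micrometres
#' @return list with `p_v_cm`, `A_T_cm2`, `perimeter_px`, `tissue_px`
#' @export
region_partition <- function(mask, pixel_size_um = NULL) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  px_um <- pixel_size_um %||%
    (if (inherits(mask, "binary_mask")) mask$pixel_size_um else 1)
  if (!any(m)) stop("empty mask: no vessel perimeter")
  if (all(m)) stop("full mask: no extravascular tissue")
  px_cm <- px_um * 1e-4
  per <- perimeter_px(m)
  list(p_v_cm = per * px_cm,
       A_T_cm2 = sum(!m) * px_cm^2,
       perimeter_px = per,
       tissue_px = sum(!m))
}

#' Mean intravascular and extravascular intensities of a time-lapse
#'
#' @param series H x W x T numeric array (or `image_stack` with a single
#'   time-lapse channel)
#' @param mask vessel `binary_mask` (or logical matrix) aligned to the frames
#' @param channel channel label when `series` is an `image_stack`
#' @return list with `I_V0` (foreground mean, frame 1), `I_T0` (background
#'   mean, frame 1), `I_Tf` (background mean per frame), `I_V` (foreground
#'   mean per frame)
#' @export
mean_intensities <- function(series, mask, channel = NULL) {
  a <- if (inherits(series, "image_stack")) get_channel(series, channel)
       else series
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  if (length(dim(a)) != 3 || dim(a)[3] < 2)
    stop("series must contain at least 2 frames")
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  if (!identical(dim(m), dim(a)[1:2]))
    stop("mask shape does not match frame shape")
  tt <- dim(a)[3]
  I_V <- vapply(seq_len(tt), function(k) mean(a[, , k][m]), numeric(1))
  I_T <- vapply(seq_len(tt), function(k) mean(a[, , k][!m]), numeric(1))
  list(I_V0 = I_V[1], I_T0 = I_T[1], I_Tf = I_T, I_V = I_V)
}

#' Bundle the permeability-formula inputs
#'
#' @param A_T extravascular tissue area, cm^2
#' @param p_v vessel perimeter, cm
#' @param t elapsed time, s
#' @param I_V0 mean intravascular intensity at t = 0
#' @param I_T0 mean extravascular intensity at t = 0
#' @param I_Tf mean extravascular intensity at time t
#' @return object of class `permeability_input`
#' @export
permeability_input <- function(A_T, p_v, t, I_V0, I_T0, I_Tf) {
  if (A_T <= 0) stop("A_T must be > 0")
  if (p_v <= 0) stop("p_v must be > 0")
  if (t <= 0) stop("t must be > 0")
  if (I_V0 <= I_T0)
    stop("undefined contrast: I_V0 must exceed I_T0")
  structure(list(A_T = A_T, p_v = p_v, t = t, I_V0 = I_V0, I_T0 = I_T0,
                 I_Tf = I_Tf), class = "permeability_input")
}

#' Apparent permeability from a single time interval
#'
#' `P = A_T * (I_Tf - I_T0) / (p_v * t * (I_V0 - I_T0))`, in cm/s for inputs
#' in cm, cm^2 and s. The sign of P follows the sign of the extravascular
#' intensity change.
#'
#' @param input a `permeability_input` (or the same six values as arguments
#'   via `...` passed to [permeability_input()])
#' @param ... alternative to `input`: named formula inputs
#' @return object of class `permeability_result`: `P_cm_per_s`, `inputs`
#' @export
permeability <- function(input = NULL, ...) {
  if (is.null(input)) input <- permeability_input(...)
  stopifnot(inherits(input, "permeability_input"))
  P <- input$A_T * (input$I_Tf - input$I_T0) /
    (input$p_v * input$t * (input$I_V0 - input$I_T0))
  structure(list(P_cm_per_s = P, inputs = input, per_interval = NULL,
                 flags = character(0)),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat("<permeability_result> P =", format(x$P_cm_per_s, digits = 4), "cm/s")
  if (!is.null(x$per_interval))
    cat(" (mean of", nrow(x$per_interval), "intervals)")
  if (length(x$flags)) cat(" [flags:", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

#' Apparent permeability from a multi-frame time-lapse
#'
#' Computes a per-interval permeability estimate from frame 1 (t = 0) to
#' every later frame and reports their mean. The vessel mask is taken at
#' t = 0. Two assumption monitors are attached as flags:
#' `"decreasing_extravascular"` when the extravascular intensity falls below
#' its t = 0 value by more than `noise_floor`, and `"boundary_flux"` when
#' the mean intravascular intensity drifts more than 5% from its t = 0
#' value (the constant-reservoir / negligible-boundary-flux assumption).
#'
#' @param series H x W x T array or `image_stack` time-lapse
#' @param mask vessel `binary_mask` at t = 0
#' @param frame_interval_s seconds between frames (taken from the stack when
#'   available)
#' @param frame_times_s optional explicit times per frame (overrides the
#'   interval); frame 1 must be 0
#' @param pixel_size_um pixel size override
#' @param noise_floor intensity tolerance for the decrease monitor
#' @param channel channel label for `image_stack` input
#' @return a `permeability_result` with `per_interval` data frame
#' @export
permeability_series <- function(series, mask, frame_interval_s = NULL,
                                frame_times_s = NULL, pixel_size_um = NULL,
                                noise_floor = 0, channel = NULL) {
  a <- if (inherits(series, "image_stack")) get_channel(series, channel)
       else series
  tt <- dim(a)[3]
  if (is.null(frame_times_s)) {
    dt <- frame_interval_s %||%
      (if (inherits(series, "image_stack")) series$frame_interval_s else NULL)
    if (is.null(dt) || is.na(dt)) stop("frame interval or times required")
    frame_times_s <- (seq_len(tt) - 1) * dt
  }
  stopifnot(length(frame_times_s) == tt, frame_times_s[1] == 0)
  geom <- region_partition(mask, pixel_size_um)
  ints <- mean_intensities(a, mask)
  flags <- character(0)
  if (any(ints$I_Tf - ints$I_T0 < -noise_floor))
    flags <- c(flags, "decreasing_extravascular")
  if (any(abs(ints$I_V - ints$I_V0) > 0.05 * ints$I_V0))
    flags <- c(flags, "boundary_flux")
  per <- data.frame(
    frame = 2:tt,
    t_s = frame_times_s[-1],
    I_Tf = ints$I_Tf[-1],
    P_cm_per_s = vapply(2:tt, function(k) {
      permeability(permeability_input(
        A_T = geom$A_T_cm2, p_v = geom$p_v_cm, t = frame_times_s[k],
        I_V0 = ints$I_V0, I_T0 = ints$I_T0, I_Tf = ints$I_Tf[k]))$P_cm_per_s
    }, numeric(1))
  )
  structure(list(
    P_cm_per_s = mean(per$P_cm_per_s),
    inputs = list(A_T = geom$A_T_cm2, p_v = geom$p_v_cm,
                  I_V0 = ints$I_V0, I_T0 = ints$I_T0,
                  frame_times_s = frame_times_s),
    per_interval = per,
    flags = flags
  ), class = "permeability_result")
}
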