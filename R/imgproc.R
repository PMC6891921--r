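# Preprocessing chain used to turn a confocal z-stack into a binary vessel
# mask. The pipeline order is fixed: maximum projection -> outlier removal
# -> Gaussian smoothing -> binarization, and every step is recorded in the
# mask's provenance.

#' Construct an image stack
#'
#' A light container for multi-channel microscopy data. Each channel holds a
#' numeric array: H x W (single plane), or H x W x K where the third axis is
#' either z (a confocal stack) or time (a time-lapse series).
#'
#' @param channels named list of numeric arrays, one per channel; all
#'   nonnegative
#' @param pixel_size_um lateral pixel size in micrometres per pixel
#' @param z_step_um z spacing in micrometres (confocal stacks)
#' @param frame_interval_s frame spacing in seconds (time-lapse series)
#' @return an object of class `image_stack`
#' @export
image_stack <- function(channels, pixel_size_um = 1, z_step_um = NA_real_,
                        frame_interval_s = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1)
  nms <- names(channels)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == ""))
    stop("channels must be uniquely named")
  for (nm in nms) {
    if (any(channels[[nm]] < 0)) stop("negative intensities in channel ", nm)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, frame_interval_s = frame_interval_s),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  dims <- vapply(x$channels, function(ch) paste(dim(ch) %||% length(ch),
                                                collapse = "x"), character(1))
  cat("<image_stack> ", length(x$channels), " channel(s): ",
      paste0(names(x$channels), " [", dims, "]", collapse = ", "),
      "; pixel ", x$pixel_size_um, " um\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_channel <- function(stack, channel) {
  if (inherits(stack, "image_stack")) {
    if (!channel %in% names(stack$channels))
      stop("unknown channel label: ", channel)
    stack$channels[[channel]]
  } else {
    stack
  }
}

#' Maximum-intensity projection over z
#'
#' Collapses a confocal stack to 2D by taking the per-pixel maximum over
#' slices. A single-plane input is returned unchanged.
#'
#' @param stack an `image_stack` or a numeric array (H x W or H x W x Z)
#' @param channel channel label, required when `stack` is an `image_stack`
#' @return numeric H x W matrix
#' @export
max_project <- function(stack, channel = NULL) {
  a <- if (inherits(stack, "image_stack")) get_channel(stack, channel) else stack
  d <- dim(a)
  if (length(d) == 2) return(a)
  if (length(d) != 3) stop("expected a 2D image or 3D stack")
  out <- a[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, a[, , k])
  out
}

# Offsets of a disc of given radius (pixel centres within `radius`).
disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

#' Conditional median filtering of outlier pixels
#'
#' Mirrors the ImageJ "Remove Outliers" despeckle: each pixel is compared
#' with the median of its disc neighbourhood (radius `radius_px`, centre
#' included) and replaced by that median only when it deviates by more than
#' `deviation_threshold`; all other pixels pass through untouched. Borders
#' are handled by reflection.
#'
#' @param img numeric matrix
#' @param radius_px neighbourhood radius in pixels (default 2)
#' @param deviation_threshold replacement threshold on the image's native
#'   intensity scale (default 50)
#' @return filtered matrix, same dimensions
#' @export
remove_outliers <- function(img, radius_px = 2, deviation_threshold = 50) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  off <- disc_offsets(radius_px)
  k <- floor(radius_px)
  p <- pad_reflect(img, k)
  nr <- nrow(img); nc <- ncol(img)
  stackarr <- array(NA_real_, c(nr, nc, nrow(off)))
  for (i in seq_len(nrow(off))) {
    stackarr[, , i] <- p[k + seq_len(nr) + off$dy[i], k + seq_len(nc) + off$dx[i]]
  }
  med <- apply(stackarr, c(1, 2), stats::median)
  out <- img
  repl <- abs(img - med) > deviation_threshold
  out[repl] <- med[repl]
  out
}

gaussian_kernel_1d <- function(sigma) {
  h <- ceiling(4 * sigma)
  x <- -h:h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized, separable Gaussian kernel truncated at
#' 4 sigma, using reflective boundary handling so border intensities are not
#' darkened.
#'
#' @param img numeric matrix
#' @param sigma_px Gaussian standard deviation in pixels (default 2)
#' @return smoothed matrix
#' @export
gaussian_smooth <- function(img, sigma_px = 2) {
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  k <- gaussian_kernel_1d(sigma_px)
  h <- (length(k) - 1L) / 2L
  p <- pad_reflect(img, h)
  nr <- nrow(img); nc <- ncol(img)
  # rows pass (convolve along y)
  tmp <- matrix(0, nr, ncol(p))
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

#' Construct a binary mask
#'
#' @param data logical matrix
#' @param pixel_size_um pixel size in micrometres
#' @param provenance list recording how the mask was produced
#' @return object of class `binary_mask`
#' @export
binary_mask <- function(data, pixel_size_um = 1, provenance = list()) {
  stopifnot(is.logical(data), is.matrix(data))
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x$data), "x", ncol(x$data), ", ",
      sprintf("%.1f%% foreground", 100 * mean(x$data)),
      ", pixel ", x$pixel_size_um, " um\n", sep = "")
  invisible(x)
}

#' Binarize an image
#'
#' Thresholds an intensity image into a vessel mask. `method = "otsu"`
#' chooses the threshold by Otsu's criterion on a 256-bin histogram over the
#' image's native range; `method = "fixed"` uses the supplied `threshold`.
#' Foreground is strictly above the threshold. The realized threshold and
#' method are recorded in the mask provenance.
#'
#' @param img numeric matrix
#' @param method `"otsu"` or `"fixed"`
#' @param threshold numeric, required for `method = "fixed"`
#' @param pixel_size_um pixel size carried onto the mask
#' @return a `binary_mask`
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     pixel_size_um = 1) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0)
      stop("constant image: Otsu threshold undefined; use method = 'fixed'")
    thr <- EBImage::otsu(img, range = rng, levels = 256)
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    thr <- threshold
  }
  binary_mask(img > thr, pixel_size_um = pixel_size_um,
              provenance = list(step = "binarize", method = method,
                                threshold = as.numeric(thr)))
}

#' Segment vessels from a confocal stack
#'
#' The full preprocessing chain in its fixed order: maximum projection,
#' conditional-median outlier removal, Gaussian smoothing, binarization.
#' Parameters of every step are recorded in the returned mask's provenance.
#'
#' @param stack `image_stack` (or plain array)
#' @param channel channel to segment
#' @param outlier_radius_px,outlier_threshold see [remove_outliers()]
#' @param sigma_px see [gaussian_smooth()]
#' @param method,threshold see [binarize()]
#' @return a `binary_mask`
#' @export
segment_vessels <- function(stack, channel = NULL, outlier_radius_px = 2,
                            outlier_threshold = 50, sigma_px = 2,
                            method = "otsu", threshold = NULL) {
  px <- if (inherits(stack, "image_stack")) stack$pixel_size_um else 1
  img <- max_project(stack, channel)
  img <- remove_outliers(img, outlier_radius_px, outlier_threshold)
  img <- gaussian_smooth(img, sigma_px)
  m <- binarize(img, method = method, threshold = threshold,
                pixel_size_um = px)
  m$provenance <- list(
    pipeline = c("max_project", "remove_outliers", "gaussian_smooth",
                 "binarize"),
    channel = channel %||% NA_character_,
    outlier_radius_px = outlier_radius_px,
    outlier_threshold = outlier_threshold,
    sigma_px = sigma_px,
    method = m$provenance$method,
    threshold = m$provenance$threshold
  )
  m
}

#' Read a (multi-page) TIFF as an array
#'
#' @param path TIFF file
#' @return H x W matrix or H x W x K array (pages stacked on the third axis)
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a binary mask as a 0/255 TIFF with a JSON provenance sidecar
#'
#' @param mask a `binary_mask`
#' @param path output TIFF path; provenance goes to `<path>.json`
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(mask$data * 1.0, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(pixel_size_um = mask$pixel_size_um, provenance = mask$provenance),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
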