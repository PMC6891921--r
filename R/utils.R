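# Internal helpers shared across modules: padding, shifting, connected
# component labelling. Images are plain numeric matrices indexed [row, col]
# = [y, x]; positions in tracking are (x = col, y = row).

#' Reflect-pad a matrix
#'
#' Pads `m` by `k` pixels on every side, mirroring the image across its
#' borders (the border pixel itself is not duplicated).
#' @param m numeric matrix
#' @param k pad width in pixels
#' @return padded matrix of size (nrow + 2k) x (ncol + 2k)
#' @keywords internal
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(k < nr, k < nc)
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dy, dx), filling vacated cells with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr); xs <- seq_len(nc)
  ysrc <- ys - dy; xsrc <- xs - dx
  keep_y <- ysrc >= 1 & ysrc <= nr
  keep_x <- xsrc >= 1 & xsrc <= nc
  out[ys[keep_y], xs[keep_x]] <- m[ysrc[keep_y], xsrc[keep_x]]
  out
}

# 8-neighbourhood offsets (dy, dx), clockwise from north.
NEIGH8 <- cbind(
  dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)

#' Label connected components of a binary mask
#'
#' 4-connected labelling is delegated to [EBImage::bwlabel()]; for
#' 8-connectivity, 4-connected labels touching diagonally are merged with a
#' union-find pass.
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of labels, 0 = background
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nlab <- max(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # diagonal adjacencies between distinct 4-labels
  for (d in list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
    sh <- shift_mat(lab, d[1], d[2], fill = 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], sh[sel]))
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Run an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so generators do not disturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Step length between two 8-adjacent pixels: 1 orthogonal, sqrt(2) diagonal.
step_length <- function(dy, dx) ifelse(dy != 0 & dx != 0, sqrt(2), 1)
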