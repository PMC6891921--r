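# Topology-preserving thinning of a vessel mask to 1-pixel centerlines and
# extraction of the skeleton graph (junctions, endpoints, branches with
# geodesic lengths). Conventions follow the common ImageJ skeleton analysis:
# 8-connectivity throughout; an endpoint has exactly one skeleton neighbour,
# a junction pixel has three or more; adjacent junction pixels are merged
# into one junction node.

# Ring-cell adjacency for the simple-point test. Ring positions follow
# NEIGH8 (clockwise from north); two cells are 8-adjacent (or 4-adjacent)
# according to their true geometric offsets.
.ring_cache <- new.env(parent = emptyenv())
ring_adj <- function() {
  if (is.null(.ring_cache$adj)) {
    a8 <- matrix(FALSE, 8, 8); a4 <- matrix(FALSE, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      dy <- abs(NEIGH8[i, "dy"] - NEIGH8[j, "dy"])
      dx <- abs(NEIGH8[i, "dx"] - NEIGH8[j, "dx"])
      if (i != j && max(dy, dx) <= 1) a8[i, j] <- TRUE
      if (i != j && dy + dx == 1) a4[i, j] <- TRUE
    }
    .ring_cache$adj <- list(a8 = a8, a4 = a4)
  }
  .ring_cache$adj
}

ring_components <- function(on, adj) {
  comp <- integer(8); nid <- 0L
  for (i in which(on)) {
    if (comp[i] > 0L) next
    nid <- nid + 1L
    queue <- i
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      if (comp[c0] > 0L) next
      comp[c0] <- nid
      queue <- c(queue, which(on & adj[c0, ] & comp == 0L))
    }
  }
  list(comp = comp, n = nid)
}

# Simplicity lookup table over the 256 neighbourhood configurations. A
# foreground pixel is simple (its removal preserves digital topology with
# 8-connected foreground / 4-connected background) iff its foreground ring
# neighbours form exactly one 8-connected component and its background ring
# neighbours form exactly one 4-connected component containing an edge cell
# (ring positions 1, 3, 5, 7 = N, E, S, W).
simple_point_lut <- function() {
  if (is.null(.ring_cache$lut)) {
    lut <- logical(256)
    for (code in 0:255) {
      v <- as.logical(bitwAnd(code, 2^(0:7)))
      if (!any(v)) next
      if (ring_components(v, ring_adj()$a8)$n != 1L) next
      bgc <- ring_components(!v, ring_adj()$a4)
      edge_comps <- unique(bgc$comp[c(1, 3, 5, 7)][!v[c(1, 3, 5, 7)]])
      lut[code + 1L] <- length(edge_comps) == 1L
    }
    .ring_cache$lut <- lut
  }
  .ring_cache$lut
}

#' Thin a binary mask to a 1-pixel skeleton
#'
#' Sequential simple-point thinning with four directional sub-cycles per
#' iteration (north, south, east, west borders in turn). The candidate set
#' of each sub-cycle is frozen before deletion starts — only pixels whose
#' neighbour in the sub-cycle direction is already background can be removed
#' in that sub-cycle — which peels the object one boundary layer per side and
#' keeps the centerline centred. Deletions are sequential with a simplicity
#' recheck, so a pixel is removed only when it is a simple point at that
#' moment (connected components and holes are preserved) and not a line
#' endpoint (tips are not eroded). The result is a minimal 8-connected
#' centerline: no remaining pixel with two or more neighbours is removable,
#' so staircase redundancy cannot occur.
#'
#' @param mask logical matrix (or `binary_mask`)
#' @return logical matrix of skeleton pixels
#' @export
thin_mask <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  stopifnot(is.logical(m))
  if (!any(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  lut <- simple_point_lut()
  pow <- 2^(0:7)
  dys <- NEIGH8[, "dy"]; dxs <- NEIGH8[, "dx"]
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, -1L)) # N, S, E, W
  repeat {
    changed <- FALSE
    for (d in dirs) {
      border <- m & shift_mat(!m, -d[1], -d[2], fill = TRUE)
      cand <- which(border)
      if (!length(cand)) next
      for (i in cand) {
        y <- (i - 1L) %% nr + 1L; x <- (i - 1L) %/% nr + 1L
        ys <- y + dys; xs <- x + dxs
        inb <- ys >= 1L & ys <= nr & xs >= 1L & xs <= nc
        v <- rep(FALSE, 8)
        v[inb] <- m[cbind(ys[inb], xs[inb])]
        if (sum(v) <= 1L) next # endpoint (or isolated): preserve
        if (lut[sum(pow[v]) + 1L]) {
          m[y, x] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m
}

# Neighbour-count matrix of a skeleton (number of 8-neighbours per pixel).
skel_degree <- function(skel) {
  deg <- matrix(0L, nrow(skel), ncol(skel))
  for (i in 1:8)
    deg <- deg + shift_mat(skel, -NEIGH8[i, "dy"], -NEIGH8[i, "dx"],
                           fill = FALSE)
  deg[!skel] <- 0L
  deg
}

# Chain-code length of a pixel path: 1 per orthogonal step, sqrt(2) per
# diagonal step. Overestimates Euclidean length of oblique straight lines by
# up to ~8%, so it is kept only as an auxiliary measure.
chain_path_length <- function(path) {
  if (nrow(path) < 2) return(0)
  dy <- diff(path[, 1]); dx <- diff(path[, 2])
  sum(step_length(dy, dx))
}

# Anchored polyline length: Euclidean distance summed between every
# `spacing`-th path pixel (plus the last). Anchors of a digital straight
# line lie within half a pixel of the true line, so straight and gently
# curved branches are measured without the chain-code length bias; the
# axis-aligned and 45-degree cases remain exact.
anchored_path_length <- function(path, spacing = 5) {
  n <- nrow(path)
  if (n < 2) return(0)
  idx <- unique(c(seq(1L, n, by = spacing), n))
  dy <- diff(path[idx, 1]); dx <- diff(path[idx, 2])
  sum(sqrt(dy^2 + dx^2))
}

# Extract nodes and branches from a thinned skeleton. Returns the raw graph;
# no pruning. Coordinates are (y, x) matrix indices.
extract_skeleton_graph <- function(skel, pixel_size_um = 1) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- skel_degree(skel)
  endpoint <- skel & deg == 1L
  junction <- skel & deg >= 3L

  # junction pixels clustered into junction nodes
  jlab <- if (any(junction)) label_components(junction, 8) else
    matrix(0L, nr, nc)
  n_junctions <- max(jlab)

  # node id per pixel: junction clusters 1..J, endpoints J+1, J+2, ...
  node_id <- jlab
  ep_idx <- which(endpoint)
  node_id[ep_idx] <- n_junctions + seq_along(ep_idx)
  n_endpoints <- length(ep_idx)

  idx_yx <- function(i) c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
  neighbours_of <- function(y, x) {
    ys <- y + NEIGH8[, "dy"]; xs <- x + NEIGH8[, "dx"]
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    ys <- ys[ok]; xs <- xs[ok]
    on <- skel[cbind(ys, xs)]
    cbind(y = ys[on], x = xs[on])
  }

  visited_slab <- matrix(FALSE, nr, nc)
  branches <- list()
  node_pairs_seen <- character(0)

  add_branch <- function(path, na, nb) {
    len_px <- anchored_path_length(path)
    branches[[length(branches) + 1L]] <<- list(
      path = path, nodes = c(na, nb),
      length_px = len_px, length_um = len_px * pixel_size_um,
      length_px_steps = chain_path_length(path))
  }

  node_pixels <- which(node_id > 0L)
  for (i in node_pixels) {
    yx <- idx_yx(i)
    nb <- neighbours_of(yx[1], yx[2])
    if (nrow(nb) == 0) next
    for (r in seq_len(nrow(nb))) {
      y2 <- nb[r, 1]; x2 <- nb[r, 2]
      nid2 <- node_id[y2, x2]
      if (nid2 > 0L) {
        # direct node-node adjacency; skip intra-cluster, dedupe pairs
        if (nid2 == node_id[i] && jlab[i] > 0L) next
        key <- paste(sort(c(i, (x2 - 1L) * nr + y2)), collapse = "-")
        if (key %in% node_pairs_seen) next
        node_pairs_seen <- c(node_pairs_seen, key)
        add_branch(rbind(yx, c(y2, x2)), node_id[i], nid2)
      } else {
        if (visited_slab[y2, x2]) next
        # walk slab pixels until the next node pixel
        path <- rbind(yx, c(y2, x2))
        prev <- yx; cur <- c(y2, x2)
        repeat {
          visited_slab[cur[1], cur[2]] <- TRUE
          nn <- neighbours_of(cur[1], cur[2])
          nxt <- nn[!(nn[, 1] == prev[1] & nn[, 2] == prev[2]), , drop = FALSE]
          if (nrow(nxt) == 0) { # dead end without endpoint flag (degenerate)
            add_branch(path, node_id[i], NA_integer_)
            break
          }
          # prefer a node pixel if several candidates (can happen next to a
          # junction cluster)
          nid_nxt <- node_id[cbind(nxt[, 1], nxt[, 2])]
          pick <- if (any(nid_nxt > 0L)) which(nid_nxt > 0L)[1] else 1L
          nxt <- nxt[pick, ]
          path <- rbind(path, nxt)
          if (node_id[nxt[1], nxt[2]] > 0L) {
            add_branch(path, node_id[i], node_id[nxt[1], nxt[2]])
            break
          }
          prev <- cur; cur <- nxt
        }
      }
    }
  }

  # pure cycles: slab pixels never visited and not adjacent to any node
  remaining <- skel & deg == 2L & !visited_slab
  if (any(remaining)) {
    rem_idx <- which(remaining)
    for (i in rem_idx) {
      if (!remaining[i]) next
      yx <- idx_yx(i)
      start <- yx
      nb <- neighbours_of(yx[1], yx[2])
      if (nrow(nb) == 0) { remaining[i] <- FALSE; next }
      path <- rbind(yx)
      prev <- yx; cur <- nb[1, ]
      repeat {
        path <- rbind(path, cur)
        remaining[path[nrow(path), 1], path[nrow(path), 2]] <- FALSE
        remaining[start[1], start[2]] <- FALSE
        if (cur[1] == start[1] && cur[2] == start[2]) break
        nn <- neighbours_of(cur[1], cur[2])
        nxt <- nn[!(nn[, 1] == prev[1] & nn[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nxt) == 0) break
        prev <- cur; cur <- nxt[1, ]
      }
      len_px <- anchored_path_length(path)
      branches[[length(branches) + 1L]] <- list(
        path = path, nodes = c(NA_integer_, NA_integer_),
        length_px = len_px, length_um = len_px * pixel_size_um,
        length_px_steps = chain_path_length(path), cycle = TRUE)
    }
  }

  list(skel = skel, deg = deg, node_id = node_id, jlab = jlab,
       n_junctions = n_junctions, n_endpoints = n_endpoints,
       endpoint_idx = ep_idx, branches = branches)
}

# Junction-geometry refinement. Thinning displaces a junction point into the
# widest part of the tube union (typically by about one tube radius), which
# systematically lengthens child branches and shortens the parent. Each
# junction is relocated to the least-squares intersection of the tangent
# lines of its incident branches, fitted just outside the junction zone, and
# incident branch lengths are re-measured to the relocated point.
refine_junction_lengths <- function(g, mask, pixel_size_um = 1) {
  if (g$n_junctions == 0 || length(g$branches) == 0 || !any(!mask)) return(g)
  edt <- edt_mask(mask)
  jrad <- vapply(seq_len(g$n_junctions), function(j)
    max(edt[g$jlab == j]), numeric(1))
  nb <- length(g$branches)
  cutinfo <- vector("list", nb)
  for (bi in seq_len(nb)) {
    b <- g$branches[[bi]]
    n <- nrow(b$path)
    info <- list(NULL, NULL)
    for (e in 1:2) {
      id <- b$nodes[e]
      if (is.na(id) || id > g$n_junctions) next
      p <- if (e == 1) b$path else b$path[n:1, , drop = FALSE]
      cum <- c(0, cumsum(step_length(diff(p[, 1]), diff(p[, 2]))))
      cap <- max(2L, floor(n * 0.4))
      ci <- which(cum >= 1.5 * jrad[id])[1]
      if (is.na(ci)) ci <- cap
      ci <- min(ci, cap)
      seg <- p[ci:min(n, ci + 7L), , drop = FALSE]
      if (nrow(seg) < 2) next
      u <- seg[nrow(seg), ] - seg[1, ]
      if (nrow(seg) >= 3) {
        pc <- stats::prcomp(seg)$rotation[, 1]
        if (sum(pc * u) < 0) pc <- -pc
        u <- pc
      }
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      info[[e]] <- list(cut = ci, a = p[ci, ], u = u / nu)
    }
    cutinfo[[bi]] <- info
  }
  # least-squares point closest to all incident tangent lines
  jloc <- matrix(NA_real_, g$n_junctions, 2)
  for (j in seq_len(g$n_junctions)) {
    A <- matrix(0, 2, 2); rhs <- c(0, 0); cnt <- 0L
    for (bi in seq_len(nb)) {
      for (e in 1:2) {
        id <- g$branches[[bi]]$nodes[e]
        if (is.na(id) || id != j) next
        inf <- cutinfo[[bi]][[e]]
        if (is.null(inf)) next
        P <- diag(2) - inf$u %o% inf$u
        A <- A + P; rhs <- rhs + as.numeric(P %*% inf$a)
        cnt <- cnt + 1L
      }
    }
    if (cnt >= 2 && abs(det(A)) > 1e-8) {
      q <- solve(A, rhs)
      cyx <- colMeans(which(g$jlab == j, arr.ind = TRUE))
      # reject implausible relocations far outside the junction zone
      if (sqrt(sum((q - cyx)^2)) <= 2 * jrad[j]) jloc[j, ] <- q
    }
  }
  for (bi in seq_len(nb)) {
    b <- g$branches[[bi]]
    n <- nrow(b$path)
    s1 <- 1L; s2 <- n; ext <- 0
    for (e in 1:2) {
      id <- b$nodes[e]
      inf <- cutinfo[[bi]][[e]]
      if (is.na(id) || id > g$n_junctions || is.null(inf) ||
          any(is.na(jloc[id, ]))) next
      if (e == 1) s1 <- inf$cut else s2 <- n - inf$cut + 1L
      ext <- ext + sqrt(sum((jloc[id, ] - inf$a)^2))
    }
    if (s1 > s2) { s1 <- s2 <- (s1 + s2) %/% 2L }
    len_px <- ext + anchored_path_length(b$path[s1:s2, , drop = FALSE])
    g$branches[[bi]]$length_px <- len_px
    g$branches[[bi]]$length_um <- len_px * pixel_size_um
  }
  g$junction_refined_yx <- jloc
  g
}

# Cap-end correction. Thinning retracts the centerline of a rounded tube end
# by a few pixels. The true centerline terminus lies one local radius short
# of the mask boundary along the outward tangent, so each endpoint branch is
# extended (or trimmed) by (distance to boundary along the tangent - local
# radius). Skipped for thin (radius < 2 px) structures, whose endpoints are
# already exact.
extend_cap_ends <- function(g, mask, pixel_size_um = 1) {
  if (length(g$branches) == 0 || !any(!mask)) return(g)
  edt <- edt_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  ray_to_boundary <- function(p0, u, maxd) {
    d <- 0
    while (d < maxd) {
      d <- d + 0.25
      y <- round(p0[1] + d * u[1]); x <- round(p0[2] + d * u[2])
      if (y < 1 || y > nr || x < 1 || x > nc || !mask[y, x]) return(d)
    }
    maxd
  }
  for (bi in seq_along(g$branches)) {
    b <- g$branches[[bi]]
    n <- nrow(b$path)
    if (n < 3) next
    ext <- 0
    for (e in 1:2) {
      id <- b$nodes[e]
      if (is.na(id) || id <= g$n_junctions) next # endpoint nodes only
      p <- if (e == 1) b$path else b$path[n:1, , drop = FALSE]
      # tube radius from the widest point near the end: the tip itself may
      # sit close to the cap boundary where the EDT underestimates it
      k <- seq_len(min(n, 10L))
      r_ref <- max(edt[cbind(p[k, 1], p[k, 2])])
      if (r_ref < 2) next
      u <- p[1, ] - p[min(n, 6L), ]
      nu <- sqrt(sum(u^2))
      if (nu == 0) next
      u <- u / nu
      d <- ray_to_boundary(p[1, ], u, 5 * r_ref)
      ext <- ext + max(-r_ref, min(d - r_ref, 3 * r_ref))
    }
    if (ext != 0) {
      g$branches[[bi]]$length_px <- b$length_px + ext
      g$branches[[bi]]$length_um <- (b$length_px + ext) * pixel_size_um
    }
  }
  g
}

#' Skeletonize a vessel mask and extract its branch graph
#'
#' Thins the mask to a 1-pixel centerline, classifies skeleton pixels by
#' their 8-neighbour count (1 = endpoint, >= 3 = junction; adjacent junction
#' pixels merge into one junction node), and walks branches between nodes.
#'
#' Branch length (`length_px`, `length_um`) is the anchored polyline length:
#' Euclidean distance summed between every 5th path pixel. This preserves the
#' exact values of axis-aligned and diagonal lines while avoiding the
#' chain-code bias (up to +8% on oblique straight lines) of the plain
#' 1/sqrt(2) step metric; the step-metric value is kept in each branch's
#' `length_px_steps`. Junction positions are additionally refined to the
#' least-squares intersection of incident branch tangents before measuring,
#' because thinning displaces junction pixels into the tube union by about
#' one radius, inflating child-branch lengths.
#'
#' Two cleaning steps guard against thinning artifacts: connected skeleton
#' components smaller than `min_branch_px` pixels are discarded, and terminal
#' spurs shorter than `min_branch_px` attached to a junction are pruned
#' before the final node classification.
#'
#' @param mask a `binary_mask` or logical matrix
#' @param pixel_size_um pixel size (taken from the mask when available)
#' @param min_branch_px spur-pruning length threshold in pixels (default 5;
#'   0 disables pruning)
#' @return an object of class `skeleton_graph` with elements `skeleton`
#'   (logical matrix), `branches` (list with `path`, `length_px`,
#'   `length_um`), `n_junctions`, `n_endpoints`, `junction_yx`,
#'   `endpoint_yx`, `pixel_size_um`
#' @export
skeletonize <- function(mask, pixel_size_um = NULL, min_branch_px = 5) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  px <- pixel_size_um %||%
    (if (inherits(mask, "binary_mask")) mask$pixel_size_um else 1)
  stopifnot(is.logical(m), is.matrix(m))
  empty <- function() structure(
    list(skeleton = matrix(FALSE, nrow(m), ncol(m)), branches = list(),
         n_junctions = 0L, n_endpoints = 0L,
         junction_yx = matrix(numeric(0), 0, 2),
         endpoint_yx = matrix(integer(0), 0, 2),
         pixel_size_um = px),
    class = "skeleton_graph")
  if (!any(m)) return(empty())

  skel <- thin_mask(m)
  # drop dust: components smaller than min_branch_px pixels
  if (min_branch_px > 0) {
    lab <- label_components(skel, 8)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_branch_px)
    if (length(small)) skel[lab %in% small] <- FALSE
  }
  if (!any(skel)) return(empty())

  g <- extract_skeleton_graph(skel, px)

  # prune short terminal spurs hanging off junctions, then re-extract
  if (min_branch_px > 0) {
    for (pass in 1:5) {
      is_ep_node <- function(id) !is.na(id) && id > g$n_junctions
      is_j_node <- function(id) !is.na(id) && id >= 1 && id <= g$n_junctions
      spur <- vapply(g$branches, function(b) {
        a <- b$nodes[1]; d <- b$nodes[2]
        ((is_ep_node(a) && is_j_node(d)) || (is_j_node(a) && is_ep_node(d))) &&
          b$length_px < min_branch_px
      }, logical(1))
      if (!any(spur)) break
      for (b in g$branches[spur]) {
        keep_junction <- g$jlab[cbind(b$path[, 1], b$path[, 2])] > 0L
        drop <- b$path[!keep_junction, , drop = FALSE]
        skel[cbind(drop[, 1], drop[, 2])] <- FALSE
      }
      if (!any(skel)) return(empty())
      g <- extract_skeleton_graph(skel, px)
    }
  }

  g <- refine_junction_lengths(g, m, px)
  g <- extend_cap_ends(g, m, px)

  jyx <- if (g$n_junctions > 0) {
    t(vapply(seq_len(g$n_junctions), function(j) {
      idx <- which(g$jlab == j)
      nr <- nrow(skel)
      c(mean((idx - 1L) %% nr + 1L), mean((idx - 1L) %/% nr + 1L))
    }, numeric(2)))
  } else matrix(numeric(0), 0, 2)
  eyx <- if (length(g$endpoint_idx)) {
    nr <- nrow(skel)
    cbind((g$endpoint_idx - 1L) %% nr + 1L,
          (g$endpoint_idx - 1L) %/% nr + 1L)
  } else matrix(integer(0), 0, 2)

  structure(
    list(skeleton = skel, branches = g$branches,
         n_junctions = g$n_junctions, n_endpoints = g$n_endpoints,
         junction_yx = jyx,
         junction_refined_yx = g$junction_refined_yx %||% NULL,
         endpoint_yx = eyx, pixel_size_um = px),
    class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> ", sum(x$skeleton), " px, ",
      length(x$branches), " branches, ",
      x$n_junctions, " junctions, ", x$n_endpoints, " endpoints\n", sep = "")
  invisible(x)
}
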