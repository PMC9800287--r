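# Ground surface machinery.
#
# The ground surface model is a Delaunay TIN with piecewise-linear
# interpolation (exact on planes). For speed the TIN is evaluated once onto a
# fine regular grid and scattered queries are then answered by bilinear
# interpolation from that grid; bilinear interpolation of plane-sampled nodes
# is still exact on planes. Small query batches go straight to the TIN.

# Decimate a large vertex set before triangulation (one median-height point
# per decimation cell). The TIN cost grows steeply with the vertex count
# while terrain information saturates long before; sets of <= 40k points are
# returned unchanged, so small (exactness-tested) clouds are never touched.
decimate_vertices <- function(gx, gy, gz, keep = 40000L, target = 30000) {
  n <- length(gx)
  if (n <= keep) return(list(x = gx, y = gy, z = gz))
  x0 <- min(gx); x1 <- max(gx); y0 <- min(gy); y1 <- max(gy)
  dcell <- sqrt(max((x1 - x0) * (y1 - y0), 1e-9) / target)
  di <- floor((gx - x0) / dcell)
  dcode <- di + floor((gy - y0) / dcell) * (max(di) + 1)
  ord <- order(dcode, gz)
  runs <- rle(dcode[ord])
  ends <- cumsum(runs$lengths)
  mid <- ord[ends - (runs$lengths - 1L) %/% 2L]
  list(x = gx[mid], y = gy[mid], z = gz[mid])
}

# Build a ground-surface object from ground coordinates.
# grid_cell = NULL picks max(extent/1000, 0.02) m.
build_ground_surface <- function(gx, gy, gz, grid_cell = NULL) {
  n <- length(gx)
  if (n == 0L) stop("no ground points")
  noncollinear <- n >= 3L && {
    dx <- gx - gx[1]; dy <- gy - gy[1]
    any(abs(dx * dy[2] - dy * dx[2]) > 1e-9 * (1 + max(abs(dx)) + max(abs(dy))))
  }
  if (!noncollinear) {
    return(structure(list(kind = "nn", gx = gx, gy = gy, gz = gz),
                     class = "ground_surface"))
  }
  x0 <- min(gx); x1 <- max(gx); y0 <- min(gy); y1 <- max(gy)
  # Very large ground sets are decimated before triangulation (one
  # median-height point per decimation cell): the TIN cost grows steeply with
  # the vertex count while terrain information saturates long before. The
  # full point set is kept for hull and nearest-neighbour queries.
  d <- decimate_vertices(gx, gy, gz)
  tx <- d$x; ty <- d$y; tz <- d$z
  if (is.null(grid_cell))
    grid_cell <- max(max(x1 - x0, y1 - y0) / 1000, 0.02)
  nx <- max(2L, ceiling((x1 - x0) / grid_cell) + 1L)
  ny <- max(2L, ceiling((y1 - y0) / grid_cell) + 1L)
  xo <- seq(x0, x1, length.out = nx)
  yo <- seq(y0, y1, length.out = ny)
  # Ghost points on the global least-squares plane, well outside the bbox:
  # the grid then has no holes at hull-boundary cells, and because the ghosts
  # are coplanar with a planar cloud, interpolation stays exact on planes.
  pl <- stats::lm.fit(cbind(1, tx, ty), tz)$coefficients
  pl[is.na(pl)] <- 0
  m <- max(2, 0.1 * max(x1 - x0, y1 - y0))
  ghx <- c(x0 - m, x1 + m, x0 - m, x1 + m, (x0 + x1) / 2, (x0 + x1) / 2, x0 - m, x1 + m)
  ghy <- c(y0 - m, y0 - m, y1 + m, y1 + m, y0 - m, y1 + m, (y0 + y1) / 2, (y0 + y1) / 2)
  ghz <- pl[1] + pl[2] * ghx + pl[3] * ghy
  g <- interp::interp(c(tx, ghx), c(ty, ghy), c(tz, ghz), xo = xo, yo = yo,
                      method = "linear", duplicate = "mean")
  zm <- g$z
  na <- which(is.na(zm))
  if (length(na) && length(na) < length(zm)) {
    ok <- which(!is.na(zm))
    oc <- arrayInd(ok, dim(zm)); nc <- arrayInd(na, dim(zm))
    nn <- FNN::get.knnx(cbind(xo[oc[, 1]], yo[oc[, 2]]),
                        cbind(xo[nc[, 1]], yo[nc[, 2]]), k = 1)$nn.index[, 1]
    zm[na] <- zm[ok[nn]]
  } else if (length(na) == length(zm)) {
    zm[] <- mean(gz)
  }
  hull <- grDevices::chull(gx, gy)
  structure(list(kind = "tin", gx = gx, gy = gy, gz = gz,
                 tx = tx, ty = ty, tz = tz,
                 xo = xo, yo = yo, z = zm,
                 hx = gx[hull], hy = gy[hull]),
            class = "ground_surface")
}

ground_surface_from_cloud <- function(cloud, grid_cell = NULL) {
  if (!has_ground_labels(cloud))
    stop("cloud has no ground labels; run classify_ground() first")
  g <- cloud$label == "ground"
  build_ground_surface(cloud$x[g], cloud$y[g], cloud$z[g], grid_cell = grid_cell)
}

# Bilinear evaluation from the precomputed grid (queries clamped to the bbox).
eval_surface_grid <- function(surf, qx, qy) {
  if (surf$kind == "nn") {
    nn <- FNN::get.knnx(cbind(surf$gx, surf$gy), cbind(qx, qy), k = 1)$nn.index[, 1]
    return(surf$gz[nn])
  }
  xo <- surf$xo; yo <- surf$yo
  dx <- xo[2] - xo[1]; dy <- yo[2] - yo[1]
  ix <- pmin.int(pmax.int(floor((qx - xo[1]) / dx), 0L), length(xo) - 2L)
  iy <- pmin.int(pmax.int(floor((qy - yo[1]) / dy), 0L), length(yo) - 2L)
  fx <- pmin.int(pmax.int((qx - xo[1]) / dx - ix, 0), 1)
  fy <- pmin.int(pmax.int((qy - yo[1]) / dy - iy, 0), 1)
  i1 <- cbind(ix + 1L, iy + 1L)
  z00 <- surf$z[i1]
  z10 <- surf$z[cbind(ix + 2L, iy + 1L)]
  z01 <- surf$z[cbind(ix + 1L, iy + 2L)]
  z11 <- surf$z[cbind(ix + 2L, iy + 2L)]
  (1 - fx) * (1 - fy) * z00 + fx * (1 - fy) * z10 +
    (1 - fx) * fy * z01 + fx * fy * z11
}

# Exact TIN evaluation (slow per query); NA outside the hull.
eval_surface_tin <- function(surf, qx, qy) {
  if (surf$kind == "nn") return(eval_surface_grid(surf, qx, qy))
  interp::interpp(surf$tx, surf$ty, surf$tz, xo = qx, yo = qy,
                  duplicate = "mean")$z
}

# Signed status relative to the ground convex hull: TRUE inside/on, plus
# distance to the hull boundary for outside queries.
hull_distance <- function(surf, qx, qy) {
  if (surf$kind == "nn") {
    d <- sqrt(FNN::get.knnx(cbind(surf$gx, surf$gy), cbind(qx, qy),
                            k = 1)$nn.dist[, 1])
    return(list(inside = d < 1e-9, dist = d))
  }
  hx <- surf$hx; hy <- surf$hy
  m <- length(hx)
  nq <- length(qx)
  inside <- rep(TRUE, nq)
  dmin <- rep(Inf, nq)
  for (k in seq_len(m)) {
    x1 <- hx[k]; y1 <- hy[k]
    x2 <- hx[if (k == m) 1L else k + 1L]; y2 <- hy[if (k == m) 1L else k + 1L]
    ex <- x2 - x1; ey <- y2 - y1
    # chull() returns clockwise order: inside points have cross <= 0
    cr <- ex * (qy - y1) - ey * (qx - x1)
    inside <- inside & (cr <= 1e-9)
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) pmin.int(pmax.int(((qx - x1) * ex + (qy - y1) * ey) / len2, 0), 1) else 0
    dmin <- pmin.int(dmin, sqrt((qx - (x1 + t * ex))^2 + (qy - (y1 + t * ey))^2))
  }
  list(inside = inside, dist = ifelse(inside, 0, dmin))
}

#' Classify ground points
#'
#' A grid-minimum classifier: the cloud is binned on a planimetric grid of
#' `cell_size`, the lowest point of each cell is taken as a local ground
#' sample, low outlier cells are suppressed by comparing each cell against the
#' median of its 3x3 neighbourhood (the reference is the larger of the two, so
#' crests on curved terrain are not biased down), the resulting minimum-surface
#' points are interpolated into a continuous reference surface, and every
#' point within `z_tolerance` of that surface is labelled `ground`.
#'
#' @param cloud A [point_cloud()].
#' @param cell_size Grid cell size in metres. Default 1 m.
#' @param z_tolerance Vertical band above the reference surface still counted
#'   as ground, in metres. Default 0.15 m.
#' @return The cloud with every point labelled `ground` or `non_ground`.
#' @examples
#' sc <- make_scene(scene_spec(extent = 20, terrain = "flat", n_trees = 3, seed = 1))
#' cl <- classify_ground(sc)
#' table(cl$label)
#' @export
classify_ground <- function(cloud, cell_size = 1, z_tolerance = 0.15) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cell_size <= 0) stop("cell_size must be positive")
  n <- length(cloud$x)
  rx <- range(cloud$x); ry <- range(cloud$y)
  if (diff(rx) < 1e-12 && diff(ry) < 1e-12) {
    if (n == 1L) {
      cloud$label <- "ground"
      return(cloud)
    }
    stop("degenerate cloud: all points share the same planimetric position")
  }
  # minimum-surface vertices are collected on half-cell subcells: the finer
  # support halves the unsupported band at plot edges on sloped terrain,
  # while the outlier veto below still works at the neighbourhood scale
  half <- cell_size / 2
  ci <- floor((cloud$x - rx[1]) / half)
  cj <- floor((cloud$y - ry[1]) / half)
  nci <- max(ci) + 1L
  cell <- ci + cj * nci
  ord <- order(cell, cloud$z)
  first <- ord[!duplicated(cell[ord])]      # index of the lowest point per cell
  mi <- ci[first]; mj <- cj[first]
  mz <- cloud$z[first]
  ncj <- max(cj) + 1L
  zmat <- matrix(NA_real_, nci, ncj)
  zmat[cbind(mi + 1L, mj + 1L)] <- mz
  # one median pass over the 3x3 neighbourhood of the minimum surface
  med <- matrix(NA_real_, nci, ncj)
  if (nci >= 2L || ncj >= 2L) {
    neigh <- array(NA_real_, c(nci, ncj, 9L))
    k <- 0L
    for (di in -1:1) for (dj in -1:1) {
      k <- k + 1L
      si <- max(1, 1 - di):min(nci, nci - di)
      sj <- max(1, 1 - dj):min(ncj, ncj - dj)
      neigh[si, sj, k] <- zmat[si + di, sj + dj]
    }
    med <- apply(neigh, c(1, 2), stats::median, na.rm = TRUE)
  }
  # keep the cell's own minimum unless it is a strong outlier against its
  # neighbourhood (pits from noise, or cells containing only canopy at the
  # plot edge); the threshold tolerates slope- and curvature-scale offsets
  medc <- med[cbind(mi + 1L, mj + 1L)]
  out_thr <- pmax(1, cell_size)
  ref_z <- ifelse(!is.na(medc) & abs(mz - medc) > out_thr, medc, mz)
  mx <- cloud$x[first]; my <- cloud$y[first]
  surf <- build_ground_surface(mx, my, ref_z,
                               grid_cell = max(cell_size / 4, 0.02))
  ref <- eval_surface_grid(surf, cloud$x, cloud$y)
  cloud$label <- ifelse(cloud$z - ref <= z_tolerance, "ground", "non_ground")
  cloud
}

#' Normalize heights above ground
#'
#' Replaces every point's z by its height above the interpolated ground
#' surface (a Delaunay TIN over the classified ground points), so ground
#' points end up at height 0 within the interpolation tolerance. Planimetric
#' coordinates are unchanged. Idempotent within tolerance.
#'
#' @param cloud A [point_cloud()] with ground labels (see [classify_ground()]).
#' @param surface Optional precomputed internal ground surface (used by the
#'   survey pipeline to avoid rebuilding the TIN).
#' @return The normalized cloud.
#' @export
normalize_heights <- function(cloud, surface = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!has_ground_labels(cloud))
    stop("cloud has no ground points; run classify_ground() first")
  surf <- if (is.null(surface)) ground_surface_from_cloud(cloud) else surface
  cloud$z <- cloud$z - eval_surface_grid(surf, cloud$x, cloud$y)
  cloud
}

#' Densify ("encrypt") the ground surface
#'
#' Ground returns are sparse relative to the occlusion raster, so a ground
#' surface that should block a pixel may miss it. This interpolates additional
#' ground points on a regular grid over the cloud's planimetric bounding box
#' (or a disc) using the TIN over the existing ground points, and appends
#' them, labelled `ground`. Original points are always retained.
#'
#' @param cloud A [point_cloud()] with ground labels.
#' @param spacing Grid spacing in metres. The survey pipeline defaults this to
#'   the raster resolution so every pixel the ground should block can be
#'   occupied.
#' @param region Optional disc `c(cx, cy, r)` restricting densification (the
#'   survey pipeline uses the sampled circular area).
#' @return The cloud with interpolated ground points appended.
#' @export
densify_ground <- function(cloud, spacing, region = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (spacing <= 0) stop("spacing must be positive")
  if (!has_ground_labels(cloud))
    stop("cloud has no ground points; run classify_ground() first")
  g <- cloud$label == "ground"
  gx <- cloud$x[g]; gy <- cloud$y[g]; gz <- cloud$z[g]
  nc <- length(gx) >= 3L && {
    dx <- gx - gx[1]; dy <- gy - gy[1]
    any(abs(dx * dy[2] - dy * dx[2]) > 1e-9 * (1 + max(abs(dx)) + max(abs(dy))))
  }
  if (!nc) stop("densify_ground needs at least 3 non-collinear ground points")
  xs <- seq(min(gx), max(gx), by = spacing)
  ys <- seq(min(gy), max(gy), by = spacing)
  if (!is.null(region)) {
    xs <- xs[xs >= region[1] - region[3] & xs <= region[1] + region[3]]
    ys <- ys[ys >= region[2] - region[3] & ys <= region[2] + region[3]]
    if (!length(xs) || !length(ys)) return(cloud)
  }
  # evaluate the TIN directly at the grid nodes (exact; NA outside the hull);
  # very dense ground sets are decimated first (see decimate_vertices)
  dv <- decimate_vertices(gx, gy, gz)
  gmat <- interp::interp(dv$x, dv$y, dv$z, xo = xs, yo = ys,
                         method = "linear", duplicate = "mean")$z
  keep <- which(!is.na(gmat))
  if (!length(keep)) return(cloud)
  idx <- arrayInd(keep, dim(gmat))
  nxs <- xs[idx[, 1]]; nys <- ys[idx[, 2]]; nzs <- gmat[keep]
  if (!is.null(region)) {
    ins <- (nxs - region[1])^2 + (nys - region[2])^2 <= region[3]^2
    nxs <- nxs[ins]; nys <- nys[ins]; nzs <- nzs[ins]
    if (!length(nxs)) return(cloud)
  }
  lab <- cloud$label
  point_cloud(c(cloud$x, nxs), c(cloud$y, nys), c(cloud$z, nzs),
              label = c(lab, rep("ground", length(nxs))),
              crs_note = cloud$crs_note)
}

#' Ground elevation at planimetric positions
#'
#' Linearly interpolated elevation on the Delaunay TIN over the classified
#' ground points. Queries outside the ground convex hull fall back to the
#' nearest ground point, up to 2 m beyond the hull; farther queries are an
#' error (out of coverage).
#'
#' @param cloud A [point_cloud()] with ground labels.
#' @param x,y Query positions (vectors, metres).
#' @param surface Optional precomputed internal ground surface.
#' @param max_outside Coverage margin beyond the hull in metres (default 2).
#' @return Numeric vector of elevations.
#' @export
ground_elevation_at <- function(cloud, x, y, surface = NULL, max_outside = 2) {
  surf <- if (is.null(surface)) ground_surface_from_cloud(cloud) else surface
  stopifnot(length(x) == length(y))
  hd <- hull_distance(surf, x, y)
  if (any(hd$dist > max_outside))
    stop(sprintf("ground query %.1f m outside ground coverage (max %.1f m allowed)",
                 max(hd$dist), max_outside))
  out <- numeric(length(x))
  if (surf$kind == "nn") return(eval_surface_grid(surf, x, y))
  ins <- hd$inside
  if (any(ins)) {
    if (sum(ins) <= 4000L) {
      z <- eval_surface_tin(surf, x[ins], y[ins])
      # fp-edge cases right on the hull boundary: use the grid value
      if (anyNA(z)) z[is.na(z)] <- eval_surface_grid(surf, x[ins][is.na(z)], y[ins][is.na(z)])
      out[ins] <- z
    } else {
      out[ins] <- eval_surface_grid(surf, x[ins], y[ins])
    }
  }
  if (any(!ins)) {
    nn <- FNN::get.knnx(cbind(surf$gx, surf$gy),
                        cbind(x[!ins], y[!ins]), k = 1)$nn.index[, 1]
    out[!ins] <- surf$gz[nn]
  }
  out
}
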