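# Projection geometry: target placement, elevation angle, projection slab,
# candidate selection, and line-of-sight projection onto the target rectangle.

#' Construct an observer
#'
#' @param x0,y0 Planimetric position in metres.
#' @param z0 Ground elevation at the observer (0 in the normalized scenario).
#' @return An object of class `observer`.
#' @export
observer <- function(x0, y0, z0 = 0) {
  stopifnot(is.finite(x0), is.finite(y0), is.finite(z0))
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0), z0 = as.numeric(z0)),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("<observer> (%.3f, %.3f, %.3f)\n", x$x0, x$y0, x$z0))
  invisible(x)
}

# Sight-axis coordinates: s along the sight direction, u lateral offset
# (left of the sight direction positive; sight along +x gives u = dy).
# The azimuth convention is theta degrees counterclockwise from the +x axis.
sight_coords <- function(x, y, obs, theta) {
  a <- theta * pi / 180
  dx <- x - obs$x0; dy <- y - obs$y0
  list(s = dx * cos(a) + dy * sin(a),
       u = dy * cos(a) - dx * sin(a))
}

#' Place the target rectangle at a polar sample position
#'
#' The observed body is represented by its minimum enclosing rectangle: a
#' vertical `w` x `h` rectangle perpendicular to the horizontal sight
#' direction, its base centred `i` metres from the observer at azimuth
#' `theta` (degrees counterclockwise from the +x axis).
#'
#' @param obs An [observer()].
#' @param theta Azimuth in degrees.
#' @param i Distance from the observer in metres (> 0).
#' @param w,h Rectangle width and height in metres.
#' @param ground Optional [point_cloud()] with ground labels (or `NULL` for
#'   the normalized scenario, where the base elevation is 0).
#' @param surface Optional precomputed internal ground surface.
#' @return A `target_rectangle`: theta, i, w, h, base_x, base_y, z_base.
#' @export
target_position <- function(obs, theta, i, w = 1.5, h = 2, ground = NULL,
                            surface = NULL) {
  stopifnot(inherits(obs, "observer"))
  if (i <= 0) stop("target distance i must be positive")
  a <- theta * pi / 180
  base_x <- obs$x0 + i * cos(a)
  base_y <- obs$y0 + i * sin(a)
  z_base <- if (is.null(ground) && is.null(surface)) 0
            else ground_elevation_at(ground, base_x, base_y, surface = surface)
  structure(list(theta = theta, i = i, w = w, h = h,
                 base_x = base_x, base_y = base_y, z_base = z_base),
            class = "target_rectangle")
}

#' Elevation angle of the sight line
#'
#' The angle Omega = arctan((z_base - z0) / i) between the horizontal and the
#' line from the observer's ground point to the target's base, strictly inside
#' (-90, 90) degrees. It tilts the projection slab in the terrain-preserving
#' scenario; on level terrain it is 0 and the scenario reduces to the
#' normalized one.
#'
#' @param obs An [observer()].
#' @param target A `target_rectangle` from [target_position()].
#' @return Omega in degrees.
#' @export
elevation_angle <- function(obs, target) {
  stopifnot(inherits(obs, "observer"), inherits(target, "target_rectangle"))
  atan((target$z_base - obs$z0) / target$i) * 180 / pi
}

#' Build the projection slab
#'
#' The axis-aligned region of space whose points are projected onto the
#' target rectangle. Planimetrically it is the bounding box of the sight
#' corridor (width `w`, length `i`), expanded by 1e-6 m. Vertically it is
#' `[0, h]` in the normalized scenario, and the band between the two planes
#' z = z0 + tan(Omega) s and z = z0 + tan(Omega) s + h (s the along-sight
#' coordinate) in the terrain-preserving scenario, so that the band passes
#' through the observer's ground point and the target base.
#'
#' @param obs An [observer()].
#' @param target A `target_rectangle`.
#' @param normalized Logical; `TRUE` for the terrain-normalized scenario.
#' @return A `projection_slab` with the planimetric bounds, `tan_omega`,
#'   `omega` (degrees) and scenario metadata.
#' @export
build_slab <- function(obs, target, normalized = TRUE) {
  stopifnot(inherits(obs, "observer"), inherits(target, "target_rectangle"))
  a <- target$theta * pi / 180
  lx <- -sin(a) * target$w / 2   # half-width vector, left of sight
  ly <- cos(a) * target$w / 2
  cx <- c(obs$x0 + lx, obs$x0 - lx, target$base_x + lx, target$base_x - lx)
  cy <- c(obs$y0 + ly, obs$y0 - ly, target$base_y + ly, target$base_y - ly)
  omega <- if (normalized) 0 else elevation_angle(obs, target)
  structure(list(x1 = min(cx) - 1e-6, x2 = max(cx) + 1e-6,
                 y1 = min(cy) - 1e-6, y2 = max(cy) + 1e-6,
                 normalized = normalized,
                 z0 = obs$z0, omega = omega, tan_omega = tan(omega * pi / 180),
                 theta = target$theta, i = target$i,
                 w = target$w, h = target$h),
            class = "projection_slab")
}

#' Select the points that project onto the target rectangle
#'
#' Returns the indices of the cloud points inside the slab: within its
#' planimetric bounds, within its vertical band, and strictly between the
#' observer and the target plane along the sight axis (0 < s < i). The lower
#' and upper vertical bounds are inclusive so that an exactly-normalized
#' ground plane (z = 0) can still occlude its pixel row. Points at the
#' observer or on the target plane are excluded: the observed does not
#' occlude itself and the observer is not an obstacle.
#'
#' @param cloud A [point_cloud()].
#' @param slab A `projection_slab` from [build_slab()].
#' @param obs The [observer()] the slab was built for.
#' @return Integer vector of point indices (possibly empty).
#' @export
select_candidates <- function(cloud, slab, obs) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(slab, "projection_slab"))
  sc <- sight_coords(cloud$x, cloud$y, obs, slab$theta)
  z <- cloud$z
  keep <- cloud$x >= slab$x1 & cloud$x <= slab$x2 &
    cloud$y >= slab$y1 & cloud$y <= slab$y2 &
    sc$s > 0 & sc$s < slab$i
  if (slab$normalized) {
    keep <- keep & z >= 0 & z <= slab$h
  } else {
    zl <- slab$z0 + slab$tan_omega * sc$s
    keep <- keep & z >= zl & z <= zl + slab$h
  }
  which(keep)
}

#' Project points onto the target rectangle
#'
#' Orthographic projection along the horizontal sight direction: each point
#' maps to a lateral offset `u` on the rectangle (0 at the centre; sight
#' along +x gives u = y - y0) and a height `v` above the rectangle base. In
#' the normalized scenario `v = z`. In the terrain-preserving scenario the
#' height is corrected for the elevation angle:
#' `v = z + tan(Omega) * d - z_base`, with `d` the horizontal distance from
#' the point to the target base line.
#'
#' @param cloud A [point_cloud()] (or any list with x, y, z vectors).
#' @param obs An [observer()].
#' @param target A `target_rectangle`.
#' @param normalized Logical scenario flag.
#' @param candidates Optional integer indices (e.g. from
#'   [select_candidates()]); default all points.
#' @param omega Elevation angle in degrees; computed from the target when
#'   omitted.
#' @return Data frame with columns `u`, `v`, `index`.
#' @export
project_points <- function(cloud, obs, target, normalized = TRUE,
                           candidates = NULL, omega = NULL) {
  stopifnot(inherits(obs, "observer"), inherits(target, "target_rectangle"))
  idx <- if (is.null(candidates)) seq_along(cloud$x) else candidates
  sc <- sight_coords(cloud$x[idx], cloud$y[idx], obs, target$theta)
  if (normalized) {
    v <- cloud$z[idx]
  } else {
    if (is.null(omega)) omega <- elevation_angle(obs, target)
    v <- cloud$z[idx] + tan(omega * pi / 180) * (target$i - sc$s) - target$z_base
  }
  if (any(!is.finite(v)) || any(!is.finite(sc$u)))
    stop("non-finite projection result")
  data.frame(u = sc$u, v = v, index = idx)
}
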