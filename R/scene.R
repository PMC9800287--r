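# Seeded synthetic forest-plot scenes with ground-truth labels, so every
# pipeline stage can be scored without field data.

#' Specify a synthetic scene
#'
#' Describes a forest-plot point cloud: an analytic terrain surface sampled
#' on a jittered grid (jitter bounded by half the spacing, so worst-case
#' ground gaps are controlled), plus optional trees (cylindrical stems and
#' uniform-in-ellipsoid crowns), solid walls, and low shrub layers. The
#' default extent emulates a 90 m x 90 m plot and the default tree height
#' distribution a broadleaved stand of mean height 5.05 m.
#'
#' @param extent Either one number (a square of that side, centred on the
#'   origin) or `c(xmin, xmax, ymin, ymax)`, metres.
#' @param terrain One of `"flat"`, `"tilt"` (z = slope x), `"sinusoid"`
#'   (z = amplitude sin(2 pi x / wavelength)), `"ridge"` (a Gaussian ridge
#'   running along y), or `"custom"` (supply `terrain_fn(x, y)`).
#' @param slope,amplitude,wavelength,ridge_height,ridge_position,ridge_width
#'   Terrain parameters, metres (slope is dimensionless).
#' @param terrain_fn Function of `(x, y)` returning elevations, for
#'   `terrain = "custom"`.
#' @param ground_spacing Ground sampling grid spacing, metres. 0.25 m
#'   (16 points/m^2) approximates a dense terrestrial-laser ground return.
#' @param n_trees Number of trees, placed uniformly.
#' @param tree_height_mean,tree_height_sd Tree height distribution, metres.
#' @param stem_diameter Stem diameter, metres.
#' @param stem_points,crown_points Points per stem / per crown.
#' @param walls List of `c(x1, y1, x2, y2, height)` vertical walls, sampled
#'   at `wall_spacing`.
#' @param wall_spacing Wall sampling spacing, metres (make it at most the
#'   survey resolution for an opaque wall).
#' @param shrubs List of `c(xmin, xmax, ymin, ymax, hag_min, hag_max, n)`
#'   low-vegetation layers: `n` points uniform in the box, at heights
#'   `hag_min`..`hag_max` above the terrain.
#' @param seed Integer seed; identical seeds give identical clouds.
#' @return A `scene_spec`.
#' @seealso [make_scene()], [canonical_ridge_scene()]
#' @export
scene_spec <- function(extent = 90, terrain = c("flat", "tilt", "sinusoid",
                                                "ridge", "custom"),
                       slope = 0.1, amplitude = 1, wavelength = 20,
                       ridge_height = 2, ridge_position = 10, ridge_width = 3,
                       terrain_fn = NULL,
                       ground_spacing = 0.25,
                       n_trees = 0, tree_height_mean = 5.05,
                       tree_height_sd = 1.2, stem_diameter = 0.36,
                       stem_points = 40, crown_points = 300,
                       walls = list(), wall_spacing = 0.02,
                       shrubs = list(), seed = 1) {
  terrain <- match.arg(terrain)
  if (length(extent) == 1L) extent <- c(-extent / 2, extent / 2,
                                        -extent / 2, extent / 2)
  stopifnot(length(extent) == 4L, extent[2] > extent[1], extent[4] > extent[3])
  if (ground_spacing <= 0) stop("ground_spacing must be positive")
  fn <- switch(terrain,
    flat = function(x, y) rep(0, length(x)),
    tilt = function(x, y) slope * x,
    sinusoid = function(x, y) amplitude * sin(2 * pi * x / wavelength),
    ridge = function(x, y) ridge_height * exp(-((x - ridge_position) / ridge_width)^2),
    custom = {
      if (!is.function(terrain_fn)) stop("terrain = 'custom' needs terrain_fn")
      terrain_fn
    })
  structure(list(extent = extent, terrain = terrain, terrain_fn = fn,
                 ground_spacing = ground_spacing,
                 n_trees = n_trees, tree_height_mean = tree_height_mean,
                 tree_height_sd = tree_height_sd, stem_diameter = stem_diameter,
                 stem_points = stem_points, crown_points = crown_points,
                 walls = walls, wall_spacing = wall_spacing,
                 shrubs = shrubs, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic scene
#'
#' Samples the scene described by a [scene_spec()] into a [point_cloud()]
#' with ground-truth metadata: attribute `truth` is a data frame with the
#' generating `label` (`ground`, `tree`, `wall`, `shrub`) and `hag` (height
#' above the analytic terrain) of every point. The returned cloud itself is
#' unclassified, as a field acquisition would be; the truth attribute lets
#' classification and normalization be scored exactly. Output is
#' deterministic for a fixed seed.
#'
#' @param spec A [scene_spec()].
#' @return A [point_cloud()] with a `truth` attribute (and `terrain_fn`, for
#'   analytic checks).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  e <- spec$extent
  fn <- spec$terrain_fn
  sp <- spec$ground_spacing

  gx0 <- seq(e[1] + sp / 2, e[2], by = sp)
  gy0 <- seq(e[3] + sp / 2, e[4], by = sp)
  gx <- rep(gx0, times = length(gy0))
  gy <- rep(gy0, each = length(gx0))
  jit <- 0.49 * sp
  gx <- gx + stats::runif(length(gx), -jit, jit)
  gy <- gy + stats::runif(length(gy), -jit, jit)
  gz <- fn(gx, gy)
  X <- list(gx); Y <- list(gy); Z <- list(gz)
  L <- list(rep("ground", length(gx)))

  if (spec$n_trees > 0) {
    tx <- stats::runif(spec$n_trees, e[1] + 1, e[2] - 1)
    ty <- stats::runif(spec$n_trees, e[3] + 1, e[4] - 1)
    th <- pmax(1.5, stats::rnorm(spec$n_trees, spec$tree_height_mean,
                                 spec$tree_height_sd))
    for (t in seq_len(spec$n_trees)) {
      base <- fn(tx[t], ty[t])
      # stem: points on the cylinder surface up to the crown base
      ns <- spec$stem_points
      ang <- stats::runif(ns, 0, 2 * pi)
      sz <- stats::runif(ns, 0, 0.45 * th[t])
      r <- spec$stem_diameter / 2
      X <- c(X, list(tx[t] + r * cos(ang)))
      Y <- c(Y, list(ty[t] + r * sin(ang)))
      Z <- c(Z, list(base + sz))
      L <- c(L, list(rep("tree", ns)))
      # crown: uniform in an ellipsoid
      nc <- spec$crown_points
      cz <- 0.65 * th[t]; ca <- 0.2 * th[t] + 0.5; cc <- 0.35 * th[t]
      u <- matrix(stats::rnorm(3 * nc), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * stats::runif(nc)^(1 / 3)
      X <- c(X, list(tx[t] + ca * u[, 1]))
      Y <- c(Y, list(ty[t] + ca * u[, 2]))
      Z <- c(Z, list(base + cz + cc * u[, 3]))
      L <- c(L, list(rep("tree", nc)))
    }
  }

  for (wl in spec$walls) {
    stopifnot(length(wl) == 5L)
    len <- sqrt((wl[3] - wl[1])^2 + (wl[4] - wl[2])^2)
    tt <- seq(0, 1, by = spec$wall_spacing / max(len, spec$wall_spacing))
    hh <- seq(0, wl[5], by = spec$wall_spacing)
    wx <- rep(wl[1] + tt * (wl[3] - wl[1]), times = length(hh))
    wy <- rep(wl[2] + tt * (wl[4] - wl[2]), times = length(hh))
    wh <- rep(hh, each = length(tt))
    X <- c(X, list(wx)); Y <- c(Y, list(wy))
    Z <- c(Z, list(fn(wx, wy) + wh))
    L <- c(L, list(rep("wall", length(wx))))
  }

  for (sh in spec$shrubs) {
    stopifnot(length(sh) == 7L)
    n <- sh[7]
    sx <- stats::runif(n, sh[1], sh[2])
    sy <- stats::runif(n, sh[3], sh[4])
    hag <- stats::runif(n, sh[5], sh[6])
    X <- c(X, list(sx)); Y <- c(Y, list(sy))
    Z <- c(Z, list(fn(sx, sy) + hag))
    L <- c(L, list(rep("shrub", n)))
  }

  x <- unlist(X); y <- unlist(Y); z <- unlist(Z); lab <- unlist(L)
  cloud <- point_cloud(x, y, z, crs_note = "synthetic scene (local metres)")
  attr(cloud, "truth") <- data.frame(label = lab, hag = z - fn(x, y))
  attr(cloud, "terrain_fn") <- fn
  cloud
}

#' The canonical ridge scene
#'
#' A fixed terrain-relief test scene used throughout the deviation analyses:
#' the observer stands on a knoll (z0 about 4.2 m), a 2 m Gaussian ridge
#' crosses the sight direction 10 m out, the far field is flat, and a dense
#' low shrub layer (0.25-0.55 m above ground) covers the ridge crest. In the
#' normalized scenario the shrub layer occludes the bottom band of any
#' target beyond the ridge; in the terrain-preserving scenario the downhill
#' elevation angle drops both ridge and shrubs below the sight corridor at
#' far distances, so visibility increases there -- a positive terrain-induced
#' visibility deviation whose magnitude shrinks as the target height h grows.
#'
#' @param seed Seed for the scene's random sampling.
#' @return List with `cloud` (a [point_cloud()] with truth attributes),
#'   `observer` (an [observer()] on the knoll), and `ridge_position`.
#' @export
canonical_ridge_scene <- function(seed = 421L) {
  fn <- function(x, y)
    4.5 / (1 + exp((x - 3) / 1.2)) + 2 * exp(-((x - 10) / 3)^2)
  spec <- scene_spec(extent = c(-4, 44, -7, 7), terrain = "custom",
                     terrain_fn = fn, ground_spacing = 0.15,
                     shrubs = list(c(8.5, 11.5, -7, 7, 0.25, 0.55, 30000)),
                     seed = seed)
  cloud <- make_scene(spec)
  list(cloud = cloud, observer = observer(0, 0, fn(0, 0)),
       ridge_position = 10)
}
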