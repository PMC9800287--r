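# Polar survey over (theta, i): the full sampling design of the framework.

#' Survey configuration
#'
#' All program inputs of a visibility survey: the observer position, the
#' observed rectangle (w, h), the polar sampling design (start/end azimuth,
#' azimuth step, farthest distance, distance step), the raster resolution, the
#' scenario flag, and the ground-processing parameters. The defaults are the
#' survey parameters of a typical forest-plot run: azimuths 10-360 degrees in
#' 10-degree steps, distances 0.5-40 m in 0.5 m steps (36 x 80 = 2880
#' samples), a 1.5 m x 2 m rectangle at 0.005 m resolution.
#'
#' @param observer An [observer()].
#' @param w,h Target rectangle width and height, metres.
#' @param start_angle,end_angle,angle_step Azimuth design, degrees
#'   (counterclockwise from the +x axis); both endpoints inclusive.
#' @param max_distance,distance_step Distance design, metres; distances run
#'   `distance_step, 2*distance_step, ..., max_distance`.
#' @param resolution Raster pixel size, metres.
#' @param normalized `TRUE` for the terrain-normalized scenario, `FALSE` to
#'   preserve terrain relief.
#' @param ground_cell,ground_tol Ground-classification parameters, metres
#'   (see [classify_ground()]).
#' @param densify_spacing Ground-densification grid spacing, metres; defaults
#'   to `resolution` so every pixel the ground should block can be occupied.
#'   Set to 0 to skip densification.
#' @return A `survey_config`.
#' @export
survey_config <- function(observer = sightshed::observer(0, 0, 0),
                          w = 1.5, h = 2,
                          start_angle = 10, end_angle = 360, angle_step = 10,
                          max_distance = 40, distance_step = 0.5,
                          resolution = 0.005, normalized = TRUE,
                          ground_cell = 1, ground_tol = 0.15,
                          densify_spacing = resolution) {
  stopifnot(inherits(observer, "observer"))
  if (w <= 0 || h <= 0) stop("w and h must be positive")
  if (angle_step <= 0) stop("angle_step must be positive")
  if (distance_step <= 0) stop("distance_step must be positive")
  if (start_angle > end_angle) stop("start_angle must be <= end_angle")
  if (max_distance < distance_step) stop("max_distance must be >= distance_step")
  if (resolution <= 0) stop("resolution must be positive")
  structure(list(observer = observer, w = w, h = h,
                 start_angle = start_angle, end_angle = end_angle,
                 angle_step = angle_step, max_distance = max_distance,
                 distance_step = distance_step, resolution = resolution,
                 normalized = isTRUE(normalized),
                 ground_cell = ground_cell, ground_tol = ground_tol,
                 densify_spacing = densify_spacing),
            class = "survey_config")
}

#' @export
print.survey_config <- function(x, ...) {
  g <- sample_grid(x)
  cat(sprintf("<survey_config> %s scenario\n",
              if (x$normalized) "normalized" else "non-normalized"))
  cat(sprintf("  observer (%.3f, %.3f, %.3f); rectangle %g m x %g m @ %g m/px\n",
              x$observer$x0, x$observer$y0, x$observer$z0, x$w, x$h, x$resolution))
  cat(sprintf("  azimuth %g..%g step %g deg; distance %g..%g step %g m  (%d samples)\n",
              x$start_angle, x$end_angle, x$angle_step,
              x$distance_step, x$max_distance, x$distance_step, nrow(g)))
  invisible(x)
}

#' Enumerate the polar sample grid
#'
#' The Cartesian product of the azimuths `start_angle, start_angle +
#' angle_step, ..., end_angle` and distances `distance_step, ...,
#' max_distance`, ordered azimuth-major. The default design yields 36
#' directions x 80 distances = 2880 samples.
#'
#' @param config A [survey_config()].
#' @return Data frame with columns `theta` (degrees) and `distance` (metres).
#' @export
sample_grid <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  nt <- floor((config$end_angle - config$start_angle) / config$angle_step + 1e-9)
  thetas <- config$start_angle + config$angle_step * (0:nt)
  nd <- floor(config$max_distance / config$distance_step + 1e-9)
  dists <- config$distance_step * seq_len(nd)
  data.frame(theta = rep(thetas, each = length(dists)),
             distance = rep(dists, times = length(thetas)))
}

# Coverage-aware ground query used by the survey loop: never errors, flags
# queries farther than max_outside beyond the ground hull as invalid.
ground_query <- function(surf, x, y, max_outside = 2) {
  hd <- hull_distance(surf, x, y)
  invalid <- hd$dist > max_outside
  z <- rep(NA_real_, length(x))
  ins <- hd$inside & !invalid
  if (any(ins)) {
    if (sum(ins) <= 4000L) {
      zi <- eval_surface_tin(surf, x[ins], y[ins])
      if (anyNA(zi))
        zi[is.na(zi)] <- eval_surface_grid(surf, x[ins][is.na(zi)], y[ins][is.na(zi)])
      z[ins] <- zi
    } else z[ins] <- eval_surface_grid(surf, x[ins], y[ins])
  }
  out <- !hd$inside & !invalid
  if (any(out) && surf$kind == "tin") {
    nn <- FNN::get.knnx(cbind(surf$gx, surf$gy), cbind(x[out], y[out]),
                        k = 1)$nn.index[, 1]
    z[out] <- surf$gz[nn]
  } else if (any(out)) {
    z[out] <- eval_surface_grid(surf, x[out], y[out])
  }
  list(z = z, invalid = invalid)
}

#' Run a visibility survey
#'
#' For every (theta, i) sample of the polar grid: place the target rectangle,
#' build the projection slab, select candidate points, project them along the
#' line of sight, rasterize, and compute the visibility index. The cloud must
#' already be classified (and normalized when `config$normalized`); use
#' [shield_survey()] for the full pipeline including pretreatment. The ground
#' is densified at `config$densify_spacing` over the sampled circular area
#' before surveying. Samples whose target base falls more than 2 m outside
#' ground coverage are flagged invalid (visibility `NA`) with a warning, and
#' the run continues.
#'
#' @param cloud A classified [point_cloud()].
#' @param config A [survey_config()].
#' @param image_dir Optional directory: writes one PNG occlusion image per
#'   sample, named `theta{theta}_d{i}.png`.
#' @param keep_images If `TRUE`, keep all occlusion images in memory (only
#'   sensible for small grids).
#' @param surface Optional precomputed internal ground surface (pass it when
#'   surveying a pre-densified cloud, so the terrain model is not rebuilt
#'   from the densified ground points).
#' @return A `visibility_survey`: list with `records` (data frame `theta`,
#'   `distance`, `visibility`, `n_occupied`, `n_total`), `config`, and
#'   optionally `images`.
#' @export
run_survey <- function(cloud, config, image_dir = NULL, keep_images = FALSE,
                       surface = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "survey_config"))
  obs <- config$observer
  rx <- range(cloud$x); ry <- range(cloud$y)
  if (obs$x0 < rx[1] || obs$x0 > rx[2] || obs$y0 < ry[1] || obs$y0 > ry[2])
    stop("observer lies outside the planimetric extent of the cloud")
  needs_ground <- !config$normalized || config$densify_spacing > 0
  if (needs_ground && !has_ground_labels(cloud))
    stop("cloud has no ground labels; run classify_ground() first")

  surf <- surface
  if (!config$normalized) {
    if (is.null(surf)) surf <- ground_surface_from_cloud(cloud)
    zg <- ground_query(surf, obs$x0, obs$y0)
    if (!zg$invalid && abs(obs$z0 - zg$z) > 0.5)
      warning(sprintf(
        "observer z0 = %.3f differs from ground elevation %.3f at (x0, y0) by more than 0.5 m",
        obs$z0, zg$z))
  }
  if (config$densify_spacing > 0) {
    cloud <- densify_ground(cloud, config$densify_spacing,
                            region = c(obs$x0, obs$y0,
                                       config$max_distance + config$w))
  }

  grid <- sample_grid(config)
  thetas <- unique(grid$theta)
  dists <- unique(grid$distance)
  nd <- length(dists)

  # target base elevations for the whole grid in one batch
  if (config$normalized) {
    zb <- rep(0, nrow(grid)); invalid <- rep(FALSE, nrow(grid))
  } else {
    a <- grid$theta * pi / 180
    q <- ground_query(surf, obs$x0 + grid$distance * cos(a),
                      obs$y0 + grid$distance * sin(a))
    zb <- q$z; invalid <- q$invalid
    if (any(invalid))
      warning(sum(invalid), " sample(s) beyond ground coverage; recorded as NA")
  }

  w <- config$w; h <- config$h; res <- config$resolution
  vis <- num_occ <- rep(NA_real_, nrow(grid))
  n_total <- px_count(w, res) * px_count(h, res)
  images <- if (keep_images) vector("list", nrow(grid)) else NULL
  if (!is.null(image_dir) && !dir.exists(image_dir))
    dir.create(image_dir, recursive = TRUE)

  for (ti in seq_along(thetas)) {
    theta <- thetas[ti]
    sc <- sight_coords(cloud$x, cloud$y, obs, theta)
    pre <- which(sc$u >= -w / 2 & sc$u <= w / 2 &
                   sc$s > 0 & sc$s < config$max_distance)
    if (config$normalized)
      pre <- pre[cloud$z[pre] >= 0 & cloud$z[pre] <= h]
    s_pre <- sc$s[pre]; u_pre <- sc$u[pre]; z_pre <- cloud$z[pre]
    for (di in seq_len(nd)) {
      k <- (ti - 1L) * nd + di
      if (invalid[k]) next
      i <- dists[di]
      if (config$normalized) {
        sel <- s_pre < i
        v <- z_pre[sel]
      } else {
        tn <- (zb[k] - obs$z0) / i      # tan(Omega)
        zl <- obs$z0 + tn * s_pre
        sel <- s_pre < i & z_pre >= zl & z_pre <= zl + h
        v <- z_pre[sel] + tn * (i - s_pre[sel]) - zb[k]
      }
      img <- rasterize(list(u = u_pre[sel], v = v), w, h, res,
                       theta = theta, i = i)
      rec <- visibility(img)
      vis[k] <- rec$visibility; num_occ[k] <- rec$n_occupied
      if (keep_images) images[[k]] <- img
      if (!is.null(image_dir))
        write_occlusion_image(img, file.path(image_dir,
                                             sprintf("theta%g_d%g.png", theta, i)))
    }
  }
  records <- data.frame(theta = grid$theta, distance = grid$distance,
                        visibility = vis, n_occupied = num_occ,
                        n_total = n_total)
  structure(list(records = records, config = config, images = images),
            class = "visibility_survey")
}

#' Full shielding-effect pipeline
#'
#' Pretreatment plus survey in one call: classify ground points (unless the
#' cloud is already labelled), normalize heights when the scenario asks for
#' it, densify the ground, and run the polar visibility survey. This is the
#' front door of the package.
#'
#' @inheritParams run_survey
#' @param cloud A raw or classified [point_cloud()].
#' @return A `visibility_survey` (see [run_survey()]).
#' @examples
#' sc <- make_scene(scene_spec(extent = 20, terrain = "flat", n_trees = 5, seed = 1))
#' cfg <- survey_config(observer(0, 0, 0), start_angle = 90, end_angle = 90,
#'                      max_distance = 8, distance_step = 2, resolution = 0.05)
#' shield_survey(sc, cfg)
#' @export
shield_survey <- function(cloud, config, image_dir = NULL, keep_images = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "survey_config"))
  if (is.null(cloud$label))
    cloud <- classify_ground(cloud, config$ground_cell, config$ground_tol)
  if (config$normalized)
    cloud <- normalize_heights(cloud)
  run_survey(cloud, config, image_dir = image_dir, keep_images = keep_images)
}

#' @export
print.visibility_survey <- function(x, ...) {
  r <- x$records
  ok <- is.finite(r$visibility)
  cat(sprintf("<visibility_survey> %s scenario: %d samples (%d directions x %d distances)%s\n",
              if (x$config$normalized) "normalized" else "non-normalized",
              nrow(r), length(unique(r$theta)), length(unique(r$distance)),
              if (all(ok)) "" else sprintf(", %d invalid", sum(!ok))))
  if (any(ok))
    cat(sprintf("  visibility: min %.1f%%, median %.1f%%, max %.1f%%\n",
                min(r$visibility[ok]), stats::median(r$visibility[ok]),
                max(r$visibility[ok])))
  invisible(x)
}

#' @export
summary.visibility_survey <- function(object, ...) {
  r <- object$records[is.finite(object$records$visibility), ]
  agg <- do.call(rbind, lapply(split(r, r$theta), function(d) {
    data.frame(theta = d$theta[1], min = min(d$visibility),
               mean = mean(d$visibility), max = max(d$visibility))
  }))
  rownames(agg) <- NULL
  agg
}

#' @export
as.data.frame.visibility_survey <- function(x, ...) x$records

#' @export
plot.visibility_survey <- function(x, ...) {
  r <- x$records[is.finite(x$records$visibility), ]
  if (!nrow(r)) stop("no valid records to plot")
  graphics::plot(NULL, xlim = range(r$distance), ylim = c(0, 100),
                 xlab = "distance (m)", ylab = "visibility (%)",
                 main = sprintf("%s scenario",
                                if (x$config$normalized) "normalized" else "non-normalized"),
                 ...)
  for (th in unique(r$theta)) {
    d <- r[r$theta == th, ]
    graphics::lines(d$distance, d$visibility,
                    col = grDevices::grey(0.2, alpha = 0.35))
  }
  invisible(x)
}
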