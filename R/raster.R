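# Binary occlusion raster and the visibility index.

# Pixel count along one axis: ceil(extent / resolution), robust to floating
# point (an extent that is an exact multiple of the resolution must not gain
# a pixel).
px_count <- function(extent, resolution) {
  r <- extent / resolution
  f <- floor(r + 1e-9)
  as.integer(if (r - f < 1e-9) f else ceiling(r))
}

#' Rasterize projected points into a binary occlusion image
#'
#' The target rectangle is divided into `ceil(w/resolution)` columns and
#' `ceil(h/resolution)` rows (a non-integer ratio yields a partial last band
#' that still counts as a full pixel). A pixel is 1 if at least one projected
#' point falls in its half-open u/v interval, 0 otherwise; each point occupies
#' exactly one pixel (no splatting -- closing ground gaps is the job of
#' [densify_ground()], not the raster). Points with `|u| > w/2` or
#' `v` outside `[0, h)` are discarded. Row 1 is the top edge of the rectangle.
#'
#' @param projected Data frame with `u` and `v` columns (see
#'   [project_points()]); may have zero rows.
#' @param w,h Rectangle width and height in metres.
#' @param resolution Pixel size in metres.
#' @param theta,i Optional provenance of the sample, stored as attributes.
#' @return An `occlusion_image`: integer 0/1 matrix with attributes
#'   `resolution`, `w`, `h`, `theta`, `i`.
#' @examples
#' img <- rasterize(data.frame(u = 0, v = 1), w = 2, h = 2, resolution = 1)
#' visibility(img)
#' @export
rasterize <- function(projected, w, h, resolution, theta = NA_real_, i = NA_real_) {
  if (w <= 0 || h <= 0 || resolution <= 0)
    stop("w, h and resolution must be positive")
  wp <- px_count(w, resolution)
  hp <- px_count(h, resolution)
  m <- matrix(0L, nrow = hp, ncol = wp)
  u <- projected$u; v <- projected$v
  if (length(u)) {
    keep <- u >= -w / 2 & u <= w / 2 & v >= 0 & v < h
    u <- u[keep]; v <- v[keep]
    col <- floor((u + w / 2) / resolution)
    band <- floor(v / resolution)
    ok <- col <= wp - 1L & band <= hp - 1L
    if (any(ok)) m[cbind(hp - band[ok], col[ok] + 1L)] <- 1L
  }
  structure(m, class = "occlusion_image",
            resolution = resolution, w = w, h = h, theta = theta, i = i)
}

#' @export
print.occlusion_image <- function(x, ...) {
  cat(sprintf("<occlusion_image> %d x %d px (%.4g m/px), %d occupied (%.2f%% visible)\n",
              nrow(x), ncol(x), attr(x, "resolution"), sum(unclass(x)),
              (1 - mean(unclass(x))) * 100))
  invisible(x)
}

#' @export
as.matrix.occlusion_image <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Visibility index of an occlusion image
#'
#' `V = (N - n) / N * 100`, the percentage of rectangle pixels not occupied
#' by projected environment points: `N` is the pixel area of the minimum
#' enclosing rectangle and `n` the occupied (occluding) pixel count.
#'
#' @param image An `occlusion_image` from [rasterize()] (any 0/1 matrix works).
#' @return One-row data frame: `theta`, `distance`, `visibility` (percent),
#'   `n_occupied`, `n_total`.
#' @export
visibility <- function(image) {
  m <- unclass(image)
  stopifnot(is.matrix(m))
  n_total <- length(m)
  n_occ <- sum(m != 0L)
  data.frame(theta = attr(image, "theta") %||% NA_real_,
             distance = attr(image, "i") %||% NA_real_,
             visibility = (n_total - n_occ) / n_total * 100,
             n_occupied = n_occ, n_total = n_total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
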