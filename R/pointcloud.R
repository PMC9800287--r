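#' Construct a point cloud
#'
#' The central container of the package: a set of 3D points in metres, with an
#' optional per-point ground classification. Coordinates may be altitudes
#' (terrain-preserving workflows) or heights above ground (after
#' [normalize_heights()]).
#'
#' @param x,y,z Numeric vectors of equal length; coordinates in metres. All
#'   values must be finite.
#' @param label Optional character vector of the same length with values in
#'   `"ground"`, `"non_ground"`, `"unclassified"`, or `NULL` for an entirely
#'   unclassified cloud.
#' @param crs_note Free-text note on the coordinate reference system. The
#'   package never reprojects; this is carried along for provenance only.
#' @return An object of class `point_cloud`: a list with elements `x`, `y`,
#'   `z`, `label` (possibly `NULL`) and `crs_note`.
#' @seealso [read_point_cloud()], [classify_ground()], [make_scene()]
#' @examples
#' pc <- point_cloud(c(0, 1, 2), c(0, 1, 2), c(0, 0, 5))
#' pc
#' @export
point_cloud <- function(x, y, z, label = NULL, crs_note = "") {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (n == 0L)
    stop("empty point cloud: at least one point is required")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("point coordinates must be finite")
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != n)
      stop("label must have the same length as the coordinates")
    bad <- setdiff(unique(label), c("ground", "non_ground", "unclassified"))
    if (length(bad))
      stop("unknown labels: ", paste(bad, collapse = ", "))
  }
  structure(list(x = x, y = y, z = z, label = label,
                 crs_note = as.character(crs_note)[1]),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud A [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  length(cloud$x)
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- length(x$x)
  cat(sprintf("<point_cloud> %d points\n", n))
  cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  if (is.null(x$label)) {
    cat("  labels: none\n")
  } else {
    tb <- table(x$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  if (nzchar(x$crs_note)) cat("  crs:", x$crs_note, "\n")
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  d <- data.frame(x = x$x, y = x$y, z = x$z)
  if (!is.null(x$label)) d$label <- x$label
  d
}

has_ground_labels <- function(cloud) {
  !is.null(cloud$label) && any(cloud$label == "ground")
}

#' Read a point cloud from disk
#'
#' Supported formats: plain XYZ text (whitespace- or comma-delimited `x y z
#' [class]` columns, an optional header line detected by a non-numeric first
#' token), PLY (`ascii` and `binary_little_endian`), and LAS 1.2-1.4 (point
#' record formats 0-5). LAS classification code 2 maps to the `ground` label
#' and any other nonzero code to `non_ground`, following the ASPRS convention;
#' a LAS file whose codes are all 0 ("created, never classified") yields an
#' unclassified cloud. Compressed LAZ is not supported.
#'
#' @param path File to read.
#' @param format One of `"auto"` (by extension), `"xyz"`, `"ply"`, `"las"`.
#' @return A [point_cloud()].
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("0 0 0", "1 1 1", "2 2 2"), f)
#' read_point_cloud(f)
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply", "las", "laz")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read point cloud: file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     las = "las", laz = "laz", ply = "ply",
                     xyz = , txt = , csv = , asc = "xyz",
                     stop("cannot infer point-cloud format from extension '",
                          ext, "'; pass format= explicitly"))
  }
  if (format == "laz")
    stop("LAZ (compressed LAS) is not supported; decompress to LAS first: ", path)
  cloud <- switch(format,
                  xyz = read_xyz(path),
                  ply = read_ply(path),
                  las = read_las(path))
  if (length(cloud$x) == 0L)
    stop("point cloud file contains no points: ", path)
  cloud
}

read_xyz <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("point cloud file contains no points: ", path)
  tok1 <- strsplit(trimws(first), "[,\\s]+", perl = TRUE)[[1]][1]
  skip <- if (is.na(suppressWarnings(as.numeric(tok1)))) 1L else 0L
  dt <- tryCatch(
    data.table::fread(path, skip = skip, header = FALSE, data.table = FALSE),
    error = function(e) stop("cannot parse XYZ text file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) stop("point cloud file contains no points: ", path)
  if (ncol(dt) < 3L) stop("XYZ text file needs at least 3 columns: ", path)
  label <- NULL
  if (ncol(dt) >= 4L) {
    cls <- suppressWarnings(as.integer(dt[[4]]))
    if (!all(is.na(cls)) && !all(cls == 0L, na.rm = TRUE))
      label <- ifelse(cls == 2L, "ground",
                      ifelse(cls == 0L | is.na(cls), "unclassified", "non_ground"))
  }
  point_cloud(dt[[1]], dt[[2]], dt[[3]], label = label)
}

#' Write a point cloud to disk
#'
#' @param cloud A [point_cloud()].
#' @param path Output file; format chosen by extension unless given.
#' @param format One of `"auto"`, `"xyz"`, `"ply"`, `"las"`. XYZ writes
#'   `x y z class` columns (class 2 = ground, 1 = non-ground, 0 =
#'   unclassified); PLY writes binary little-endian doubles; LAS writes
#'   version 1.2, point format 0, with a 0.001 m coordinate scale.
#' @return Invisibly, `path`.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "ply", "las")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, las = "las", ply = "ply",
                     xyz = , txt = , csv = , asc = "xyz",
                     stop("cannot infer output format from extension '", ext, "'"))
  }
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path),
         las = write_las(cloud, path))
  invisible(path)
}

label_codes <- function(cloud) {
  if (is.null(cloud$label)) rep.int(0L, length(cloud$x))
  else ifelse(cloud$label == "ground", 2L,
              ifelse(cloud$label == "non_ground", 1L, 0L))
}

write_xyz <- function(cloud, path) {
  d <- data.frame(x = cloud$x, y = cloud$y, z = cloud$z, class = label_codes(cloud))
  ok <- tryCatch({
    data.table::fwrite(d, path, sep = " ", col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write point cloud to ", path)
}

#' Write a distance-visibility table as CSV
#'
#' One row per survey sample, ordered by azimuth then distance, with columns
#' `theta_deg,distance_m,visibility_pct,n_occupied,n_total`.
#'
#' @param records A `visibility_survey` object from [run_survey()] or a data
#'   frame with columns `theta`, `distance`, `visibility`, `n_occupied`,
#'   `n_total`.
#' @param path Output CSV file.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  d <- as.data.frame(records)
  need <- c("theta", "distance", "visibility", "n_occupied", "n_total")
  if (!all(need %in% names(d)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (nrow(d) == 0L) stop("no records to write")
  d <- d[order(d$theta, d$distance), need]
  names(d) <- c("theta_deg", "distance_m", "visibility_pct", "n_occupied", "n_total")
  ok <- tryCatch({ data.table::fwrite(d, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Read a distance-visibility table written by [write_table()]
#' @param path CSV file.
#' @return Data frame with columns `theta`, `distance`, `visibility`,
#'   `n_occupied`, `n_total`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  d <- data.table::fread(path, data.table = FALSE)
  names(d) <- sub("_deg$|_m$|_pct$", "", names(d))
  d
}

#' Write a binary occlusion image
#'
#' Lossless raster output of an [occlusion image][rasterize]: occupied pixels
#' (value 1) are written as 255, exposed pixels as 0. Row 1 of the matrix is
#' the top edge of the target rectangle. Format by extension: `.png`
#' (via the png package) or `.pgm` (binary P5).
#'
#' @param image An `occlusion_image` from [rasterize()], or any 0/1 matrix.
#' @param path Output file ending in `.png` or `.pgm`.
#' @return Invisibly, `path`.
#' @export
write_occlusion_image <- function(image, path) {
  m <- unclass(image)
  stopifnot(is.matrix(m))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    ok <- tryCatch({ png::writePNG(m * 1.0, target = path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write image to ", path)
  } else if (ext == "pgm") {
    con <- tryCatch(file(path, "wb"), error = function(e) NULL)
    if (is.null(con)) stop("cannot write image to ", path)
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
    writeBin(as.raw(t(m) * 255L), con)
  } else stop("unsupported image extension '", ext, "' (use .png or .pgm)")
  invisible(path)
}

#' Read an occlusion image written by [write_occlusion_image()]
#' @param path A `.png` or `.pgm` file.
#' @return Integer 0/1 matrix, row 1 = top of the rectangle.
#' @export
read_occlusion_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    return(matrix(as.integer(m > 0.5), nrow(m), ncol(m)))
  }
  if (ext == "pgm") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readLines(con, n = 1L)
    if (!identical(magic, "P5")) stop("not a binary PGM file: ", path)
    dims <- scan(con, what = integer(), n = 3L, quiet = TRUE)
    raw <- readBin(con, "raw", n = dims[1] * dims[2])
    return(matrix(as.integer(as.integer(raw) > 127L), dims[2], dims[1], byrow = TRUE))
  }
  stop("unsupported image extension '", ext, "'")
}
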