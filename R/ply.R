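# Minimal PLY reader/writer: ascii and binary_little_endian, element "vertex"
# with scalar properties. A "class"/"classification" vertex property, when
# present, is mapped like the LAS classification codes.

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; elems <- list(); cur <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("PLY header not terminated: ", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.numeric(tok[3]), props = character(),
                           types = character(), has_list = FALSE)
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header: ", path)
      if (tok[2] == "list") {
        elems[[cur]]$has_list <- TRUE
      } else {
        elems[[cur]]$props <- c(elems[[cur]]$props, tok[3])
        elems[[cur]]$types <- c(elems[[cur]]$types, tok[2])
      }
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' (ascii or binary_little_endian): ", path)
  enames <- names(elems)
  if (!"vertex" %in% enames) stop("PLY file has no vertex element: ", path)
  if (match("vertex", enames) != 1L)
    stop("PLY files with elements before 'vertex' are not supported: ", path)
  v <- elems$vertex
  if (v$has_list) stop("list properties on the vertex element are not supported: ", path)
  need <- c("x", "y", "z")
  if (!all(need %in% v$props)) stop("PLY vertex element lacks x/y/z: ", path)
  n <- v$count
  if (n == 0) stop("point cloud file contains no points: ", path)

  if (fmt == "ascii") {
    dat <- matrix(scan(con, what = numeric(), n = n * length(v$props), quiet = TRUE),
                  ncol = length(v$props), byrow = TRUE)
    cols <- dat
  } else {
    sizes <- ply_type_size[v$types]
    if (anyNA(sizes)) stop("unknown PLY property type: ", path)
    stride <- sum(sizes)
    r <- readBin(con, "raw", n = n * stride)
    if (length(r) < n * stride) stop("truncated PLY data: ", path)
    m <- matrix(r, nrow = stride, ncol = n)
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    cols <- matrix(0, nrow = n, ncol = length(v$props))
    for (j in seq_along(v$props)) {
      b <- m[(offs[j] + 1):(offs[j] + sizes[j]), , drop = FALSE]
      ty <- v$types[j]
      cols[, j] <- switch(ty,
        float = , float32 = readBin(as.vector(b), "double", n = n, size = 4, endian = "little"),
        double = , float64 = readBin(as.vector(b), "double", n = n, size = 8, endian = "little"),
        char = , int8 = readBin(as.vector(b), "integer", n = n, size = 1, signed = TRUE),
        uchar = , uint8 = as.numeric(as.integer(b[1, ])),
        short = , int16 = readBin(as.vector(b), "integer", n = n, size = 2,
                                  signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(as.vector(b), "integer", n = n, size = 2,
                                    signed = FALSE, endian = "little"),
        int = , int32 = , uint = , uint32 =
          readBin(as.vector(b), "integer", n = n, size = 4, endian = "little"))
    }
  }
  xi <- match(c("x", "y", "z"), v$props)
  label <- NULL
  ci <- match(c("class", "classification", "scalar_classification"), tolower(v$props))
  ci <- ci[!is.na(ci)][1]
  if (!is.na(ci)) {
    cls <- as.integer(cols[, ci])
    if (any(cls != 0L))
      label <- ifelse(cls == 2L, "ground",
                      ifelse(cls == 0L, "unclassified", "non_ground"))
  }
  point_cloud(cols[, xi[1]], cols[, xi[2]], cols[, xi[3]], label = label)
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- length(cloud$x)
  cls <- label_codes(cloud)
  con <- tryCatch(file(path, "wb"), error = function(e) NULL)
  if (is.null(con)) stop("cannot write PLY file to ", path)
  on.exit(close(con))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           "property uchar class",
           "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    rec <- matrix(as.raw(0L), nrow = 25, ncol = n)
    pack <- function(v) matrix(writeBin(as.numeric(v), raw(), size = 8,
                                        endian = "little"), nrow = 8)
    rec[1:8, ] <- pack(cloud$x)
    rec[9:16, ] <- pack(cloud$y)
    rec[17:24, ] <- pack(cloud$z)
    rec[25, ] <- as.raw(cls)
    writeBin(as.vector(rec), con)
  } else {
    writeLines(sprintf("%.10g %.10g %.10g %d", cloud$x, cloud$y, cloud$z, cls), con)
  }
  invisible(path)
}
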