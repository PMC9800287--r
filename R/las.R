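# Minimal LAS reader/writer.
# Reads LAS 1.2-1.4, point record formats 0-5 (classification byte at offset
# 15, low 5 bits). Writes LAS 1.2, point format 0, 0.001 m coordinate scale.

read_u16 <- function(r, off) {
  readBin(r[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
read_u32 <- function(r, off) {
  v <- readBin(r[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}
read_u64 <- function(r, off) {
  read_u32(r, off) + read_u32(r, off + 4) * 2^32
}
read_f64 <- function(r, off) {
  readBin(r[(off + 1):(off + 8)], "double", size = 8, endian = "little")
}

read_las <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 227 || rawToChar(r[1:4]) != "LASF")
    stop("not a LAS file (missing LASF signature): ", path)
  ver_major <- as.integer(r[25]); ver_minor <- as.integer(r[26])
  if (ver_major != 1L)
    stop("unsupported LAS version ", ver_major, ".", ver_minor, ": ", path)
  offset_points <- read_u32(r, 96)
  fmt <- as.integer(r[105])
  # some writers set the laszip compatibility bit
  if (fmt >= 128L) stop("compressed LAZ payload is not supported: ", path)
  if (fmt > 5L)
    stop("LAS point record format ", fmt, " is not supported (formats 0-5): ", path)
  rec_len <- read_u16(r, 105)
  n <- read_u32(r, 107)
  if (n == 0 && ver_minor >= 4L) n <- read_u64(r, 247)
  if (n == 0) stop("point cloud file contains no points: ", path)
  scale <- c(read_f64(r, 131), read_f64(r, 139), read_f64(r, 147))
  off <- c(read_f64(r, 155), read_f64(r, 163), read_f64(r, 171))

  pts <- r[(offset_points + 1):(offset_points + n * rec_len)]
  if (length(pts) < n * rec_len) stop("truncated LAS point data: ", path)
  m <- matrix(pts, nrow = rec_len, ncol = n)
  int_at <- function(byte0) {
    readBin(as.vector(m[(byte0 + 1):(byte0 + 4), , drop = FALSE]),
            "integer", n = n, size = 4, endian = "little")
  }
  x <- int_at(0) * scale[1] + off[1]
  y <- int_at(4) * scale[2] + off[2]
  z <- int_at(8) * scale[3] + off[3]
  cls <- bitwAnd(as.integer(m[16, ]), 31L)
  label <- NULL
  if (any(cls != 0L))
    label <- ifelse(cls == 2L, "ground", ifelse(cls == 0L, "unclassified", "non_ground"))
  point_cloud(x, y, z, label = label)
}

write_las <- function(cloud, path, scale = 0.001) {
  n <- length(cloud$x)
  off <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  xi <- as.integer(round((cloud$x - off[1]) / scale))
  yi <- as.integer(round((cloud$y - off[2]) / scale))
  zi <- as.integer(round((cloud$z - off[3]) / scale))
  cls <- label_codes(cloud)  # 2 ground, 1 non-ground, 0 unclassified
  # non-ground written as ASPRS 1 (unclassified-but-processed is close enough
  # for round-tripping; the reader maps any nonzero non-2 code to non_ground)
  con <- tryCatch(file(path, "wb"), error = function(e) NULL)
  if (is.null(con)) stop("cannot write LAS file to ", path)
  on.exit(close(con))
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_f64 <- function(v) writeBin(as.numeric(v), con, size = 8, endian = "little")
  pad <- function(k) writeBin(raw(k), con)

  writeChar("LASF", con, eos = NULL)
  w_u16(0); w_u16(0)                    # source id, global encoding
  pad(16)                               # GUID
  writeBin(as.raw(c(1L, 2L)), con)      # version 1.2
  sys_id <- charToRaw(formatC("sightshed", width = 32, flag = "-"))
  writeBin(sys_id, con)
  writeBin(sys_id, con)                 # generating software
  w_u16(1); w_u16(2026)                 # day, year
  w_u16(227)                            # header size
  w_u32(227)                            # offset to point data
  w_u32(0)                              # number of VLRs
  writeBin(as.raw(0L), con)             # point data format 0
  w_u16(20)                             # record length
  w_u32(n)                              # legacy point count
  for (k in 1:5) w_u32(0)               # by return
  w_f64(scale); w_f64(scale); w_f64(scale)
  w_f64(off[1]); w_f64(off[2]); w_f64(off[3])
  w_f64(max(cloud$x)); w_f64(off[1])
  w_f64(max(cloud$y)); w_f64(off[2])
  w_f64(max(cloud$z)); w_f64(off[3])

  # point records, built as a raw matrix for speed
  rec <- matrix(as.raw(0L), nrow = 20, ncol = n)
  pack_i32 <- function(v) matrix(writeBin(v, raw(), size = 4, endian = "little"), nrow = 4)
  rec[1:4, ] <- pack_i32(xi)
  rec[5:8, ] <- pack_i32(yi)
  rec[9:12, ] <- pack_i32(zi)
  rec[16, ] <- as.raw(cls)
  writeBin(as.vector(rec), con)
  invisible(path)
}
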