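ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_type_signed <- c(char = TRUE, int8 = TRUE, uchar = FALSE, uint8 = FALSE,
                     short = TRUE, int16 = TRUE, ushort = FALSE, uint16 = FALSE,
                     int = TRUE, int32 = TRUE, uint = FALSE, uint32 = FALSE,
                     float = TRUE, float32 = TRUE, double = TRUE, float64 = TRUE)

#' Read a point cloud file
#'
#' Reads colored point clouds from PLY (ASCII or binary little-endian),
#' LAS 1.x (point record formats 2/3, RGB), or plain XYZRGB CSV. Colors are
#' rescaled to `[0, 1]` at this boundary: 8-bit channels are divided by 255,
#' 16-bit by 65535; floating-point channels are taken as already scaled.
#' Point order and x,y,z axis order are preserved.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"ply"`, `"las"`,
#'   `"xyzrgb_csv"`.
#' @param plot_id plot identifier; defaults to the file name sans extension.
#' @param centroid_xy plot-centre map coordinate carried on the cloud.
#' @return a [plot_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "las", "xyzrgb_csv"),
                             plot_id = NULL, centroid_xy = c(0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      ply = "ply", las = "las", laz = "laz",
      csv = "xyzrgb_csv", txt = "xyzrgb_csv",
      stop("cannot infer point-cloud format from extension '.", ext,
           "'; pass `format`", call. = FALSE))
  }
  if (format == "laz") {
    stop("LAZ (compressed LAS) is not supported; decompress to .las first",
         call. = FALSE)
  }
  if (is.null(plot_id)) plot_id <- tools::file_path_sans_ext(basename(path))
  switch(format,
    ply = read_ply(path, plot_id, centroid_xy),
    las = read_las(path, plot_id, centroid_xy),
    xyzrgb_csv = read_xyzrgb_csv(path, plot_id, centroid_xy))
}

read_ply <- function(path, plot_id, centroid_xy = c(0, 0)) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(pos) == 0L) {
    stop("not a PLY file (no end_header): ", path, call. = FALSE)
  }
  body_off <- pos[1] + nchar("end_header")
  if (body_off <= length(raw) && raw[body_off] == as.raw(13L)) {
    body_off <- body_off + 1L
  }
  if (body_off <= length(raw) && raw[body_off] == as.raw(10L)) {
    body_off <- body_off + 1L
  }
  hdr <- strsplit(rawToChar(raw[seq_len(pos[1] - 1L)]), "\r?\n")[[1]]
  hdr <- trimws(hdr)
  if (!identical(hdr[1], "ply")) stop("not a PLY file: ", path, call. = FALSE)

  fmt_line <- grep("^format ", hdr, value = TRUE)
  fmt <- strsplit(fmt_line[1], "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }

  # parse element/property declarations
  elements <- list(); cur <- NULL
  for (line in hdr) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(), props = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$list <- TRUE
      } else {
        cur$types <- c(cur$types, tok[2])
        cur$props <- c(cur$props, tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!"vertex" %in% names(elements)) stop("PLY has no vertex element", call. = FALSE)
  if (names(elements)[1] != "vertex") {
    stop("only PLY files with vertex as first element are supported", call. = FALSE)
  }
  el <- elements$vertex
  if (el$count < 1L) stop("empty point cloud: ", path, call. = FALSE)
  need <- c("x", "y", "z")
  colnm <- c("red", "green", "blue")
  for (ch in c(need, colnm)) {
    if (!ch %in% el$props) {
      stop("PLY vertex element is missing channel '", ch, "'", call. = FALSE)
    }
  }

  if (fmt == "ascii") {
    body <- rawToChar(raw[seq.int(body_off, length(raw))])
    rows <- strsplit(trimws(strsplit(body, "\r?\n")[[1]]), "\\s+")
    rows <- rows[lengths(rows) > 0]
    if (length(rows) < el$count) stop("PLY truncated: ", path, call. = FALSE)
    vals <- matrix(as.numeric(unlist(rows[seq_len(el$count)])),
                   nrow = el$count, byrow = TRUE)
    colnames(vals) <- el$props
  } else {
    sizes <- ply_type_size[el$types]
    if (anyNA(sizes)) stop("unknown PLY property type", call. = FALSE)
    rec <- sum(sizes)
    need_bytes <- rec * el$count
    body <- raw[seq.int(body_off, body_off + need_bytes - 1L)]
    recm <- matrix(body, nrow = rec)  # one column per vertex
    off <- cumsum(c(0L, sizes[-length(sizes)]))
    vals <- matrix(0, nrow = el$count, ncol = length(el$props))
    colnames(vals) <- el$props
    for (j in seq_along(el$props)) {
      bytes <- recm[off[j] + seq_len(sizes[j]), , drop = FALSE]
      ty <- el$types[j]
      what <- if (ty %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
      vals[, j] <- readBin(as.vector(bytes), what = what, n = el$count,
                           size = sizes[j], signed = ply_type_signed[ty] || sizes[j] >= 4,
                           endian = "little")
    }
  }

  pts <- vals[, need, drop = FALSE]
  cols <- vals[, colnm, drop = FALSE]
  for (j in seq_len(3)) {
    ty <- el$types[match(colnm[j], el$props)]
    cols[, j] <- rescale_color(cols[, j], ty)
  }
  plot_cloud(pts, cols, plot_id = plot_id, centroid_xy = centroid_xy)
}

rescale_color <- function(v, type) {
  switch(type,
    uchar = , uint8 = , char = , int8 = v / 255,
    ushort = , uint16 = , short = , int16 = v / 65535,
    v)  # float types assumed already in [0,1]
}

#' Write a point cloud to PLY
#'
#' Coordinates are stored as float32, colors as 8-bit `uchar` (the common
#' PLY convention); reading the file back reproduces coordinates to about
#' 1e-6 m and 8-bit colors exactly.
#'
#' @param cloud a [plot_cloud()].
#' @param path output path.
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  stopifnot(inherits(cloud, "plot_cloud"))
  n <- n_points(cloud)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  cols8 <- round(cloud$colors * 255)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    xyz <- writeBin(as.vector(t(cloud$points)), raw(), size = 4, endian = "little")
    xyzm <- matrix(xyz, nrow = 12L)  # 12 bytes of coordinates per vertex
    rgbm <- matrix(as.raw(t(cols8)), nrow = 3L)
    writeBin(as.vector(rbind(xyzm, rgbm)), con)
  } else {
    rows <- paste(format(cloud$points[, 1], trim = TRUE, digits = 9),
                  format(cloud$points[, 2], trim = TRUE, digits = 9),
                  format(cloud$points[, 3], trim = TRUE, digits = 9),
                  cols8[, 1], cols8[, 2], cols8[, 3])
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

read_xyzrgb_csv <- function(path, plot_id, centroid_xy = c(0, 0)) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  need <- c("x", "y", "z")
  if (!all(need %in% names(d))) stop("CSV must have columns x,y,z", call. = FALSE)
  cn <- intersect(c("r", "g", "b", "red", "green", "blue"), names(d))
  if (length(cn) < 3L) {
    miss <- setdiff(c("r", "g", "b"), names(d))
    stop("CSV is missing color channel(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cols <- as.matrix(d[, cn[1:3]])
  if (max(cols) > 1) cols <- cols / 255
  if (nrow(d) < 1L) stop("empty point cloud: ", path, call. = FALSE)
  h <- if ("height" %in% names(d)) as.numeric(d$height) else NULL
  plot_cloud(as.matrix(d[, need]), cols, plot_id = plot_id,
             centroid_xy = centroid_xy, height = h)
}

#' Write a point cloud as XYZRGB CSV
#'
#' Full-precision coordinates and `[0,1]` colors, header `x,y,z,r,g,b`
#' (plus `height` when attached, so processed canopy clouds round-trip).
#' @inheritParams write_ply
#' @return `path`, invisibly.
#' @export
write_xyzrgb_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "plot_cloud"))
  d <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2], z = cloud$points[, 3],
                  r = cloud$colors[, 1], g = cloud$colors[, 2], b = cloud$colors[, 3])
  if (!is.null(cloud$height)) d$height <- cloud$height
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# Minimal LAS 1.2 reader, point record formats 2/3 (xyz + RGB).
read_las <- function(path, plot_id, centroid_xy = c(0, 0)) {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", n = 20))            # source id .. guid
  invisible(readBin(con, "raw", n = 2 + 32 + 32))   # version, sys id, software
  invisible(readBin(con, "raw", n = 4))             # day, year
  invisible(readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")) # header size
  pt_offset <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little")) # n VLRs
  fmt <- as.integer(readBin(con, "raw", n = 1))
  reclen <- readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  npts <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", n = 5, size = 4, endian = "little")) # by return
  sc <- readBin(con, "numeric", n = 3, size = 8, endian = "little")
  of <- readBin(con, "numeric", n = 3, size = 8, endian = "little")
  if (!fmt %in% c(2L, 3L)) {
    stop("LAS point format ", fmt, " has no RGB; formats 2/3 supported", call. = FALSE)
  }
  if (npts < 1L) stop("empty point cloud: ", path, call. = FALSE)
  close(con); on.exit()
  raw <- readBin(path, "raw", n = file.size(path))
  body <- raw[seq.int(pt_offset + 1L, pt_offset + reclen * npts)]
  recm <- matrix(body, nrow = reclen)
  int_at <- function(off, size, signed = TRUE) {
    readBin(as.vector(recm[off + seq_len(size), , drop = FALSE]), "integer",
            n = npts, size = size, signed = signed, endian = "little")
  }
  X <- int_at(0L, 4L); Y <- int_at(4L, 4L); Z <- int_at(8L, 4L)
  rgb_off <- if (fmt == 2L) 20L else 28L
  R <- int_at(rgb_off, 2L, signed = FALSE)
  G <- int_at(rgb_off + 2L, 2L, signed = FALSE)
  B <- int_at(rgb_off + 4L, 2L, signed = FALSE)
  pts <- cbind(X * sc[1] + of[1], Y * sc[2] + of[2], Z * sc[3] + of[3])
  plot_cloud(pts, cbind(R, G, B) / 65535, plot_id = plot_id, centroid_xy = centroid_xy)
}

#' Write a point cloud to LAS 1.2 (point format 2)
#'
#' Coordinates are quantized at `scale` (default 0.1 mm); colors stored as
#' 16-bit RGB.
#' @inheritParams write_ply
#' @param scale coordinate quantization step in metres.
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path, scale = 1e-4) {
  stopifnot(inherits(cloud, "plot_cloud"))
  n <- n_points(cloud)
  off <- apply(cloud$points, 2, min)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("LASF", con, eos = NULL)
  writeBin(rep(as.raw(0), 20), con)                    # source id, encoding, guid
  writeBin(as.raw(c(1, 2)), con)                       # version 1.2
  writeBin(rep(as.raw(0), 64), con)                    # sys id + software
  writeBin(rep(as.raw(0), 4), con)                     # day/year
  writeBin(c(227L), con, size = 2, endian = "little")  # header size
  writeBin(227L, con, size = 4, endian = "little")     # offset to points
  writeBin(0L, con, size = 4, endian = "little")       # no VLRs
  writeBin(as.raw(2), con)                             # point format 2
  writeBin(26L, con, size = 2, endian = "little")      # record length
  writeBin(n, con, size = 4, endian = "little")
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4, endian = "little")
  writeBin(rep(scale, 3), con, size = 8, endian = "little")
  writeBin(as.numeric(off), con, size = 8, endian = "little")
  mx <- apply(cloud$points, 2, max)
  writeBin(as.numeric(rbind(mx, off)), con, size = 8, endian = "little")
  ixyz <- round(sweep(cloud$points, 2, off) / scale)
  i4 <- writeBin(as.integer(t(ixyz)), raw(), size = 4, endian = "little")
  im <- matrix(i4, nrow = 12L)
  mid <- matrix(rep(as.raw(0), 8L * n), nrow = 8L)     # intensity..point source
  rgb <- writeBin(as.integer(t(round(cloud$colors * 65535))), raw(),
                  size = 2, endian = "little")
  rgbm <- matrix(rgb, nrow = 6L)
  writeBin(as.vector(rbind(im, mid, rgbm)), con)
  invisible(path)
}
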