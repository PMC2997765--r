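# Minimal baseline TIFF 6.0 reader/writer (uncompressed grayscale, one
# sample per pixel, multi-page). No TIFF library is available in this R
# environment, so the subset of the format the pipeline needs is implemented
# here: 8/16-bit unsigned pages, strip storage, little- or big-endian on
# read, little-endian single-strip pages on write. Pixel size is stored in
# X/YResolution (pixels per centimetre) and full acquisition metadata in an
# ImageDescription JSON on the first page.

TIFF_TYPE_SIZE <- c(1, 1, 2, 4, 8)  # BYTE, ASCII, SHORT, LONG, RATIONAL

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are rounded and clamped to the unsigned 16-bit range. Voxel
#' size and aspect/channel metadata are preserved: lateral pixel size in the
#' TIFF resolution tags, everything else in an ImageDescription JSON.
#'
#' @param stack a [voxel_stack()], a [lens_projection()] (written as a
#'   single page), or a plain (z, y, x) array / (y, x) matrix.
#' @param path output file path.
#' @param voxel_size length-3 voxel size (z, y, x) in micrometres, used when
#'   `stack` is a plain array.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, voxel_size = c(1, 1, 1)) {
  meta <- list(software = "lenscount")
  if (inherits(stack, "voxel_stack")) {
    a <- stack$intensities
    voxel_size <- stack$voxel_size
    meta <- c(meta, list(voxel_size_um = voxel_size, channel = stack$channel,
                         aspect = stack$aspect, origin_um = stack$origin,
                         z_vals_um = stack$z_vals,
                         view_azimuth = stack$view_azimuth))
  } else if (inherits(stack, "lens_projection")) {
    ps <- attr(stack, "pixel_size")
    voxel_size <- c(1, ps, ps)
    meta <- c(meta, list(voxel_size_um = voxel_size,
                         channel = attr(stack, "channel"),
                         aspect = attr(stack, "aspect"),
                         origin_um = attr(stack, "origin"),
                         view_azimuth = attr(stack, "view_azimuth"),
                         projection = TRUE))
    a <- array(unclass(stack), c(1, nrow(stack), ncol(stack)))
  } else if (is.matrix(stack)) {
    a <- array(stack, c(1, nrow(stack), ncol(stack)))
    meta$voxel_size_um <- voxel_size
  } else {
    a <- stack
    meta$voxel_size_um <- voxel_size
  }
  stopifnot(length(dim(a)) == 3)
  if (max(a) > 65535)
    warning("intensities above 65535 clamped on TIFF write")
  a <- round(pmin(pmax(a, 0), 65535))
  desc <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  d <- dim(a); nz <- d[1]; h <- d[2]; w <- d[3]
  ppcm_x <- 1e4 / voxel_size[3]; ppcm_y <- 1e4 / voxel_size[2]

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  w4(8L)  # offset of the first IFD

  offset <- 8
  entry <- function(tag, type, count, value) c(tag, type, count, value)
  for (p in seq_len(nz)) {
    n_entries <- if (p == 1) 14L else 13L
    ifd_size <- 2 + 12 * n_entries + 4
    res_off <- offset + ifd_size
    desc_off <- res_off + 16
    data_off <- desc_off + if (p == 1) length(desc_raw) else 0
    next_off <- data_off + w * h * 2
    entries <- list(
      entry(256, 4, 1, w), entry(257, 4, 1, h),
      entry(258, 3, 1, 16), entry(259, 3, 1, 1), entry(262, 3, 1, 1))
    if (p == 1)
      entries <- c(entries, list(entry(270, 2, length(desc_raw), desc_off)))
    entries <- c(entries, list(
      entry(273, 4, 1, data_off), entry(277, 3, 1, 1),
      entry(278, 4, 1, h), entry(279, 4, 1, w * h * 2),
      entry(282, 5, 1, res_off), entry(283, 5, 1, res_off + 8),
      entry(296, 3, 1, 3), entry(339, 3, 1, 1)))
    w2(n_entries)
    for (e in entries) {
      w2(e[1]); w2(e[2]); w4(e[3])
      if (e[2] == 3 && e[3] == 1) { w2(e[4]); w2(0L) } else w4(e[4])
    }
    w4(if (p < nz) next_off else 0L)
    # resolution rationals (numerator scaled for precision)
    w4(round(ppcm_x * 1e3)); w4(1000L)
    w4(round(ppcm_y * 1e3)); w4(1000L)
    if (p == 1) writeBin(desc_raw, con)
    # row-major pixel data: row i of the page = a[p, i, ]
    writeBin(as.integer(t(matrix(a[p, , ], h, w))), con, size = 2,
             endian = "little")
    offset <- next_off
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the baseline subset: uncompressed 8- or 16-bit unsigned
#' grayscale, strip storage, either byte order. If the file carries the
#' metadata JSON written by [write_tiff_stack()], a full [voxel_stack()] is
#' reconstructed; otherwise pixel size falls back to the resolution tags
#' (or 1 um).
#'
#' @param path TIFF file path.
#' @param as `"stack"` (default) for a [voxel_stack()], `"projection"` for a
#'   [lens_projection()] (single page), or `"array"` for the raw
#'   (z, y, x) array.
#' @return see `as`.
#' @export
read_tiff_stack <- function(path, as = c("stack", "projection", "array")) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  r2 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                           endian = endian)
  r4 <- function() readBin(con, "integer", 1, size = 4, endian = endian)
  if (r2() != 42) stop("not a TIFF file: ", path)
  ifd_off <- r4()

  read_values <- function(type, count, value_field_pos) {
    size <- TIFF_TYPE_SIZE[type]
    if (size * count <= 4) seek(con, value_field_pos) else {
      seek(con, value_field_pos); seek(con, r4())
    }
    if (type == 2) {
      raw <- readBin(con, "raw", count)
      rawToChar(raw[raw != 0])
    } else if (type == 5) {
      v <- readBin(con, "integer", 2 * count, size = 4, endian = endian)
      v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
    } else {
      readBin(con, "integer", count, size = size, signed = size >= 4,
              endian = endian)
    }
  }

  pages <- list(); desc <- NULL; xres <- NULL
  while (ifd_off > 0) {
    seek(con, ifd_off)
    n <- r2()
    tags <- list()
    for (k in seq_len(n)) {
      pos <- ifd_off + 2 + (k - 1) * 12
      seek(con, pos)
      tag <- r2(); type <- r2(); count <- r4()
      tags[[as.character(tag)]] <- read_values(type, count, pos + 8)
    }
    seek(con, ifd_off + 2 + n * 12)
    ifd_off <- r4()
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]] %||% 1
    if ((tags[["259"]] %||% 1) != 1)
      stop("compressed TIFF is not supported")
    if (!bits %in% c(8, 16)) stop("only 8/16-bit TIFF supported, got ", bits)
    if (is.null(desc)) desc <- tags[["270"]]
    if (is.null(xres)) xres <- tags[["282"]]
    offs <- tags[["273"]]
    counts <- tags[["279"]] %||% (w * h * bits / 8)
    px <- integer(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      px <- c(px, readBin(con, "integer", counts[s] / (bits / 8),
                          size = bits / 8, signed = FALSE, endian = endian))
    }
    pages[[length(pages) + 1]] <- matrix(px, h, w, byrow = TRUE)
  }
  nz <- length(pages)
  a <- array(0, c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (p in seq_len(nz)) a[p, , ] <- pages[[p]]
  meta <- if (!is.null(desc) && grepl("lenscount", desc, fixed = TRUE))
    jsonlite::fromJSON(desc) else NULL
  ps <- if (!is.null(meta)) meta$voxel_size_um[2]
        else if (!is.null(xres) && xres > 0) 1e4 / xres else 1
  if (as == "array") return(a)
  if (as == "projection") {
    if (nz != 1) stop("projection read requested but file has ", nz, " pages")
    return(lens_projection(a[1, , ], ps,
                           origin = meta$origin_um %||% NULL,
                           channel = meta$channel %||% "dna",
                           aspect = meta$aspect %||% "anterior",
                           view_azimuth = meta$view_azimuth %||% 0))
  }
  voxel_stack(a,
              voxel_size = meta$voxel_size_um %||% c(1, ps, ps),
              channel = meta$channel %||% "dna",
              aspect = meta$aspect %||% "anterior",
              origin = meta$origin_um %||% c(0, 0),
              z_vals = meta$z_vals_um %||% NULL,
              view_azimuth = meta$view_azimuth %||% 0)
}
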