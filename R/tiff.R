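# Minimal TIFF codec for microscopy stacks.
#
# Scope: single-channel grayscale, uncompressed, striped; 8/16-bit unsigned
# integer and 32-bit float samples; multi-page; both byte orders on read,
# little-endian on write. Pixel pitches are carried in the X/YResolution
# tags (pixels per centimetre). This is deliberately the smallest subset of
# the format that microscopy stacks need; anything else is rejected with a
# clear message.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, xres = 282L,
               yres = 283L, resolution_unit = 296L, sample_format = 339L)

#' Write a multi-page TIFF
#'
#' @param x a matrix (one page) or nx x ny x n 3D array (n pages); pages are
#'   written row-major (y fastest), so a matrix round-trips exactly
#' @param path output file
#' @param bits 32 (float) or 16/8 (unsigned integer)
#' @param dx,dy pixel pitch in nm, stored in the resolution tags
#' @return `path`, invisibly
#' @export
write_tiff <- function(x, path, bits = 32L, dx = 1, dy = dx) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L, bits %in% c(8L, 16L, 32L))
  nx <- dim(x)[1]; ny <- dim(x)[2]; np <- dim(x)[3]
  bytes_px <- bits / 8L
  page_bytes <- nx * ny * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) { # unsigned 32-bit, wrapped into R's signed integer
    v <- round(v)
    v <- ifelse(v >= 2^31, v - 2^32, v)
    writeBin(as.integer(v), con, size = 4, endian = "little")
  }
  writeBin(charToRaw("II"), con); w16(42L); w32(8L) # header, first IFD at 8

  n_entries <- 14L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  extra_bytes <- 16L # two RATIONALs per page
  pos <- 8L
  for (p in seq_len(np)) {
    ifd_off <- pos
    extra_off <- ifd_off + ifd_bytes
    data_off <- extra_off + extra_bytes
    next_ifd <- if (p < np) data_off + page_bytes else 0L
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count); w32(value)
    }
    w16(n_entries)
    entry(TIFF_TAGS["width"], 3L, 1L, ny)   # columns = image width
    entry(TIFF_TAGS["length"], 3L, 1L, nx)  # rows = image length
    entry(TIFF_TAGS["bits"], 3L, 1L, bits)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L) # black is zero
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_off)
    entry(TIFF_TAGS["samples"], 3L, 1L, 1L)
    entry(TIFF_TAGS["rows_per_strip"], 3L, 1L, nx)
    entry(TIFF_TAGS["strip_bytes"], 4L, 1L, page_bytes)
    entry(TIFF_TAGS["xres"], 5L, 1L, extra_off)
    entry(TIFF_TAGS["yres"], 5L, 1L, extra_off + 8L)
    entry(TIFF_TAGS["resolution_unit"], 3L, 1L, 3L) # centimetre
    entry(TIFF_TAGS["sample_format"], 3L, 1L, if (bits == 32L) 3L else 1L)
    # one spare entry keeps the count honest: software tag (2 = ascii "e\0")
    entry(305L, 2L, 2L, utf8ToInt("e"))
    w32(next_ifd)
    # resolution rationals: pixels per cm = 1e7 / pitch_nm (x100 precision)
    w32(round(1e9 / dy)); w32(100L)
    w32(round(1e9 / dx)); w32(100L)
    page_vec <- as.vector(t(x[, , p])) # scanlines = matrix rows
    if (bits == 32L) {
      writeBin(as.double(page_vec), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(page_vec))
      if (any(v < 0) || any(v >= 2^bits))
        stop("integer TIFF values out of range for ", bits, " bits")
      if (bits == 8L) writeBin(as.raw(v), con)
      else w16_vec(v, con)
    }
    pos <- data_off + page_bytes
  }
  invisible(path)
}

w16_vec <- function(v, con) {
  # writeBin size=2 rejects values >= 2^15 as signed; recode
  v <- as.integer(v)
  v[v >= 32768L] <- v[v >= 32768L] - 65536L
  writeBin(v, con, size = 2, endian = "little")
}

#' Read a multi-page TIFF
#'
#' Supports the subset written by [write_tiff()] (plus big-endian byte order
#' and multi-strip pages). Multi-channel or compressed files are rejected.
#'
#' @param path TIFF file
#' @return nx x ny x n_pages array with attributes `dx_nm`, `dy_nm` when
#'   resolution tags are present
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42L) stop("bad TIFF magic in ", path)
  ifd <- u32(4)
  pages <- list(); dx <- NA_real_; dy <- NA_real_
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        voff = off + 8)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      tsize <- c(1, 1, 2, 4, 8)[t$type]
      inline <- tsize * t$count <= 4
      base <- if (inline) t$voff else u32(t$voff)
      vals <- numeric(t$count)
      for (i in seq_len(t$count)) {
        o <- base + (i - 1) * tsize
        vals[i] <- switch(as.character(t$type),
          "1" = as.integer(raw[o + 1]),
          "3" = u16(o),
          "4" = u32(o),
          "5" = u32(o) / u32(o + 4),
          stop("unsupported TIFF tag type ", t$type))
      }
      vals
    }
    width <- gv(256); height <- gv(257)
    bits <- gv(258, 1L); comp <- gv(259, 1L); spp <- gv(277, 1L)
    fmt <- gv(339, 1L)
    if (comp != 1L) stop("compressed TIFF not supported: ", path)
    if (spp != 1L) stop("multi-channel TIFF not supported (samples/pixel = ",
                        spp, "): ", path)
    offs <- gv(273); counts <- gv(279, width * height * bits / 8)
    xres <- gv(282); yres <- gv(283)
    if (!is.null(xres) && xres > 0) dx <- 1e7 / xres
    if (!is.null(yres) && yres > 0) dy <- 1e7 / yres
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + counts[s])])
    n_px <- width * height
    vals <- if (bits == 32L && fmt == 3L)
      readBin(buf, "double", n_px, size = 4, endian = endian)
    else if (bits == 16L)
      readBin(buf, "integer", n_px, size = 2, signed = FALSE, endian = endian)
    else if (bits == 8L)
      as.integer(buf[seq_len(n_px)])
    else stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt, ")")
    pages[[length(pages) + 1L]] <- t(matrix(vals, width, height)) # to nx x ny
    ifd <- u32(ifd + 2 + n * 12)
  }
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  out <- array(0, dim = c(nx, ny, length(pages)))
  for (p in seq_along(pages)) out[, , p] <- pages[[p]]
  attr(out, "dx_nm") <- dy # x = rows = image length direction
  attr(out, "dy_nm") <- dx
  out
}
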