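# Minimal baseline TIFF I/O for 16-bit grayscale, uncompressed images.
# Implemented in-package because no TIFF-capable R package is available in
# the target runtime; the format subset written here (single-strip,
# little-endian, photometric min-is-black) is readable by any baseline TIFF
# reader, and the reader accepts both byte orders and multi-strip layouts so
# files from standard writers (e.g. Python tifffile) round-trip.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L)

#' Write a 16-bit grayscale TIFF
#'
#' Writes an integer matrix (values 0..65535) as an uncompressed,
#' single-strip, little-endian baseline TIFF. Rows of the matrix map to
#' image scanlines.
#'
#' @param image Numeric matrix; values are rounded and clipped to 0..65535.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff16()]
#' @export
write_tiff16 <- function(image, path) {
  stopifnot(is.matrix(image), is.numeric(image))
  v <- as.vector(t(image))          # row-major scanlines
  v <- pmin(pmax(round(v), 0), 65535)
  h <- nrow(image); w <- ncol(image)
  nbytes <- length(v) * 2L
  data_offset <- 8L
  ifd_offset <- data_offset + nbytes
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data: unsigned 16-bit, written via signed representation
  vs <- as.integer(ifelse(v > 32767, v - 65536, v))
  writeBin(vs, con, size = 2, endian = "little")
  if (ifd_offset > data_offset + nbytes) writeBin(0L, con, size = 1)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(.tiff_types[[type]], con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == "SHORT") {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tags <- list( # must be in ascending tag order
    list(256L, "LONG",  w),           # ImageWidth
    list(257L, "LONG",  h),           # ImageLength
    list(258L, "SHORT", 16L),         # BitsPerSample
    list(259L, "SHORT", 1L),          # Compression: none
    list(262L, "SHORT", 1L),          # Photometric: min-is-black
    list(273L, "LONG",  data_offset), # StripOffsets
    list(277L, "SHORT", 1L),          # SamplesPerPixel
    list(278L, "LONG",  h),           # RowsPerStrip
    list(279L, "LONG",  nbytes)       # StripByteCounts
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (t in tags) entry(t[[1]], t[[2]], 1L, t[[3]])
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

.read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_along(b) - 1))
}

#' Read a 16-bit grayscale TIFF
#'
#' Reads the first image of an uncompressed grayscale TIFF with 16 bits per
#' sample, either byte order, one or more strips. Compressed, tiled, paletted
#' or multi-sample files are rejected with a descriptive error.
#'
#' @param path Path to a TIFF file.
#' @return Integer matrix (rows = scanlines) with values 0..65535.
#' @export
read_tiff16 <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (.read_uint(raw, 2, 2, endian) != 42) stop("not a TIFF file (bad magic): ", path)
  ifd <- .read_uint(raw, 4, 4, endian)
  n_entries <- .read_uint(raw, ifd, 2, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- .read_uint(raw, off, 2, endian)
    type <- .read_uint(raw, off + 2, 2, endian)
    count <- .read_uint(raw, off + 4, 4, endian)
    tsize <- .tiff_type_size[type]
    total <- tsize * count
    voff <- if (total <= 4) off + 8 else .read_uint(raw, off + 8, 4, endian)
    vals <- if (type %in% c(3L, 4L)) {
      vapply(seq_len(count) - 1L,
             function(j) .read_uint(raw, voff + j * tsize, tsize, endian),
             numeric(1))
    } else NULL
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  w <- g(256); h <- g(257)
  if (is.null(w) || is.null(h)) stop("TIFF missing image dimensions: ", path)
  if (!identical(as.integer(g(259, 1)), 1L)) stop("unsupported TIFF: compressed data in ", path)
  bits <- g(258, 1)
  if (any(bits != 16)) stop("unsupported TIFF: expected 16 bits per sample in ", path)
  if (!identical(as.integer(g(277, 1)), 1L)) stop("unsupported TIFF: multi-sample image in ", path)
  strip_offsets <- g(273)
  strip_counts <- g(279)
  if (is.null(strip_offsets) || is.null(strip_counts)) {
    stop("unsupported TIFF: missing strip layout in ", path)
  }
  vals <- unlist(lapply(seq_along(strip_offsets), function(i) {
    o <- strip_offsets[i]; nb <- strip_counts[i]
    b <- raw[(o + 1):(o + nb)]
    readBin(b, "integer", n = nb / 2, size = 2, signed = FALSE, endian = endian)
  }))
  if (length(vals) != w * h) stop("TIFF pixel payload does not match dimensions in ", path)
  matrix(as.integer(vals), nrow = h, ncol = w, byrow = TRUE)
}
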