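# Minimal baseline TIFF codec for single-channel 16-bit grayscale images.
# Only what the pipeline needs: little-endian, uncompressed, one sample per
# pixel. No installed R package reads or writes TIFF in this toolchain, so the
# codec is part of the package; round-trips are tested against an independent
# reader.

#' Write a 16-bit grayscale TIFF
#'
#' Writes an integer matrix (values in 0..65535) as an uncompressed
#' little-endian baseline TIFF with one strip. Row `i`, column `j` of the
#' matrix maps to image row `i`, column `j`.
#'
#' @param img integer matrix with values in `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff16()]
#' @export
write_tiff16 <- function(img, path) {
  if (!is_uint16(img)) {
    stop("`img` must be an integer-valued matrix in [0, 65535]", call. = FALSE)
  }
  nr <- nrow(img)
  nc <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)          # little-endian byte order
  w2(42L)                                  # TIFF magic
  w4(8L)                                   # offset of first IFD
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_offset <- 8L + ifd_size
  w2(n_entries)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  entry(256L, 3L, 1L, nc)                  # ImageWidth
  entry(257L, 3L, 1L, nr)                  # ImageLength
  entry(258L, 3L, 1L, 16L)                 # BitsPerSample
  entry(259L, 3L, 1L, 1L)                  # Compression = none
  entry(262L, 3L, 1L, 1L)                  # Photometric = BlackIsZero
  entry(273L, 4L, 1L, data_offset)         # StripOffsets
  entry(278L, 3L, 1L, nr)                  # RowsPerStrip
  entry(279L, 4L, 1L, 2L * nr * nc)        # StripByteCounts
  w4(0L)                                   # no further IFD
  # pixel payload, row-major, unsigned 16-bit little-endian
  v <- as.integer(t(img))
  payload <- raw(2L * length(v))
  payload[seq(1L, length(payload), by = 2L)] <- as.raw(bitwAnd(v, 255L))
  payload[seq(2L, length(payload), by = 2L)] <- as.raw(bitwShiftR(v, 8L))
  writeBin(payload, con)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF
#'
#' Reads uncompressed single-channel 16-bit grayscale TIFF files (either byte
#' order, any strip layout). Anything else - compressed, tiled, multi-sample,
#' or non-16-bit data - is rejected with an error rather than misread.
#'
#' @param path file path.
#' @return integer matrix of pixel values.
#' @seealso [write_tiff16()]
#' @export
read_tiff16 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path, call. = FALSE)
  rd <- function(offset, size, n = 1L) {
    # sizes 1-2 are read unsigned; 4-byte values in these files are < 2^31
    readBin(raw_all[(offset + 1L):(offset + size * n)], "integer",
            n = n, size = size, endian = endian, signed = size > 2L)
  }
  if (rd(2L, 2L) != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd <- rd(4L, 4L)
  n_entries <- rd(ifd, 2L)
  tags <- list()
  type_sizes <- c(1L, 1L, 2L, 4L, 8L)
  for (i in seq_len(n_entries)) {
    base <- ifd + 2L + (i - 1L) * 12L
    tag <- rd(base, 2L)
    type <- rd(base + 2L, 2L)
    count <- rd(base + 4L, 4L)
    size <- if (type <= 5L) type_sizes[type] else 1L
    value_size <- if (type %in% c(3L, 4L)) size else NA_integer_
    if (is.na(value_size)) next
    if (count * value_size <= 4L) {
      vals <- rd(base + 8L, value_size, count)
    } else {
      vals <- rd(rd(base + 8L, 4L), value_size, count)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, call. = FALSE)
      default
    } else v
  }
  nc <- need(256L)
  nr <- need(257L)
  bits <- need(258L, 1L)
  if (!all(bits == 16L)) stop("only 16-bit TIFF supported", call. = FALSE)
  if (need(259L, 1L) != 1L) stop("only uncompressed TIFF supported", call. = FALSE)
  if (need(277L, 1L) != 1L) stop("only single-channel TIFF supported", call. = FALSE)
  offsets <- need(273L)
  counts <- need(279L, 2L * nr * nc)
  payload <- raw(0)
  for (i in seq_along(offsets)) {
    payload <- c(payload, raw_all[(offsets[i] + 1L):(offsets[i] + counts[i])])
  }
  v <- readBin(payload, "integer", n = nr * nc, size = 2L,
               endian = endian, signed = FALSE)
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}
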