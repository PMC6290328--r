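# Minimal baseline TIFF codec.
#
# No TIFF reader/writer is available among the package's allowed
# dependencies, so volume I/O is backed by this small implementation of the
# baseline subset the pipeline needs: little-endian, uncompressed, striped,
# single-sample grayscale pages with uint8/uint16/float32 samples and an
# optional ImageDescription. This covers the files the package writes plus
# plain exported microscopy TIFFs; compressed or tiled files are rejected
# with a clear error.

TIFF_TYPES <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L)

tiff_dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(bits = 8L,  bytes = 1L, format = 1L),
    uint16  = list(bits = 16L, bytes = 2L, format = 1L),
    float32 = list(bits = 32L, bytes = 4L, format = 3L),
    stopf("unsupported TIFF dtype '%s'", dtype))
}

## ---- writing --------------------------------------------------------------

u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32_raw <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  c(u16_raw(lo), u16_raw(hi))
}

tiff_entry <- function(tag, type, count, value_raw4) {
  stopifnot(length(value_raw4) == 4)
  c(u16_raw(tag), u16_raw(type), u32_raw(count), value_raw4)
}

entry_short <- function(tag, value) tiff_entry(tag, TIFF_TYPES["SHORT"], 1, c(u16_raw(value), as.raw(c(0, 0))))
entry_long  <- function(tag, value) tiff_entry(tag, TIFF_TYPES["LONG"], 1, u32_raw(value))

page_pixels_raw <- function(m, dtype) {
  v <- as.vector(t(m))            # TIFF is row-major
  if (dtype == "float32") return(writeBin(as.numeric(v), raw(), size = 4, endian = "little"))
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0))
    stopf("integer TIFF pages cannot hold negative or non-finite values")
  v <- round(v)
  if (dtype == "uint8") {
    if (any(v > 255)) stopf("uint8 TIFF page overflow")
    return(as.raw(v))
  }
  if (any(v > 65535)) stopf("uint16 TIFF page overflow")
  v[v > 32767] <- v[v > 32767] - 65536
  writeBin(as.integer(v), raw(), size = 2, endian = "little")
}

#' Write a multi-page grayscale TIFF
#'
#' @param path output file path.
#' @param pages list of numeric matrices, all with identical dimensions.
#' @param dtype one of `"uint8"`, `"uint16"`, `"float32"`.
#' @param description optional character scalar stored as ImageDescription of
#'   the first page (the volume I/O layer stores its sidecar JSON here too).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, dtype = "uint16", description = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) stopf("no pages to write")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all TIFF pages must share one shape")
  ny <- dims[1, 1]; nx <- dims[2, 1]
  info <- tiff_dtype_info(dtype)
  npages <- length(pages)
  pagesize <- as.numeric(ny) * nx * info$bytes

  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0)) else raw(0)
  data_off <- 8 + pagesize * (seq_len(npages) - 1)
  desc_off <- 8 + pagesize * npages
  ifd0_off <- desc_off + length(desc_raw)
  n_entries <- function(i) if (i == 1 && length(desc_raw)) 11L else 10L
  ifd_size <- function(i) 2 + 12 * n_entries(i) + 4
  ifd_off <- ifd0_off + c(0, cumsum(vapply(seq_len(npages), ifd_size, numeric(1))))[seq_len(npages)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16_raw(42), con)
  writeBin(u32_raw(ifd_off[1]), con)
  for (i in seq_len(npages)) writeBin(page_pixels_raw(pages[[i]], dtype), con)
  if (length(desc_raw)) writeBin(desc_raw, con)
  for (i in seq_len(npages)) {
    entries <- list(
      entry_long(256, nx),                 # ImageWidth
      entry_long(257, ny),                 # ImageLength
      entry_short(258, info$bits),         # BitsPerSample
      entry_short(259, 1),                 # Compression: none
      entry_short(262, 1))                 # Photometric: BlackIsZero
    if (i == 1 && length(desc_raw))
      entries <- c(entries, list(tiff_entry(270, TIFF_TYPES["ASCII"],
                                            length(desc_raw), u32_raw(desc_off))))
    entries <- c(entries, list(
      entry_long(273, data_off[i]),        # StripOffsets
      entry_short(277, 1),                 # SamplesPerPixel
      entry_long(278, ny),                 # RowsPerStrip
      entry_long(279, pagesize),           # StripByteCounts
      entry_short(339, info$format)))      # SampleFormat
    writeBin(u16_raw(length(entries)), con)
    for (e in entries) writeBin(e, con)
    nxt <- if (i < npages) ifd_off[i + 1] else 0
    writeBin(u32_raw(nxt), con)
  }
  invisible(path)
}

## ---- reading --------------------------------------------------------------

rd_u16 <- function(bytes, off, n = 1) {
  readBin(bytes[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
          signed = FALSE, endian = "little")
}
rd_u32 <- function(bytes, off, n = 1) {
  v <- readBin(bytes[(off + 1):(off + 4 * n)], "integer", n = n, size = 4,
               endian = "little")
  v <- as.numeric(v)
  v[v < 0] <- v[v < 0] + 2^32
  v
}

read_tag_values <- function(bytes, off) {
  tag <- rd_u16(bytes, off)
  type <- rd_u16(bytes, off + 2)
  count <- rd_u32(bytes, off + 4)
  elt_size <- c(1, 1, 2, 4)[type]
  if (is.na(elt_size)) return(NULL)
  total <- elt_size * count
  voff <- if (total <= 4) off + 8 else rd_u32(bytes, off + 8)
  values <- switch(as.character(type),
    `1` = as.integer(bytes[(voff + 1):(voff + count)]),
    `2` = rawToChar(bytes[(voff + 1):(voff + count - 1)]),
    `3` = rd_u16(bytes, voff, count),
    `4` = rd_u32(bytes, voff, count))
  list(tag = tag, values = values)
}

#' Read a multi-page grayscale TIFF
#'
#' Accepts the baseline subset written by [write_tiff()]: little-endian,
#' uncompressed, single-sample pages.
#'
#' @param path file path.
#' @return list with elements `pages` (list of numeric matrices) and
#'   `description` (ImageDescription string or `NULL`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8 || rawToChar(bytes[1:2]) != "II" || rd_u16(bytes, 2) != 42)
    stopf("'%s' is not a little-endian TIFF", path)
  ifd_off <- rd_u32(bytes, 4)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n <- rd_u16(bytes, ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      tv <- read_tag_values(bytes, ifd_off + 2 + 12 * (i - 1))
      if (!is.null(tv)) tags[[as.character(tv$tag)]] <- tv$values
    }
    ifd_off <- rd_u32(bytes, ifd_off + 2 + 12 * n)
    nx <- tags[["256"]]; ny <- tags[["257"]]
    bits <- tags[["258"]] %||% 8L
    comp <- tags[["259"]] %||% 1L
    fmt <- tags[["339"]] %||% 1L
    spp <- tags[["277"]] %||% 1L
    if (comp != 1) stopf("compressed TIFF not supported (compression=%d)", comp)
    if (spp != 1) stopf("multi-sample TIFF pages not supported")
    if (!is.null(tags[["270"]]) && is.null(description)) description <- tags[["270"]]
    offs <- tags[["273"]]; counts <- tags[["279"]]
    data <- raw(0)
    for (k in seq_along(offs))
      data <- c(data, bytes[(offs[k] + 1):(offs[k] + counts[k])])
    vals <- if (fmt == 3 && bits == 32) {
      readBin(data, "numeric", n = nx * ny, size = 4, endian = "little")
    } else if (bits == 16) {
      readBin(data, "integer", n = nx * ny, size = 2, signed = FALSE, endian = "little")
    } else if (bits == 8) {
      as.integer(data[seq_len(nx * ny)])
    } else stopf("unsupported TIFF sample: %d bits, format %d", bits, fmt)
    pages[[length(pages) + 1]] <- matrix(as.numeric(vals), nrow = ny, ncol = nx,
                                         byrow = TRUE)
  }
  list(pages = pages, description = description)
}
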