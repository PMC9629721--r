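# Shared I/O: greyscale TIFF/PNG images, load-trace CSV, JSON reports.
# Images are numeric matrices; on disk they are 8- or 16-bit integers.
# The TIFF codec is deliberately minimal (single-plane, uncompressed) —
# no TIFF package is available in the supported stack.

#' Read a greyscale image
#'
#' Supports uncompressed greyscale TIFF (8/16-bit) and PNG (8/16-bit,
#' greyscale or RGB). Multi-channel images are reduced to their first
#' channel with a warning. Intensities are preserved losslessly as
#' integers.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return a list with `image` (integer-valued numeric matrix), `bits`,
#'   `max_value` and `path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  magic <- readBin(path, "raw", 8)
  if (length(magic) >= 4 &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    return(read_tiff(path))
  }
  if (length(magic) >= 8 &&
      identical(magic[1:8],
                as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    return(read_png_grey(path))
  }
  stop("unsupported image format (expected TIFF or PNG): ", path,
       call. = FALSE)
}

read_png_grey <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  bits <- as.integer(raw[25])  # IHDR bit depth byte
  a <- png::readPNG(raw)
  if (length(dim(a)) == 3L) {
    warning("multi-channel PNG: using first channel", call. = FALSE)
    a <- a[, , 1]
  }
  mx <- 2^bits - 1
  list(image = round(a * mx), bits = bits, max_value = mx, path = path)
}

#' Write a greyscale image
#'
#' Scales a [0, 1] (or integer-valued) matrix to the requested bit depth
#' and writes TIFF (via the built-in uncompressed codec) or PNG by file
#' extension.
#'
#' @param image numeric matrix; values in [0, 1] are scaled to the full
#'   integer range, values > 1 are treated as already-integer intensities.
#' @param path output path ending in .tif/.tiff/.png.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16) {
  check_image(image)
  stopifnot(bits %in% c(8, 16))
  mx <- 2^bits - 1
  vals <- if (max(image) <= 1) round(image * mx) else round(image)
  if (min(vals) < 0 || max(vals) > mx) {
    stop("intensities out of range for ", bits, "-bit output", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff(vals, path, bits = bits)
  } else if (ext == "png") {
    png::writePNG(vals / mx, path)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

# --- minimal uncompressed greyscale TIFF codec ------------------------------

write_tiff <- function(vals, path, bits = 16) {
  h <- nrow(vals); w <- ncol(vals)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)           # II, 42
  writeBin(as.integer(8L), con, size = 4, endian = "little")  # IFD offset
  tags <- list(
    c(256L, 3L, 1L, w),            # ImageWidth
    c(257L, 3L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, bits),         # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression: none
    c(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 1L, 0L),           # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 3L, 1L, h),            # RowsPerStrip
    c(279L, 4L, 1L, h * w * bits / 8)  # StripByteCounts
  )
  n_tags <- length(tags)
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  tags[[6]][4] <- data_offset
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    if (tg[2] == 3L) {  # SHORT value, left-justified in 4 bytes
      writeBin(as.integer(tg[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  px <- as.integer(t(vals))  # row-major
  writeBin(px, con, size = bits / 8, endian = "little")
  invisible(path)
}

read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  le <- identical(raw[1:2], as.raw(c(0x49, 0x49)))
  endian <- if (le) "little" else "big"
  rd <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  ifd <- rd(4, 4)
  n_tags <- rd(ifd, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2 + (i - 1) * 12
    id <- rd(base, 2, signed = FALSE)
    typ <- rd(base + 2, 2, signed = FALSE)
    cnt <- rd(base + 4, 4)
    val <- if (typ == 3L) {
      if (cnt == 1L) rd(base + 8, 2, signed = FALSE)
      else if (cnt == 2L) rd(base + 8, 2, n = 2, signed = FALSE)
      else rd(rd(base + 8, 4), 2, n = cnt, signed = FALSE)
    } else {
      if (cnt == 1L) rd(base + 8, 4)
      else rd(rd(base + 8, 4), 4, n = cnt)
    }
    tags[[as.character(id)]] <- val
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", id, " missing", call. = FALSE)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8L)[1]
  comp <- need(259, 1L)
  spp <- need(277, 1L)
  if (comp != 1L) {
    stop("unsupported TIFF: compressed (only uncompressed supported)",
         call. = FALSE)
  }
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported TIFF bit depth: ", bits, call. = FALSE)
  }
  offsets <- need(273)
  counts <- need(279, h * w * spp * bits / 8)
  bytes <- raw(0)
  for (i in seq_along(offsets)) {
    bytes <- c(bytes, raw[(offsets[i] + 1):(offsets[i] + counts[i])])
  }
  px <- readBin(bytes, "integer", n = length(bytes) / (bits / 8),
                size = bits / 8, endian = endian, signed = FALSE)
  if (spp > 1L) {
    warning("multi-channel TIFF: using first channel", call. = FALSE)
    px <- px[seq(1, length(px), by = spp)]
  }
  img <- matrix(as.double(px), nrow = h, ncol = w, byrow = TRUE)
  list(image = img, bits = bits, max_value = 2^bits - 1, path = path)
}

# --- traces, tables, reports ------------------------------------------------

#' Write / read a load trace CSV
#'
#' Column contract: `time_s, force_N, displacement_mm, phase` with phase in
#' {loading, unloading, hold}.
#'
#' @param trace a load-trace data frame.
#' @param path CSV path.
#' @return the path (write) or the trace data frame (read).
#' @export
write_trace_csv <- function(trace, path) {
  req <- c("time_s", "force_N", "displacement_mm", "phase")
  stopifnot(all(req %in% names(trace)))
  utils::write.csv(trace[, req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time_s", "force_N", "displacement_mm"), names(tr))
  if (length(miss)) {
    stop("trace CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
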