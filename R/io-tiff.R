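# Minimal multi-page 32-bit-float TIFF support.
#
# No R TIFF package is available in the target environment, so the package
# carries its own reader/writer for the single layout it produces:
# little-endian baseline TIFF, one page per frame, uncompressed IEEE
# float32 samples, one strip per page. The reader validates every field it
# relies on and refuses anything else.

tiff_types <- c(SHORT = 3L, LONG = 4L)

write_ifd_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == tiff_types[["SHORT"]]) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a multi-frame float32 TIFF
#'
#' One page per frame, uncompressed little-endian IEEE float32, ADU values
#' stored without quantization. Rows are y (slowest), columns x.
#'
#' @param w N x P matrix (P = npix^2, pixel index x-fastest) or an
#'   `spt_image_stack`.
#' @param path Output file path.
#' @param npix Pixels per side (taken from the stack if one is given).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(w, path, npix = NULL) {
  if (inherits(w, "spt_image_stack")) {
    npix <- w$npix
    w <- w$w
  }
  stopifnot(is.matrix(w), !is.null(npix))
  npix <- as.integer(npix)
  if (ncol(w) != npix * npix) stop_invalid("w must have npix^2 columns")
  n <- nrow(w)
  page_bytes <- npix * npix * 4L
  n_entries <- 10L
  ifd_bytes <- 2L + 12L * n_entries + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  first_ifd <- 8L + page_bytes
  writeBin(first_ifd, con, size = 4, endian = "little")
  for (i in seq_len(n)) {
    data_off <- 8L + (i - 1L) * (page_bytes + ifd_bytes)
    writeBin(as.numeric(w[i, ]), con, size = 4, endian = "little")
    writeBin(n_entries, con, size = 2, endian = "little")
    write_ifd_entry(con, 256, 3, 1, npix)              # ImageWidth
    write_ifd_entry(con, 257, 3, 1, npix)              # ImageLength
    write_ifd_entry(con, 258, 3, 1, 32)                # BitsPerSample
    write_ifd_entry(con, 259, 3, 1, 1)                 # no compression
    write_ifd_entry(con, 262, 3, 1, 1)                 # BlackIsZero
    write_ifd_entry(con, 273, 4, 1, data_off)          # StripOffsets
    write_ifd_entry(con, 277, 3, 1, 1)                 # SamplesPerPixel
    write_ifd_entry(con, 278, 3, 1, npix)              # RowsPerStrip
    write_ifd_entry(con, 279, 4, 1, page_bytes)        # StripByteCounts
    write_ifd_entry(con, 339, 3, 1, 3)                 # IEEE float
    # the next page's IFD sits after that page's pixel data
    next_ifd <- if (i < n) data_off + 2L * page_bytes + ifd_bytes else 0L
    writeBin(next_ifd, con, size = 4, endian = "little")
  }
  invisible(path)
}

read_uint <- function(raw, offset, size) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a multi-frame float32 TIFF written by [write_tiff()]
#'
#' @param path TIFF file path.
#' @return List with `w` (N x P matrix of ADU) and `npix`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || read_uint(raw, 2, 2) != 42) {
    stop_invalid("not a little-endian TIFF: %s", path)
  }
  ifd_off <- read_uint(raw, 4, 4)
  pages <- list()
  npix <- NULL
  while (ifd_off != 0) {
    n_entries <- read_uint(raw, ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- read_uint(raw, base, 2)
      type <- read_uint(raw, base + 2, 2)
      val <- read_uint(raw, base + 8, if (type == 3) 2 else 4)
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "258", "259", "262", "273", "279", "339")
    if (!all(need %in% names(tags))) {
      stop_invalid("TIFF page missing required fields")
    }
    if (tags[["258"]] != 32 || tags[["259"]] != 1 || tags[["339"]] != 3) {
      stop_invalid("unsupported TIFF layout (need uncompressed float32)")
    }
    wpx <- tags[["256"]]; hpx <- tags[["257"]]
    if (wpx != hpx) stop_invalid("only square pages supported")
    if (is.null(npix)) npix <- wpx
    if (wpx != npix) stop_invalid("inconsistent page sizes")
    off <- tags[["273"]]
    nb <- tags[["279"]]
    if (nb != wpx * hpx * 4) stop_invalid("unexpected strip size")
    vals <- readBin(raw[(off + 1):(off + nb)], "numeric", n = wpx * hpx,
                    size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- vals
    ifd_off <- read_uint(raw, ifd_off + 2 + n_entries * 12, 4)
  }
  list(w = do.call(rbind, pages), npix = npix)
}
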