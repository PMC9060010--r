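# Minimal multipage TIFF codec (uncompressed, little-endian writer; reader
# accepts either byte order). No R TIFF package is available in the target
# environment, so the subset of baseline TIFF needed for microscopy stacks is
# implemented here: grayscale pages, 8/16-bit unsigned or 64-bit float
# samples, arbitrary strip layout on read, one strip per page on write.
# Stack metadata (axes order, spacing, channel roles, depth origin) is
# embedded as JSON in the ImageDescription tag of the first page, the same
# place Python's tifffile puts its shape metadata.

TAG_WIDTH <- 256L; TAG_HEIGHT <- 257L; TAG_BITS <- 258L
TAG_COMPRESSION <- 259L; TAG_PHOTOMETRIC <- 262L; TAG_DESCRIPTION <- 270L
TAG_STRIP_OFFSETS <- 273L; TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_BYTECOUNTS <- 279L; TAG_SAMPLE_FORMAT <- 339L

write_uint <- function(con, x, size) {
  # writeBin has no unsigned types; values stay below 2^31 here
  writeBin(as.integer(x), con, size = size, endian = "little")
}

# pages: list of y-by-x numeric matrices; desc: character scalar or NULL
write_tiff_pages <- function(path, pages, bits, sample_format, desc = NULL) {
  npages <- length(pages)
  stopifnot(npages >= 1)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  bytes_per <- bits / 8L
  page_bytes <- as.integer(w * h * bytes_per)
  desc_raw <- if (!is.null(desc)) c(charToRaw(desc), as.raw(0L)) else raw(0)
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  ntags1 <- if (length(desc_raw)) 10L else 9L
  ntags <- 9L
  data_off <- 8L
  desc_off <- data_off + npages * page_bytes
  ifd_off <- integer(npages)
  ifd_off[1] <- desc_off + length(desc_raw)
  if (npages > 1) {
    sz1 <- 2L + ntags1 * 12L + 4L
    szn <- 2L + ntags * 12L + 4L
    for (i in 2:npages) ifd_off[i] <- ifd_off[1] + sz1 + (i - 2L) * szn
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_uint(con, 42L, 2L)
  write_uint(con, ifd_off[1], 4L)
  for (p in pages) {
    # TIFF pages are row-major (x fastest); our matrices are (y, x)
    v <- as.vector(t(p))
    if (sample_format == 3L) {
      writeBin(as.double(v), con, size = bytes_per, endian = "little")
    } else if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else {
      v <- as.integer(round(v))
      over <- v > 32767L # writeBin size=2 is signed; re-encode upper half
      v[over] <- v[over] - 65536L
      writeBin(v, con, size = 2L, endian = "little")
    }
  }
  if (length(desc_raw)) writeBin(desc_raw, con)

  tag <- function(id, type, count, value, value_is_offset = FALSE) {
    write_uint(con, id, 2L)
    write_uint(con, type, 2L)
    write_uint(con, count, 4L)
    if (type == 3L && !value_is_offset) { # SHORT inline
      write_uint(con, value, 2L); write_uint(con, 0L, 2L)
    } else {
      write_uint(con, value, 4L)
    }
  }
  for (i in seq_len(npages)) {
    has_desc <- i == 1L && length(desc_raw) > 0L
    write_uint(con, if (has_desc) ntags1 else ntags, 2L)
    tag(TAG_WIDTH, 4L, 1L, w)
    tag(TAG_HEIGHT, 4L, 1L, h)
    tag(TAG_BITS, 3L, 1L, bits)
    tag(TAG_COMPRESSION, 3L, 1L, 1L)
    tag(TAG_PHOTOMETRIC, 3L, 1L, 1L)
    if (has_desc)
      tag(TAG_DESCRIPTION, 2L, length(desc_raw), desc_off, TRUE)
    tag(TAG_STRIP_OFFSETS, 4L, 1L, data_off + (i - 1L) * page_bytes)
    tag(TAG_ROWS_PER_STRIP, 4L, 1L, h)
    tag(TAG_STRIP_BYTECOUNTS, 4L, 1L, page_bytes)
    tag(TAG_SAMPLE_FORMAT, 3L, 1L, sample_format)
    write_uint(con, if (i < npages) ifd_off[i + 1L] else 0L, 4L)
  }
  invisible(path)
}

read_uint <- function(con, size, endian) {
  # readBin only honours signed = FALSE for sizes 1 and 2; 4-byte offsets
  # below 2^31 read correctly as signed
  v <- readBin(con, "integer", n = 1L, size = size,
               signed = !(size < 4L), endian = endian)
  if (size < 4L && v < 0) v <- v + if (size == 1L) 256L else 65536L
  v
}

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `11` = 4L,
                    `12` = 8L)

read_tag_payload <- function(con, type, count, endian) {
  size <- tiff_type_size[as.character(type)]
  if (is.na(size)) return(NULL)
  if (type == 2L) { # ASCII
    raw <- readBin(con, "raw", n = count)
    return(rawToChar(raw[raw != as.raw(0L)]))
  }
  if (type == 5L) { # RATIONAL
    v <- readBin(con, "integer", n = 2L * count, size = 4L, endian = endian)
    return(v[seq(1, length(v), 2)] / v[seq(2, length(v), 2)])
  }
  if (type == 11L)
    return(readBin(con, "double", n = count, size = 4L, endian = endian))
  if (type == 12L)
    return(readBin(con, "double", n = count, size = 8L, endian = endian))
  v <- readBin(con, "integer", n = count, size = size,
               signed = size >= 4L || type %in% c(6L, 8L), endian = endian)
  if (type == 3L) v[v < 0] <- v[v < 0] + 65536L
  if (type == 1L) v[v < 0] <- v[v < 0] + 256L
  v
}

# Returns list(pages = list of (y, x) matrices, desc = character or NULL)
read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_mark <- rawToChar(readBin(con, "raw", 2L))
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (read_uint(con, 2L, endian) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- read_uint(con, 4L, endian)
  pages <- list()
  desc <- NULL
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    ntags <- read_uint(con, 2L, endian)
    tags <- list()
    for (k in seq_len(ntags)) {
      id <- read_uint(con, 2L, endian)
      type <- read_uint(con, 2L, endian)
      count <- read_uint(con, 4L, endian)
      size <- tiff_type_size[as.character(type)]
      here <- seek(con)
      if (!is.na(size) && size * count <= 4L) {
        val <- read_tag_payload(con, type, count, endian)
      } else {
        off <- read_uint(con, 4L, endian)
        seek(con, off)
        val <- read_tag_payload(con, type, count, endian)
      }
      seek(con, here + 4L)
      tags[[as.character(id)]] <- val
    }
    next_ifd <- read_uint(con, 4L, endian)
    w <- tags[[as.character(TAG_WIDTH)]]
    h <- tags[[as.character(TAG_HEIGHT)]]
    bits <- tags[[as.character(TAG_BITS)]][1]
    comp <- tags[[as.character(TAG_COMPRESSION)]] %||% 1L
    sf <- tags[[as.character(TAG_SAMPLE_FORMAT)]][1] %||% 1L
    if (comp != 1L)
      stop("unsupported TIFF compression scheme ", comp,
           " (only uncompressed is supported)")
    offsets <- tags[[as.character(TAG_STRIP_OFFSETS)]]
    counts <- tags[[as.character(TAG_STRIP_BYTECOUNTS)]]
    if (is.null(offsets)) stop("malformed TIFF: page without strip offsets")
    if (is.null(counts)) counts <- w * h * bits / 8L
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n <- counts[min(s, length(counts))] / (bits / 8L)
      v <- if (sf == 3L) {
        readBin(con, "double", n = n, size = bits / 8L, endian = endian)
      } else if (bits == 8L) {
        as.numeric(readBin(con, "raw", n = n))
      } else if (bits == 16L) {
        x <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                     endian = endian)
        as.numeric(x)
      } else if (bits == 32L) {
        as.numeric(readBin(con, "integer", n = n, size = 4L, endian = endian))
      } else stop("unsupported TIFF bit depth ", bits)
      vals <- c(vals, v)
    }
    if (length(vals) != w * h) stop("malformed TIFF: strip size mismatch")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    d <- tags[[as.character(TAG_DESCRIPTION)]]
    if (is.null(desc) && !is.null(d)) desc <- d
    ifd_off <- next_ifd
  }
  list(pages = pages, desc = desc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
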