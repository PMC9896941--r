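# Minimal baseline TIFF 6.0 I/O (little-endian, uncompressed, single-sample
# grayscale, 16-bit unsigned or 32-bit float, multi-page). No R TIFF package
# is assumed to be installed; this covers exactly what the pipeline needs:
# hyperstacks with axes T,Z,C,Y,X stored as pages ordered C-fastest, then Z,
# then T, with a JSON ImageDescription carrying shape, axes and voxel size.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `11` = 4L, `12` = 8L)

#' Write a grayscale image or hyperstack as a multi-page TIFF
#'
#' Arrays are interpreted with the trailing two dimensions as Y, X. A matrix
#' is a single plane; a 3D array is Z,Y,X; a 4D array is T,Z,Y,X; a 5D
#' array is T,Z,C,Y,X. Pixel data are written uncompressed as 16-bit
#' unsigned counts (values clamped to [0, 65535] and rounded) or 32-bit
#' floats. Shape, axis labels, voxel size and any extra metadata are stored
#' as JSON in the ImageDescription tag of the first page.
#'
#' @param path output file path.
#' @param data numeric matrix or 3D/5D array (see above).
#' @param dtype `"uint16"` or `"float32"`.
#' @param voxel_size_nm optional numeric, physical voxel size per spatial
#'   axis in nm, e.g. `c(z = 200, y = 100, x = 100)`.
#' @param metadata optional named list merged into the JSON description.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, data, dtype = c("uint16", "float32"),
                       voxel_size_nm = NULL, metadata = list()) {
  dtype <- match.arg(dtype)
  d <- dim(data)
  if (is.null(d)) stopf("`data` must be a matrix or array")
  nd <- length(d)
  if (!nd %in% c(2L, 3L, 4L, 5L))
    stopf(paste("`data` must have 2 (Y,X), 3 (Z,Y,X), 4 (T,Z,Y,X) or 5",
                "(T,Z,C,Y,X) dimensions"))
  axes <- switch(as.character(nd), `2` = "YX", `3` = "ZYX", `4` = "TZYX",
                 `5` = "TZCYX")
  h <- d[nd - 1L]; w <- d[nd]
  n_pages <- prod(d) / (h * w)

  desc <- c(list(axes = axes, shape = as.integer(d)),
            if (!is.null(voxel_size_nm))
              list(voxel_size_nm = as.numeric(voxel_size_nm)),
            metadata)
  desc_raw <- c(charToRaw(jsonlite::toJSON(desc, auto_unbox = TRUE,
                                           digits = NA)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  bps <- if (dtype == "uint16") 2L else 4L
  page_bytes <- h * w * bps
  # layout: header | page data ... | description | IFDs
  data_off <- 8 + (seq_len(n_pages) - 1) * page_bytes
  desc_off <- 8 + n_pages * page_bytes
  ifd0_off <- desc_off + length(desc_raw)
  n_entries <- function(i) if (i == 1L) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_off <- ifd0_off + cumsum(c(0, vapply(seq_len(n_pages)[-1] - 1,
                                           ifd_size, 0)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)
  write_u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                    endian = "little")
  write_u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                    endian = "little")
  write_u32(ifd0_off)

  # pixel data, pages flattened row-major (x fastest)
  flat <- aperm(array(data, dim = c(prod(d[-c(nd - 1L, nd)]), h, w)),
                c(3L, 2L, 1L))  # x, y, page
  if (dtype == "uint16") {
    v <- round(pmin(pmax(as.vector(flat), 0), 65535))
    v[v > 32767] <- v[v > 32767] - 65536  # two's complement for writeBin
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(as.vector(flat)), con, size = 4, endian = "little")
  }
  writeBin(desc_raw, con)

  entry <- function(tag, type, count, value) {
    write_u16(tag); write_u16(type); write_u32(count)
    if (type == 3L && count == 1L) { write_u16(value); write_u16(0L) }
    else write_u32(value)
  }
  fmt <- if (dtype == "uint16") 1L else 3L
  for (i in seq_len(n_pages)) {
    write_u16(n_entries(i))
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, 8L * bps)
    entry(259L, 3L, 1L, 1L)        # no compression
    entry(262L, 3L, 1L, 1L)        # BlackIsZero
    if (i == 1L) entry(270L, 2L, length(desc_raw), desc_off)
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, fmt)
    write_u32(if (i < n_pages) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Reads uncompressed little-endian grayscale TIFFs (8/16-bit unsigned or
#' 32-bit float, one sample per pixel, any strip layout). If the first page
#' carries a JSON ImageDescription written by [write_tiff()], the array is
#' reshaped to the recorded axes; otherwise pages are returned as a Z,Y,X
#' array (or Y,X matrix for a single page).
#'
#' @param path TIFF file path.
#' @return list with `data` (numeric array), `axes` (character) and
#'   `metadata` (parsed description, or NULL).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) as.integer(raw[off + 1L]) +
    256L * as.integer(raw[off + 2L])
  u32 <- function(off) as.double(as.integer(raw[off + 1L])) +
    256 * as.integer(raw[off + 2L]) + 65536 * as.integer(raw[off + 3L]) +
    16777216 * as.integer(raw[off + 4L])
  if (rawToChar(raw[1:2]) != "II")
    stopf("only little-endian ('II') TIFF is supported")
  if (u16(2L) != 42L) stopf("not a TIFF file: %s", path)

  read_values <- function(type, count, off) {
    size <- TIFF_TYPE_SIZE[as.character(type)]
    total <- size * count
    voff <- if (total <= 4) off else u32(off)
    if (type == 2L) {
      return(rawToChar(raw[(voff + 1L):(voff + count - 1L)]))
    }
    vapply(seq_len(count) - 1L, function(k) {
      o <- voff + k * size
      if (size == 2L) u16(o) else u32(o)
    }, 0)
  }

  pages <- list(); desc <- NULL
  ifd <- u32(4L)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      o <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(o); type <- u16(o + 2L); count <- u32(o + 4L)
      if (!as.character(type) %in% names(TIFF_TYPE_SIZE)) next
      tags[[as.character(tag)]] <- read_values(type, count, o + 8L)
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- (tags[["258"]] %||% 16L)[1]
    if ((tags[["259"]] %||% 1) != 1) stopf("compressed TIFF not supported")
    fmt <- tags[["339"]] %||% 1
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    if (is.null(desc) && !is.null(tags[["270"]]))
      desc <- tryCatch(jsonlite::fromJSON(tags[["270"]]),
                       error = function(e) NULL)
    buf <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1L):(offs[k] + cnts[k])]), use.names = FALSE)
    con <- rawConnection(buf)
    px <- if (fmt == 3) readBin(con, "numeric", h * w, size = 4,
                                endian = "little")
          else readBin(con, "integer", h * w, size = bits / 8L,
                       signed = FALSE, endian = "little")
    close(con)
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    ifd <- u32(ifd + 2L + n * 12L)
  }

  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(unlist(lapply(pages, t), use.names = FALSE),
               dim = c(w, h, length(pages)))
  arr <- aperm(arr, c(3L, 2L, 1L))  # page, y, x; page varies fastest in vec
  axes <- "ZYX"
  if (!is.null(desc) && !is.null(desc$shape) && !is.null(desc$axes) &&
      prod(desc$shape) == length(arr)) {
    # leading page dims were flattened column-major on write, so the
    # (page, y, x) vector is already in column-major order of the shape
    arr <- array(as.vector(arr), dim = desc$shape)
    axes <- desc$axes
  } else if (length(pages) == 1L) {
    arr <- pages[[1]]; axes <- "YX"
  }
  list(data = arr, axes = axes, metadata = desc)
}
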