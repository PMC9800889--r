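# File formats. No TIFF reader/writer exists in the installed R stack, so a
# minimal baseline TIFF codec is implemented here: little-endian, uncompressed,
# single-sample grayscale, 8/16-bit unsigned or 32/64-bit IEEE float, one or
# more strips per page, multi-page via chained IFDs. This covers everything
# the pipeline writes and the common grayscale exports of scientific tools.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Read and write multi-page grayscale TIFF stacks
#'
#' `write_tiff_stack()` writes an `H x W x T` numeric array as an uncompressed
#' little-endian multi-page grayscale TIFF; `read_tiff_stack()` reads one back.
#' Supported sample types: unsigned 8/16-bit integers and IEEE 32/64-bit
#' floats. Values are stored verbatim (no rescaling), so a float round-trip is
#' bit-exact; interpretation (e.g. scaling integer data to `[0, 1]`) is left
#' to [read_video()].
#'
#' @param arr numeric `H x W x T` array (or `H x W` matrix).
#' @param path file path.
#' @param dtype one of `"float64"`, `"float32"`, `"uint8"`, `"uint16"`.
#' @return `read_tiff_stack()` returns an `H x W x T` array with attribute
#'   `dtype`; `write_tiff_stack()` returns `path` invisibly.
#' @export
write_tiff_stack <- function(arr, path, dtype = c("float64", "float32", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  h <- dim(arr)[1]; w <- dim(arr)[2]; n <- dim(arr)[3]
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L, float64 = 64L)
  fmt <- if (startsWith(dtype, "float")) 3L else 1L
  bpp <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # data strips first; IFDs after all pixel data
  data_offsets <- 8L + (0:(n - 1)) * (h * w * bpp)
  ifd0 <- 8L + n * h * w * bpp
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  for (t in seq_len(n)) {
    v <- as.vector(t(arr[, , t])) # TIFF is row-major
    if (fmt == 3L) {
      writeBin(as.numeric(v), con, size = bpp, endian = "little")
    } else {
      if (any(v < 0 | v > 2^bits - 1)) stop_input("values out of range for %s", dtype)
      iv <- as.integer(round(v))
      if (bits == 16L) iv <- ifelse(iv > 32767L, iv - 65536L, iv) # two's complement
      writeBin(iv, con, size = bpp, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) { # type 3 = SHORT, 4 = LONG
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (t in seq_len(n)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 4, 1, w)
    entry(257, 4, 1, h)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)       # no compression
    entry(262, 3, 1, 1)       # BlackIsZero
    entry(273, 4, 1, data_offsets[t])
    entry(277, 3, 1, 1)
    entry(278, 4, 1, h)
    entry(279, 4, 1, h * w * bpp)
    entry(339, 3, 1, fmt)
    next_ifd <- if (t < n) ifd0 + t * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop_format("not a little-endian TIFF file: %s", path)
  ifd <- u32(4)
  pages <- list()
  dtype <- NULL
  while (ifd != 0) {
    if (ifd + 2 > length(raw)) stop_format("truncated TIFF IFD in %s", path)
    cnt <- u16(ifd)
    tags <- list()
    for (i in seq_len(cnt)) {
      off <- ifd + 2 + (i - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      size <- c(1, 1, 2, 4, 8)[type]
      vals <- if (count * size <= 4) {
        if (type == 3L) sapply(seq_len(count), function(k) u16(off + 8 + (k - 1) * 2))
        else u32(off + 8)
      } else {
        voff <- u32(off + 8)
        if (type == 3L) sapply(seq_len(count), function(k) u16(voff + (k - 1) * 2))
        else sapply(seq_len(count), function(k) u32(voff + (k - 1) * 4))
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256); h <- g(257); bits <- g(258, 8)[1]
    if (is.null(w) || is.null(h)) stop_format("TIFF page missing dimensions in %s", path)
    if (g(259, 1)[1] != 1) stop_format("compressed TIFF not supported: %s", path)
    if (g(277, 1)[1] != 1) stop_format("only single-sample grayscale TIFF supported: %s", path)
    fmt <- g(339, 1)[1]
    offs <- g(273); bytes <- g(279, h * w * bits / 8)
    bpp <- bits %/% 8
    buf <- raw(0)
    for (k in seq_along(offs)) {
      if (offs[k] + bytes[k] > length(raw)) stop_format("truncated TIFF strip in %s", path)
      buf <- c(buf, raw[(offs[k] + 1):(offs[k] + bytes[k])])
    }
    v <- if (fmt == 3) {
      readBin(buf, "double", n = h * w, size = bpp, endian = "little")
    } else {
      x <- readBin(buf, "integer", n = h * w, size = bpp, endian = "little",
                   signed = bpp > 2)
      if (bpp <= 2) x <- ifelse(x < 0, x + 2^bits, x)
      x
    }
    dtype <- sprintf(if (fmt == 3) "float%d" else "uint%d", bits)
    pages[[length(pages) + 1]] <- t(matrix(v, w, h))
    ifd <- u32(ifd + 2 + cnt * 12)
  }
  if (!length(pages)) stop_format("TIFF contains no pages: %s", path)
  out <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  attr(out, "dtype") <- dtype
  out
}

FLO_MAGIC <- 202021.25

#' Middlebury .flo optical-flow files
#'
#' Standard layout: float32 magic `202021.25`, int32 width and height, then
#' `W * H` interleaved `(dx, dy)` float32 pairs in row-major order. Values are
#' stored as 32-bit floats; a file round-trip is bit-exact.
#'
#' @param flow a [flow_field()] (`H x W x 2`, channels `(dx, dy)`).
#' @param path file path.
#' @return `read_flo()` returns a [flow_field()]; `write_flo()` returns `path`
#'   invisibly.
#' @export
write_flo <- function(flow, path) {
  h <- dim(flow)[1]; w <- dim(flow)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4, endian = "little")
  writeBin(as.integer(c(w, h)), con, size = 4, endian = "little")
  inter <- rbind(as.vector(t(flow[, , 1])), as.vector(t(flow[, , 2])))
  writeBin(as.numeric(inter), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_flo
#' @export
read_flo <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "double", n = 1, size = 4, endian = "little")
  if (!length(magic) || abs(magic - FLO_MAGIC) > 1e-3)
    stop_format("bad .flo magic in %s", path)
  wh <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  if (length(wh) < 2 || any(wh <= 0)) stop_format("bad .flo header in %s", path)
  w <- wh[1]; h <- wh[2]
  v <- readBin(con, "double", n = 2 * w * h, size = 4, endian = "little")
  if (length(v) < 2 * w * h) stop_format("truncated .flo file: %s", path)
  m <- matrix(v, nrow = 2)
  flow_field(array(c(t(matrix(m[1, ], w, h)), t(matrix(m[2, ], w, h))), c(h, w, 2)))
}

#' Read and write grayscale video sequences
#'
#' Supported inputs: a multi-frame TIFF file (`.tif`/`.tiff`) or a directory
#' of PNG frames (sorted by file name). Integer TIFF/PNG data are scaled to
#' `[0, 1]` by the dtype maximum; float TIFF data are taken verbatim, so a
#' float TIFF written by [write_video()] round-trips bit-exactly.
#'
#' @param path file or directory path.
#' @param pixel_spacing mm/px metadata attached to the result.
#' @param video a [video_sequence()].
#' @param dtype TIFF sample type for writing (default `"float64"`, lossless).
#' @return `read_video()` returns a [video_sequence()].
#' @export
read_video <- function(path, pixel_spacing = 1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop_format("no PNG frames found in directory %s", path)
    frames <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3) im <- apply(im[, , 1:min(3, dim(im)[3]), drop = FALSE], c(1, 2), mean)
      im
    })
    arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
    return(video_sequence(arr, pixel_spacing))
  }
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop_format("unsupported video format: %s (use multi-frame TIFF or a PNG directory)", path)
  arr <- read_tiff_stack(path)
  dt <- attr(arr, "dtype")
  if (startsWith(dt, "uint")) {
    bits <- as.integer(sub("uint", "", dt))
    arr <- arr / (2^bits - 1)
  }
  attr(arr, "dtype") <- NULL
  video_sequence(arr, pixel_spacing)
}

#' @rdname read_video
#' @export
write_video <- function(video, path, dtype = "float64") {
  arr <- unclass(video)
  attributes(arr) <- list(dim = dim(video))
  if (dtype %in% c("uint8", "uint16")) arr <- round(arr * (2^c(uint8 = 8, uint16 = 16)[[dtype]] - 1))
  write_tiff_stack(arr, path, dtype = dtype)
}

#' @rdname read_video
#' @param masks a [mask_sequence()].
#' @export
write_masks <- function(masks, path) {
  arr <- unclass(masks)
  attributes(arr) <- list(dim = dim(masks))
  write_tiff_stack(arr, path, dtype = "uint8")
}

#' @rdname read_video
#' @export
read_masks <- function(path, pixel_spacing = 1) {
  arr <- read_tiff_stack(path)
  attr(arr, "dtype") <- NULL
  mask_sequence(arr, pixel_spacing)
}

#' Point-track CSV I/O
#'
#' Tracks are stored long-form with columns `frame` (0-based), `k` (1-based
#' point id), `x`, `y` (0-based pixel coordinates).
#'
#' @param points per-frame list of `K x 2` matrices, as in a
#'   `phantom_sequence`.
#' @param path file path.
#' @return `read_points_csv()` returns the per-frame list of matrices;
#'   `points_tibble()` the long-form [tibble::tibble()].
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points_tibble(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
points_tibble <- function(points) {
  tibble::tibble(
    frame = rep(seq_along(points) - 1L, vapply(points, nrow, 1L)),
    k = unlist(lapply(points, function(p) seq_len(nrow(p)))),
    x = unlist(lapply(points, function(p) p[, 1])),
    y = unlist(lapply(points, function(p) p[, 2])))
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "k", "x", "y") %in% names(df)))
    stop_format("points CSV must have columns frame, k, x, y: %s", path)
  lapply(sort(unique(df$frame)), function(t) {
    d <- df[df$frame == t, ]
    d <- d[order(d$k), ]
    cbind(x = d$x, y = d$y)
  })
}

#' Write all artifacts of a phantom sequence to a directory
#'
#' Emits `video.tif`, `masks.tif`, ground-truth flows as `flow_####.flo`,
#' `points.csv` and `gls_true.csv`.
#'
#' @param phantom a `phantom_sequence` from [make_phantom()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_video(phantom$video, file.path(dir, "video.tif"))
  write_masks(phantom$masks, file.path(dir, "masks.tif"))
  for (i in seq_along(phantom$flows))
    write_flo(phantom$flows[[i]], file.path(dir, sprintf("flow_%04d.flo", i - 1)))
  write_points_csv(phantom$points, file.path(dir, "points.csv"))
  utils::write.csv(
    data.frame(frame = seq_along(phantom$gls_true) - 1L, gls_true = phantom$gls_true),
    file.path(dir, "gls_true.csv"), row.names = FALSE)
  invisible(dir)
}
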