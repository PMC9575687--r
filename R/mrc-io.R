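#' @include AllClasses.R
NULL

#' Round doubles to 32-bit float precision
#'
#' MRC mode-2 files store 32-bit reals; this helper applies the same
#' quantization in memory, so that a write/read round trip of already
#' quantized data is bit-exact.
#'
#' @param x numeric vector/array.
#' @return numeric of the same shape, quantized to float32.
#' @export
float32Round <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
                 "numeric", n = length(x), size = 4, endian = "little")
  dim(out) <- d
  out
}

.mrcHeader <- function(nx, ny, nz, pixelSizeA, dmin, dmax, dmean, rms) {
  con <- raw(0)
  wInt <- function(...) writeBin(as.integer(c(...)), raw(), size = 4,
                                 endian = "little")
  wFlt <- function(...) writeBin(as.numeric(c(...)), raw(), size = 4,
                                 endian = "little")
  h <- c(
    wInt(nx, ny, nz, 2L),                      # dims + mode 2 (float32)
    wInt(0L, 0L, 0L),                          # nstart
    wInt(nx, ny, nz),                          # sampling grid
    wFlt(nx * pixelSizeA, ny * pixelSizeA, nz * pixelSizeA),  # cell A
    wFlt(90, 90, 90),                          # cell angles
    wInt(1L, 2L, 3L),                          # axis order
    wFlt(dmin, dmax, dmean),
    wInt(0L, 0L),                              # ispg, nsymbt
    raw(25 * 4),                               # extra (words 25-49)
    wFlt(0, 0, 0))                             # origin (words 50-52)
  h <- c(h, charToRaw("MAP "),                 # word 53
         as.raw(c(0x44, 0x44, 0x00, 0x00)),    # little-endian stamp
         wFlt(rms),
         wInt(0L),                             # nlabl
         raw(800))
  stopifnot(length(h) == 1024)
  h
}

.mrcReadHeader <- function(con) {
  hdr <- readBin(con, "raw", n = 1024)
  if (length(hdr) < 1024) stop("truncated MRC file: header incomplete")
  ri <- function(w) readBin(hdr[((w - 1) * 4 + 1):(w * 4)], "integer",
                            size = 4, endian = "little")
  rf <- function(w) readBin(hdr[((w - 1) * 4 + 1):(w * 4)], "numeric",
                            size = 4, endian = "little")
  list(nx = ri(1), ny = ri(2), nz = ri(3), mode = ri(4),
       xlen = rf(11), nlabl = ri(56))
}

#' Write an image stack as an MRCS file (mode 2, 32-bit real)
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMRCS <- function(stack, path) {
  d <- dim(stack@images)
  v <- as.numeric(stack@images)
  hdr <- .mrcHeader(d[1], d[2], d[3], stack@pixelSizeA,
                    min(v), max(v), mean(v), stats::sd(v))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRCS image stack
#'
#' Only MRC mode 2 (32-bit real) is supported; the header pixel size is
#' honored. The returned stack carries minimal metadata (sequential image
#' ids); pair it with a STAR-style table via [readStarTable] for full
#' metadata.
#'
#' @param path MRCS file path.
#' @return an [ImageStack-class].
#' @export
readMRCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrcReadHeader(con)
  if (h$mode != 2L)
    stop("unsupported MRC mode ", h$mode, " (only mode 2, 32-bit real)")
  n <- h$nx * h$ny * h$nz
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(v) < n)
    stop("truncated MRC file: expected ", n * 4 + 1024, " bytes, data ",
         "section holds ", length(v) * 4, " of ", n * 4)
  px <- if (h$nx > 0 && h$xlen > 0) h$xlen / h$nx else 1
  imgs <- array(v, c(h$nx, h$ny, h$nz))
  meta <- data.frame(imageId = seq_len(h$nz), pdId = NA_integer_,
                     defocusUM = NA_real_, snr = NA_real_,
                     noiseSeed = NA_integer_)
  new("ImageStack", images = imgs, pixelSizeA = px, meta = meta)
}

#' Write a cubic volume as an MRC file
#' @param vol cubic numeric array.
#' @param path output path.
#' @param pixelSizeA pixel size in Angstrom.
#' @export
writeMRCVolume <- function(vol, path, pixelSizeA = 1) {
  d <- dim(vol)
  v <- as.numeric(vol)
  hdr <- .mrcHeader(d[1], d[2], d[3], pixelSizeA,
                    min(v), max(v), mean(v), stats::sd(v))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#' @param path MRC file path.
#' @return numeric array with attribute `pixelSizeA`.
#' @export
readMRCVolume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrcReadHeader(con)
  if (h$mode != 2L)
    stop("unsupported MRC mode ", h$mode, " (only mode 2, 32-bit real)")
  n <- h$nx * h$ny * h$nz
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(v) < n)
    stop("truncated MRC file: expected ", n * 4 + 1024, " bytes, data ",
         "section holds ", length(v) * 4, " of ", n * 4)
  out <- array(v, c(h$nx, h$ny, h$nz))
  attr(out, "pixelSizeA") <- if (h$nx > 0 && h$xlen > 0) h$xlen / h$nx else 1
  out
}
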