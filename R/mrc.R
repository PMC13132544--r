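# ---- MRC2014 input/output --------------------------------------------------
#
# Minimal MRC2014 reader/writer: 1024-byte header, little-endian, modes 0
# (int8), 1 (int16), 2 (float32) and 6 (uint16) on read; mode 2 on write.
# The first pixel is the image origin with x as the fastest-varying axis;
# densities are held as doubles in memory and written as 32-bit floats.

mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maps <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 100))                 # extra words 25-49
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_id <- rawToChar(readBin(con, "raw", n = 4))
  invisible(readBin(con, "raw", n = 4))                   # machine stamp
  rms <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 4 + 800))             # nlabl + labels
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], my = ints[9], mz = ints[10],
       cella = cella, dmin = dstats[1], dmax = dstats[2], dmean = dstats[3],
       nsymbt = nsymbt, origin = origin, map_id = map_id, rms = rms)
}

#' Read an MRC/MRCS image or stack
#'
#' @param path Path to an MRC2014 file.
#' @return A list with \code{data} (array \code{c(nx, ny, nz)}),
#'   \code{pixel_size} (A/pixel from cella/mx; NA when the header carries no
#'   cell), and the parsed \code{header}.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- mrc_read_header(con)
  if (is.na(hdr$nx) || hdr$nx <= 0 || hdr$ny <= 0 || hdr$nz <= 0 ||
      !hdr$mode %in% c(0, 1, 2, 6)) {
    stop("corrupt or unsupported MRC header in ", path,
         " (mode ", hdr$mode, ")")
  }
  if (hdr$nsymbt > 0) invisible(readBin(con, "raw", n = hdr$nsymbt))
  n <- as.double(hdr$nx) * hdr$ny * hdr$nz
  data <- switch(as.character(hdr$mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")))
  if (length(data) < n) stop("truncated MRC data in ", path)
  px <- if (hdr$mx > 0 && hdr$cella[1] > 0) hdr$cella[1] / hdr$mx else NA_real_
  list(data = array(data, dim = c(hdr$nx, hdr$ny, hdr$nz)),
       pixel_size = px, header = hdr)
}

#' Write an array as a 32-bit float MRC2014 file
#'
#' @param data A matrix (single image) or array \code{c(nx, ny, nz)}.
#' @param path Output path.
#' @param pixel_size Pixel size in A/pixel, stored via the cell dimensions.
#' @export
write_mrc <- function(data, path, pixel_size = 1) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("data contain non-finite values")
  d <- dim(data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(c(d * pixel_size, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")
  writeBin(c(min(data), max(data), mean(data)), con, size = 4,
           endian = "little")
  writeBin(c(0L, 0L), con, size = 4, endian = "little")     # ispg, nsymbt
  writeBin(raw(100), con)                                   # extra
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")    # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)          # LE machine stamp
  writeBin(stats::sd(data), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")            # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a dose-fractionated movie from an MRC/MRCS stack
#'
#' @param path Path to the stack (>= 2 sections).
#' @param pixel_size_override Optional pixel size (A/pixel) taking precedence
#'   over the header value; required when the header carries none.
#' @param exposure_per_frame Exposure per frame in e-/A^2.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_override = NULL,
                       exposure_per_frame = 0) {
  m <- read_mrc(path)
  if (dim(m$data)[3] < 2) stop("movie must contain >= 2 frames")
  px <- if (!is.null(pixel_size_override)) pixel_size_override else
    m$pixel_size
  if (is.null(px) || is.na(px) || px <= 0) {
    stop("no pixel size in header; pass pixel_size_override")
  }
  movie_stack(m$data, pixel_size = px,
              exposure_per_frame = exposure_per_frame)
}

#' Write a micrograph to an MRC file
#'
#' @param mic A [micrograph()].
#' @param path Output path.
#' @export
write_image <- function(mic, path) {
  stopifnot(inherits(mic, "micrograph"))
  write_mrc(mic$pixels, path, pixel_size = mic$pixel_size)
}

#' Read a micrograph from an MRC file
#'
#' @param path Path to a single-section MRC file.
#' @param pixel_size_override Optional pixel size override.
#' @return A [micrograph()].
#' @export
read_image <- function(path, pixel_size_override = NULL) {
  m <- read_mrc(path)
  px <- if (!is.null(pixel_size_override)) pixel_size_override else
    m$pixel_size
  micrograph(m$data[, , 1], pixel_size = px)
}
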