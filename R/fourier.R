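# ---- Fourier-space utilities ----------------------------------------------
#
# All spectra are full complex 2D FFTs (stats::fft on a matrix); frequencies
# are in cycles/pixel, converted to 1/A with the pixel size where physical
# units matter. Image shifts are applied as phase ramps: a frame whose
# content has moved by s is aligned by multiplying its spectrum with
# exp(+2*pi*i * k . s).

# Signed frequency index axis in cycles/pixel (FFT order).
freq_axis <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

# Frequency grids for an nx x ny image: matrices of kx and ky.
freq_grids <- function(nx, ny) {
  kx <- freq_axis(nx)
  ky <- freq_axis(ny)
  list(kx = matrix(kx, nx, ny), ky = matrix(ky, nx, ny, byrow = TRUE))
}

# Frequency axis vectors for an nx x ny image.
freq_axes <- function(nx, ny) {
  list(kx = freq_axis(nx), ky = freq_axis(ny))
}

# Phase ramp as the outer product of 1D complex exponentials: cheaper than
# exponentiating a full 2D grid.
ramp_outer <- function(kx_axis, ky_axis, sx, sy) {
  outer(exp(2i * pi * kx_axis * sx), exp(2i * pi * ky_axis * sy))
}

#' B-factor low-pass weighting of a Fourier spectrum
#'
#' Multiplies every Fourier coefficient by \code{exp(-B * s^2 / 4)} where
#' \code{s} is the spatial frequency in 1/A (the crystallographic
#' convention). The DC term is unchanged.
#'
#' @param frame_ft Complex matrix: full 2D FFT of a frame.
#' @param bfactor B-factor in A^2 (>= 0).
#' @param pixel_size Pixel size in A/pixel.
#' @return The weighted spectrum.
#' @export
bfactor_filter <- function(frame_ft, bfactor, pixel_size) {
  if (bfactor < 0) stop("bfactor must be >= 0")
  if (bfactor == 0) return(frame_ft)
  g <- freq_grids(nrow(frame_ft), ncol(frame_ft))
  s2 <- (g$kx^2 + g$ky^2) / pixel_size^2
  frame_ft * exp(-bfactor * s2 / 4)
}

# Gaussian B-factor weight map for an nx x ny spectrum.
bfactor_weights <- function(nx, ny, bfactor, pixel_size) {
  g <- freq_grids(nx, ny)
  exp(-bfactor * (g$kx^2 + g$ky^2) / pixel_size^2 / 4)
}

# 1-based FFT indices of an n_in axis retained when cropping to n_out.
crop_indices <- function(n_in, n_out) {
  c(seq_len(ceiling(n_out / 2)),
    if (floor(n_out / 2) > 0) (n_in - floor(n_out / 2) + 1):n_in)
}

#' Fourier-crop a movie to a target pixel size
#'
#' Downsamples every frame by truncating Fourier components beyond the new
#' Nyquist frequency. Output dimensions are
#' \code{round(dim * pixel_size / target)}; the exact realized pixel size
#' (\code{nx * pixel_size / nx_out}, x axis) is stored. The image mean is
#' conserved.
#'
#' @param movie A [movie_stack()].
#' @param target_pixel_size Target pixel size in A/pixel (>= current).
#' @return A Fourier-cropped [movie_stack()].
#' @export
fourier_crop <- function(movie, target_pixel_size) {
  stopifnot(inherits(movie, "movie_stack"))
  if (target_pixel_size < movie$pixel_size) {
    stop("target pixel size smaller than input (upsampling not supported)")
  }
  nx <- movie$nx; ny <- movie$ny
  mx <- round(nx * movie$pixel_size / target_pixel_size)
  my <- round(ny * movie$pixel_size / target_pixel_size)
  if (mx == nx && my == ny) return(movie)
  ix <- crop_indices(nx, mx)
  iy <- crop_indices(ny, my)
  out <- array(0, dim = c(mx, my, movie$NF))
  for (f in seq_len(movie$NF)) {
    ft <- stats::fft(movie$frames[, , f])
    out[, , f] <- Re(stats::fft(ft[ix, iy], inverse = TRUE)) / (nx * ny)
  }
  movie_stack(out, pixel_size = nx * movie$pixel_size / mx,
              exposure_per_frame = movie$exposure_per_frame)
}

#' Fourier-crop dimensions for given geometry
#'
#' The dimension rule used by [fourier_crop()], exposed for planning runs.
#'
#' @param nx,ny Input dimensions in pixels.
#' @param pixel_size Input pixel size (A/pixel).
#' @param target_pixel_size Target pixel size (A/pixel).
#' @return Integer vector \code{c(nx_out, ny_out)}.
#' @export
fourier_crop_dims <- function(nx, ny, pixel_size, target_pixel_size) {
  c(round(nx * pixel_size / target_pixel_size),
    round(ny * pixel_size / target_pixel_size))
}

# Shift an image by (sx, sy) pixels via a Fourier phase ramp; positive shift
# aligns a frame whose content has moved by (+sx, +sy).
fourier_shift_image <- function(img, sx, sy) {
  ft <- stats::fft(img)
  a <- freq_axes(nrow(img), ncol(img))
  Re(stats::fft(ft * ramp_outer(a$kx, a$ky, sx, sy),
                inverse = TRUE)) / length(img)
}

# Subpixel peak of a cross-correlation map by separable parabolic fits
# around the integer maximum (wrapped indices). Returns c(dx, dy).
cc_peak_subpixel <- function(cc) {
  nx <- nrow(cc); ny <- ncol(cc)
  im <- which.max(cc)
  i0 <- (im - 1) %% nx + 1
  j0 <- (im - 1) %/% nx + 1
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (den >= 0) 0 else {
      d <- 0.5 * (ym - yp) / den
      max(min(d, 0.5), -0.5)
    }
  }
  dx <- para(cc[wrap(i0 - 1, nx), j0], cc[i0, j0], cc[wrap(i0 + 1, nx), j0])
  dy <- para(cc[i0, wrap(j0 - 1, ny)], cc[i0, j0], cc[i0, wrap(j0 + 1, ny)])
  sx <- i0 - 1 + dx
  sy <- j0 - 1 + dy
  if (sx > nx / 2) sx <- sx - nx
  if (sy > ny / 2) sy <- sy - ny
  c(sx, sy)
}
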