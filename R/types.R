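#' unbendr: local motion correction for cryo-EM movies
#'
#' Implements full-frame and patch-based cross-correlation alignment of
#' dose-fractionated movies, a 3D B-spline deformation model, pixel-wise
#' distortion correction, strain-field quantification, and template-matching
#' SNR utilities, plus a seeded synthetic test bed.
#'
#' @keywords internal
"_PACKAGE"

#' Run configuration
#'
#' Bundles the tunable parameters of the alignment and modeling pipeline.
#'
#' @param bfactor_initial Gaussian down-weighting B-factor (A^2) applied to
#'   both images during cross-correlation alignment; outlier frames are
#'   re-aligned with twice this value. Default 1500.
#' @param sg_enabled Apply Savitzky-Golay smoothing to the full-frame
#'   trajectory instead of keeping raw shifts. Off by default; raw shifts can
#'   represent real discontinuous sample motion.
#' @param sg_window,sg_order Savitzky-Golay window (odd; capped at the frame
#'   count) and polynomial order.
#' @param iqr_factor Interquartile-range multiplier for outlier detection in
#'   both alignment stages. Default 1.5.
#' @param output_pixel_size Target pixel size (A/pixel) the movie is
#'   Fourier-cropped to before alignment. Default 1.5.
#' @param patch_nx,patch_ny Optional overrides of the patch counts.
#' @param patch_size Optional override of the square patch edge (pixels);
#'   default chosen from the output pixel size by [choose_patch_size()].
#' @param knot_exposure_spacing Exposure between consecutive z-knots
#'   (e-/A^2). Default 4.
#' @param min_knots Minimum in-plane knot count per axis. Default 4.
#' @param max_iter Iteration cap for the cross-correlation refinement of the
#'   spline parameters. Default 200.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(bfactor_initial = 1500,
                       sg_enabled = FALSE,
                       sg_window = 11,
                       sg_order = 3,
                       iqr_factor = 1.5,
                       output_pixel_size = 1.5,
                       patch_nx = NULL,
                       patch_ny = NULL,
                       patch_size = NULL,
                       knot_exposure_spacing = 4,
                       min_knots = 4,
                       max_iter = 200) {
  stopifnot(bfactor_initial >= 0, iqr_factor > 0, output_pixel_size > 0,
            knot_exposure_spacing > 0, min_knots >= 2, max_iter >= 1,
            sg_order >= 1)
  structure(list(bfactor_initial = bfactor_initial,
                 sg_enabled = isTRUE(sg_enabled),
                 sg_window = sg_window,
                 sg_order = sg_order,
                 iqr_factor = iqr_factor,
                 output_pixel_size = output_pixel_size,
                 patch_nx = patch_nx, patch_ny = patch_ny,
                 patch_size = patch_size,
                 knot_exposure_spacing = knot_exposure_spacing,
                 min_knots = min_knots,
                 max_iter = max_iter),
            class = "run_config")
}

#' Movie stack
#'
#' A dose-fractionated movie: NF frames of identical dimensions with pixel
#' size and per-frame exposure metadata. Frames are stored as a 3D array with
#' dim \code{c(nx, ny, NF)}; the first index runs along x (fastest axis of
#' the MRC layout), indices are 0-based in all coordinate arithmetic.
#'
#' @param frames Numeric array \code{c(nx, ny, NF)} (or a list of matrices).
#' @param pixel_size Pixel size in A/pixel (> 0).
#' @param exposure_per_frame Exposure per frame in e-/A^2 (>= 0).
#' @return An object of class \code{movie_stack}.
#' @export
movie_stack <- function(frames, pixel_size, exposure_per_frame = 0) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) stop("movie must contain >= 2 frames")
  stopifnot(pixel_size > 0, exposure_per_frame >= 0)
  if (!all(is.finite(frames))) stop("frames contain non-finite values")
  structure(list(frames = frames,
                 pixel_size = pixel_size,
                 exposure_per_frame = exposure_per_frame,
                 nx = dim(frames)[1], ny = dim(frames)[2],
                 NF = dim(frames)[3]),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("movie_stack: %d frames of %d x %d px at %.4g A/px, %.3g e-/A^2 per frame\n",
              x$NF, x$nx, x$ny, x$pixel_size, x$exposure_per_frame))
  invisible(x)
}

#' Micrograph
#'
#' A single 2D image with pixel size metadata, stored as an \code{nx x ny}
#' matrix (x along rows).
#'
#' @param pixels Numeric matrix.
#' @param pixel_size Pixel size in A/pixel.
#' @return An object of class \code{micrograph}.
#' @export
micrograph <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (!all(is.finite(pixels))) stop("pixels contain non-finite values")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 nx = nrow(pixels), ny = ncol(pixels)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px at %.4g A/px (mean %.4g)\n",
              x$nx, x$ny, x$pixel_size, mean(x$pixels)))
  invisible(x)
}
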