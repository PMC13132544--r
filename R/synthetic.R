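# ---- Synthetic test bed ----------------------------------------------------
#
# Seeded phantom movies with known global drift, known spline-generated
# local deformation, and Gaussian noise. The ground-truth deformation is
# expressed relative to the exposure-time-mean configuration (a zero-mean
# temporal ramp): an alignment method can only recover motion up to a static
# reference, so the truth is placed in the recoverable gauge and the clean
# phantom is the time-mean configuration.

#' Phantom movie specification
#'
#' Defaults describe the package's standard validation fixture: a 768 x 512
#' px, 24-frame movie at 1.5 A/pixel and 1 e-/A^2 per frame, 150 Gaussian
#' blobs of sigma 3 px and unit peak contrast, per-frame Gaussian noise of
#' sigma 0.3 (variance-SNR about 0.1 per frame, typical of low-exposure
#' cryo-EM frames), global drift with 6 px peak-to-peak range, and a random
#' smooth deformation with knot amplitudes up to 6 px, ramped linearly over
#' the exposure around the time-mean configuration.
#'
#' @param nx,ny Image dimensions (pixels).
#' @param NF Number of frames.
#' @param pixel_size Pixel size (A/pixel).
#' @param exposure_per_frame Exposure per frame (e-/A^2).
#' @param n_particles Number of Gaussian blobs.
#' @param sigma Blob standard deviation (pixels).
#' @param contrast Blob peak density.
#' @param noise_sigma Per-frame Gaussian noise standard deviation.
#' @param drift_amplitude Peak-to-peak global drift (pixels).
#' @param deformation_amplitude Maximum knot amplitude of the local
#'   deformation (pixels).
#' @param seed Integer seed recorded in all outputs.
#' @param allow_empty Permit \code{n_particles = 0} (flat phantom).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(nx = 768, ny = 512, NF = 24,
                         pixel_size = 1.5, exposure_per_frame = 1.0,
                         n_particles = 150, sigma = 3, contrast = 1,
                         noise_sigma = 0.3,
                         drift_amplitude = 6, deformation_amplitude = 6,
                         seed = 1, allow_empty = FALSE) {
  stopifnot(nx >= 32, ny >= 32, NF >= 2, pixel_size > 0, sigma > 0,
            noise_sigma >= 0, drift_amplitude >= 0,
            deformation_amplitude >= 0)
  if (n_particles < 1 && !allow_empty) {
    stop("zero particles (set allow_empty = TRUE for a flat phantom)")
  }
  structure(as.list(environment()), class = "phantom_spec")
}

#' Render the clean phantom image
#'
#' Gaussian blobs at seeded, uniformly distributed subpixel positions, kept
#' fully inside the image (4 sigma margin).
#'
#' @param spec A [phantom_spec()].
#' @return An nx x ny matrix.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- matrix(0, spec$nx, spec$ny)
  if (spec$n_particles < 1) return(img)
  set.seed(spec$seed)
  margin <- 4 * spec$sigma
  px <- stats::runif(spec$n_particles, margin, spec$nx - 1 - margin)
  py <- stats::runif(spec$n_particles, margin, spec$ny - 1 - margin)
  r <- ceiling(4 * spec$sigma)
  for (i in seq_len(spec$n_particles)) {
    xs <- max(0, floor(px[i]) - r):min(spec$nx - 1, ceiling(px[i]) + r)
    ys <- max(0, floor(py[i]) - r):min(spec$ny - 1, ceiling(py[i]) + r)
    gx <- exp(-(xs - px[i])^2 / (2 * spec$sigma^2))
    gy <- exp(-(ys - py[i])^2 / (2 * spec$sigma^2))
    img[xs + 1, ys + 1] <- img[xs + 1, ys + 1] +
      spec$contrast * outer(gx, gy)
  }
  img
}

#' Ground truth for a synthetic movie
#'
#' Drift: a smooth, exponentially settling trajectory (fast early motion,
#' the signature of stage drift after exposure start) along a seeded
#' direction, with zero mean over frames. Deformation: a random in-plane
#' knot pattern on the default knot grid, multiplied along the exposure axis
#' by a linear ramp that is exactly zero-mean over frames.
#'
#' @param spec A [phantom_spec()].
#' @param config A [run_config()] (controls the knot-grid layout).
#' @param np_x,np_y Patch counts used to size the knot grid.
#' @return An object of class \code{ground_truth}: \code{drift} (NF x 2,
#'   pixels), \code{grid} (a [knot_grid_3d()]), \code{reference} (the clean
#'   phantom), and \code{spec}.
#' @export
make_ground_truth <- function(spec, config = run_config(),
                              np_x = 6, np_y = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  reference <- make_phantom(spec)
  set.seed(spec$seed + 1000L)
  NF <- spec$NF
  settle <- 1 - exp(-3 * (seq_len(NF) - 1) / (NF - 1))
  settle <- settle / max(settle)
  theta <- stats::runif(1, 0, 2 * pi)
  drift <- cbind(spec$drift_amplitude * cos(theta) * settle,
                 spec$drift_amplitude * sin(theta) * settle)
  drift <- sweep(drift, 2, colMeans(drift))
  grid <- build_default_knot_grid(np_x, np_y, NF, spec$exposure_per_frame,
                                  spec$nx, spec$ny, config)
  dims <- dim(grid$Kx)
  # linear ramp over the exposure, exactly zero-mean over frames, spanning
  # about [-1, 1] so the extreme frames reach the full knot amplitude
  ramp <- 2 * (grid$z_positions - (NF + 1) / 2) / NF
  amp <- spec$deformation_amplitude
  Px <- matrix(stats::runif(dims[1] * dims[2], -amp, amp), dims[1], dims[2])
  Py <- matrix(stats::runif(dims[1] * dims[2], -amp, amp), dims[1], dims[2])
  for (k in seq_len(dims[3])) {
    grid$Kx[, , k] <- ramp[k] * Px
    grid$Ky[, , k] <- ramp[k] * Py
  }
  structure(list(drift = drift, grid = grid, reference = reference,
                 spec = spec),
            class = "ground_truth")
}

# Total true displacement field of one frame (drift + deformation).
true_total_field <- function(truth, f) {
  field <- eval_shift_field(truth$grid, f, nx = truth$spec$nx,
                            ny = truth$spec$ny)
  list(ux = field$ux + truth$drift[f, 1],
       uy = field$uy + truth$drift[f, 2])
}

#' Simulate a dose-fractionated movie from ground truth
#'
#' Frame \code{fi} is the reference warped by the total true displacement
#' (drift plus deformation) of that frame, plus iid Gaussian noise of
#' \code{noise_sigma}.
#'
#' @param reference Clean phantom image (from [make_phantom()]).
#' @param truth A [make_ground_truth()] object.
#' @param spec The [phantom_spec()].
#' @return A [movie_stack()].
#' @export
simulate_movie <- function(reference, truth, spec) {
  set.seed(spec$seed + 2000L)
  frames <- array(0, dim = c(spec$nx, spec$ny, spec$NF))
  for (f in seq_len(spec$NF)) {
    u <- true_total_field(truth, f)
    frames[, , f] <- warp_frame(reference, -u$ux, -u$uy)
    if (spec$noise_sigma > 0) {
      frames[, , f] <- frames[, , f] +
        stats::rnorm(spec$nx * spec$ny, sd = spec$noise_sigma)
    }
  }
  movie_stack(frames, spec$pixel_size, spec$exposure_per_frame)
}

#' Run configuration for the standard synthetic fixture
#'
#' The default 512-px patch rule is sized for ~4k-px real micrographs; on
#' the 768 x 512 px fixture it would give a degenerate 2 x 1 patch grid.
#' The fixture configuration uses 128-px patches instead, preserving the
#' spatial sampling density (a 6 x 4 patch grid, hence the minimum 4 x 4
#' in-plane knot grid) that the default rules produce at real sizes.
#'
#' @param ... Overrides passed to [run_config()].
#' @return A [run_config()] with \code{patch_size = 128}.
#' @export
fixture_config <- function(...) {
  run_config(patch_size = 128, ...)
}

#' Zero-mean normalized cross-correlation of two images
#'
#' @param a,b Numeric matrices of identical dimensions.
#' @return Pearson correlation of the pixel values.
#' @export
ncc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  stats::cor(as.vector(a), as.vector(b))
}

#' Parameter-recovery report for a synthetic experiment
#'
#' Compares the recovered total motion model (global trajectory plus spline
#' deformation) against the ground truth and scores the corrected
#' micrograph against the clean phantom.
#'
#' @param truth A [make_ground_truth()] object.
#' @param fitted A fitted [knot_grid_3d()].
#' @param global_traj The recovered full-frame [shift_trajectory()].
#' @param corrected The distortion-corrected [micrograph()].
#' @param fullframe_mic The full-frame-only [micrograph()] for comparison.
#' @param stride Raster subsampling stride for the field RMSE (pixels).
#' @return List with \code{rmse_per_frame} (px), \code{rmse} (overall px),
#'   \code{knot_rmse} (px; NA when layouts differ), \code{cc_corrected},
#'   \code{cc_fullframe}.
#' @export
recovery_report <- function(truth, fitted, global_traj, corrected,
                            fullframe_mic, stride = 4) {
  spec <- truth$spec
  if (corrected$nx != spec$nx || corrected$ny != spec$ny) {
    stop("raster mismatch between corrected micrograph and ground truth")
  }
  xs <- seq(0, spec$nx - 1, by = stride)
  ys <- seq(0, spec$ny - 1, by = stride)
  at <- as.matrix(expand.grid(x = xs, y = ys))
  rmse_per_frame <- vapply(seq_len(spec$NF), function(f) {
    rec <- eval_shift_field(fitted, f, at = at)
    tru <- eval_shift_field(truth$grid, f, at = at)
    ex <- rec$ux + global_traj$shifts[f, 1] - (tru$ux + truth$drift[f, 1])
    ey <- rec$uy + global_traj$shifts[f, 2] - (tru$uy + truth$drift[f, 2])
    sqrt(mean(ex^2 + ey^2))
  }, numeric(1))
  knot_rmse <- if (all(dim(fitted$Kx) == dim(truth$grid$Kx))) {
    sqrt(mean((fitted$Kx - truth$grid$Kx)^2 +
                (fitted$Ky - truth$grid$Ky)^2))
  } else NA_real_
  list(rmse_per_frame = rmse_per_frame,
       rmse = sqrt(mean(rmse_per_frame^2)),
       knot_rmse = knot_rmse,
       cc_corrected = ncc(corrected$pixels, truth$reference),
       cc_fullframe = ncc(fullframe_mic$pixels, truth$reference))
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the movie (MRC stack), the ground-truth spline parameter file and
#' drift table, and a JSON manifest recording the seed and spec.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [phantom_spec()].
#' @param config A [run_config()]; the default uses 128-px patches, the
#'   patch scale matched to the fixture's small raster (see
#'   [fixture_config()]).
#' @return Invisibly, the list of written paths.
#' @export
make_fixture <- function(dir, spec = phantom_spec(),
                         config = fixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_ground_truth(spec, config)
  movie <- simulate_movie(truth$reference, truth, spec)
  paths <- list(movie = file.path(dir, "movie.mrcs"),
                params = file.path(dir, "truth_spline.json"),
                drift = file.path(dir, "truth_drift.txt"),
                manifest = file.path(dir, "manifest.json"))
  write_mrc(movie$frames, paths$movie, spec$pixel_size)
  export_spline_parameters(truth$grid,
                           list(nx = spec$nx, ny = spec$ny,
                                pixel_size = spec$pixel_size, NF = spec$NF,
                                exposure_per_frame = spec$exposure_per_frame),
                           paths$params)
  utils::write.table(data.frame(frame = seq_len(spec$NF),
                                x_px = truth$drift[, 1],
                                y_px = truth$drift[, 2]),
                     paths$drift, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(spec)[setdiff(names(spec), "")],
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
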