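# ---- Pipeline orchestration ------------------------------------------------
#
# The four-stage correction: (1) full-frame alignment, (2) patch alignment,
# (3) least-squares spline fit, (4) cross-correlation refinement plus
# pixel-wise warping and frame summation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the local motion-correction pipeline on a movie
#'
#' Fourier-crops the movie to the output pixel size, aligns full frames
#' (with IQR outlier re-alignment), aligns overlapping patches, fits and
#' refines the 3D spline deformation model, and sums the per-pixel-warped
#' frames into the corrected micrograph. With a single patch the pipeline
#' degenerates to full-frame-only correction with a notice.
#'
#' @param movie A [movie_stack()].
#' @param config A [run_config()].
#' @param verbose Print stage-tagged progress lines.
#' @return An object of class \code{unbend_result}: \code{micrograph}
#'   (corrected), \code{fullframe_micrograph} (global alignment only),
#'   \code{trajectory}, \code{patch_grid}, \code{patch_shifts},
#'   \code{model}, \code{fit_l1}, \code{fit_l2}, \code{patch_stats},
#'   \code{config}.
#' @export
unbend <- function(movie, config = run_config(), verbose = FALSE) {
  say <- function(stage, ...) {
    if (verbose) message("[", stage, "] ", ...)
  }
  say("crop", "Fourier crop to ", config$output_pixel_size, " A/px")
  work <- fourier_crop(movie, config$output_pixel_size)
  say("fullframe", "aligning ", work$NF, " frames of ",
      work$nx, "x", work$ny)
  traj <- align_full_frames(work, config)
  traj <- resolve_shift_outliers(work, traj, config)
  patch_size <- config$patch_size %||% choose_patch_size(work$pixel_size)
  grid <- build_patch_grid(work$nx, work$ny, patch_size,
                           config$patch_nx, config$patch_ny)
  fullframe_mic <- sum_corrected_frames(work, traj, NULL)
  if (grid$np_x * grid$np_y < 2) {
    message("single patch: no local information; full-frame output only")
    return(structure(list(micrograph = fullframe_mic,
                          fullframe_micrograph = fullframe_mic,
                          trajectory = traj, patch_grid = grid,
                          patch_shifts = NULL, model = NULL,
                          fit_l1 = NULL, fit_l2 = NULL,
                          patch_stats = NULL, config = config,
                          working = list(nx = work$nx, ny = work$ny,
                                         pixel_size = work$pixel_size,
                                         NF = work$NF)),
                     class = "unbend_result"))
  }
  say("patch", grid$np_x, "x", grid$np_y, " patches of ",
      grid$patch_size, " px")
  shifts <- align_patch_stacks(work, traj, grid, config)
  shifts <- replace_patch_outliers(shifts, grid, config$iqr_factor)
  knots <- build_default_knot_grid(grid$np_x, grid$np_y, work$NF,
                                   work$exposure_per_frame,
                                   work$nx, work$ny, config)
  say("spline", length(knots$x_positions), "x", length(knots$y_positions),
      "x", length(knots$z_positions), " knots")
  fit1 <- fit_spline_l1(shifts, knots, grid$centers)
  say("refine", "L1 residual ", signif(fit1$l1_residual, 4), " px^2")
  fit2 <- refine_spline_l2(work, fit1$grid, grid, config, traj)
  say("refine", "L2 ", signif(fit2$l2_value, 6), " after ",
      fit2$iterations, " evaluations")
  mic <- sum_corrected_frames(work, traj, fit2$grid)
  structure(list(micrograph = mic, fullframe_micrograph = fullframe_mic,
                 trajectory = traj, patch_grid = grid,
                 patch_shifts = shifts, model = fit2$grid,
                 fit_l1 = fit1, fit_l2 = fit2,
                 patch_stats = patch_displacement_stats(shifts,
                                                        work$pixel_size),
                 config = config,
                 working = list(nx = work$nx, ny = work$ny,
                                pixel_size = work$pixel_size,
                                NF = work$NF)),
            class = "unbend_result")
}

#' @export
print.unbend_result <- function(x, ...) {
  cat(sprintf("unbend_result: %d x %d micrograph at %.4g A/px\n",
              x$micrograph$nx, x$micrograph$ny, x$micrograph$pixel_size))
  if (!is.null(x$patch_stats)) {
    cat(sprintf("  patch displacement (A): max %.2f, mean %.2f, sd %.2f\n",
                x$patch_stats$max, x$patch_stats$mean, x$patch_stats$sd))
  }
  invisible(x)
}

#' File-to-file pipeline run with artifacts and manifest
#'
#' Reads a movie, runs [unbend()], and writes the corrected micrograph,
#' trajectory and patch tables, the spline parameter file, and a JSON run
#' manifest (resolved parameters, package version, seed, input checksum,
#' per-stage timing). Partial outputs are removed if a stage fails.
#'
#' @param input Path to an MRC/MRCS movie.
#' @param output_dir Output directory.
#' @param pixel_size Pixel size override (A/pixel); required if absent from
#'   the header.
#' @param exposure_per_frame Exposure per frame (e-/A^2).
#' @param config A [run_config()].
#' @param seed Seed recorded in the manifest (the correction itself is
#'   deterministic).
#' @param verbose Progress lines to stderr.
#' @return Invisibly, the list of written paths.
#' @export
run_unbend <- function(input, output_dir, pixel_size = NULL,
                       exposure_per_frame = 0, config = run_config(),
                       seed = NULL, verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  movie <- read_movie(input, pixel_size_override = pixel_size,
                      exposure_per_frame = exposure_per_frame)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(micrograph = file.path(output_dir, "corrected.mrc"),
                trajectory = file.path(output_dir, "trajectory.txt"),
                patches = file.path(output_dir, "patches.txt"),
                params = file.path(output_dir, "spline_parameters.json"),
                manifest = file.path(output_dir, "manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(unlist(paths)), add = TRUE)
  res <- unbend(movie, config, verbose = verbose)
  write_image(res$micrograph, paths$micrograph)
  write_trajectory_table(res$trajectory, res$working$pixel_size,
                         paths$trajectory)
  if (!is.null(res$patch_shifts)) {
    write_patch_table(res$patch_shifts, res$patch_grid,
                      res$working$pixel_size, paths$patches)
  }
  if (!is.null(res$model)) {
    export_spline_parameters(res$model,
                             list(nx = res$working$nx, ny = res$working$ny,
                                  pixel_size = res$working$pixel_size,
                                  NF = res$working$NF,
                                  exposure_per_frame = exposure_per_frame),
                             paths$params)
  }
  manifest <- list(
    package = "unbendr",
    version = as.character(utils::packageVersion("unbendr")),
    input = normalizePath(input),
    input_md5 = unname(tools::md5sum(input)),
    seed = seed,
    parameters = unclass(config),
    working = res$working,
    patch_stats = if (is.null(res$patch_stats)) NULL else
      res$patch_stats[c("max", "mean", "sd")],
    elapsed_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  ok <- TRUE
  invisible(paths)
}
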