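# ---- Full-frame alignment --------------------------------------------------
#
# Iterative leave-one-out cross-correlation alignment: each frame is aligned
# against the sum of all other frames shifted by their current estimates,
# over three passes with the resolution limit of the correlation relaxed from
# half to three-quarters to the full working Nyquist. Both images are
# down-weighted with a large B-factor to suppress high-resolution noise.

#' Shift trajectory
#'
#' Per-frame (x, y) shifts in working pixels. The gauge convention is
#' zero mean over frames (applying a constant shift to every frame leaves
#' the relative alignment unchanged).
#'
#' @param shifts NF x 2 numeric matrix (columns x, y).
#' @param flagged Optional logical vector marking outlier-re-aligned frames.
#' @return An object of class \code{shift_trajectory}.
#' @export
shift_trajectory <- function(shifts, flagged = NULL) {
  shifts <- as.matrix(shifts)
  stopifnot(ncol(shifts) == 2, all(is.finite(shifts)))
  colnames(shifts) <- c("x", "y")
  if (is.null(flagged)) flagged <- rep(FALSE, nrow(shifts))
  structure(list(shifts = shifts, flagged = flagged),
            class = "shift_trajectory")
}

#' @export
print.shift_trajectory <- function(x, ...) {
  cat(sprintf("shift_trajectory: %d frames, max |shift| = %.3f px, %d flagged\n",
              nrow(x$shifts), max(abs(x$shifts)), sum(x$flagged)))
  invisible(x)
}

# Weight map for CC alignment: B-factor times a hard resolution cutoff given
# as a fraction of Nyquist (0.5 cycles/pixel); DC retained here (the peak
# location is insensitive to a constant offset of the map).
cc_weights <- function(nx, ny, bfactor, pixel_size, res_frac = 1) {
  w <- bfactor_weights(nx, ny, bfactor, pixel_size)
  if (res_frac < 1) {
    g <- freq_grids(nx, ny)
    w[g$kx^2 + g$ky^2 > (0.5 * res_frac)^2] <- 0
  }
  w
}

# Leave-one-out CC alignment engine shared by the full-frame and patch
# stages. frames: array c(nx, ny, NF). Returns NF x 2 shifts (no gauge fix).
loo_align <- function(frames, bfactor, pixel_size, iterations = 3,
                      res_schedule = c(0.5, 0.75, 1),
                      init = NULL) {
  nx <- dim(frames)[1]; ny <- dim(frames)[2]; NF <- dim(frames)[3]
  fts <- vector("list", NF)
  for (f in seq_len(NF)) {
    fr <- frames[, , f]
    if (stats::sd(fr) == 0) stop("no signal: frame ", f, " has zero variance")
    fts[[f]] <- stats::fft(fr)
  }
  a <- freq_axes(nx, ny)
  sh <- if (is.null(init)) matrix(0, NF, 2) else init
  for (it in seq_len(iterations)) {
    w <- cc_weights(nx, ny, bfactor, pixel_size,
                    res_schedule[min(it, length(res_schedule))])
    ramps <- lapply(seq_len(NF),
                    function(f) ramp_outer(a$kx, a$ky, sh[f, 1], sh[f, 2]))
    S <- Reduce(`+`, Map(function(ft, r) ft * r, fts, ramps))
    # simultaneous (Jacobi) sweep: every frame is aligned against the same
    # reference state, which keeps the trajectory's neutral gauge mode (a
    # constant shift of all frames) where the iteration started
    new_sh <- sh
    for (f in seq_len(NF)) {
      R <- S - fts[[f]] * ramps[[f]]
      cc <- Re(stats::fft(Conj(R) * fts[[f]] * w, inverse = TRUE))
      new_sh[f, ] <- cc_peak_subpixel(cc)
    }
    sh <- new_sh
  }
  sh
}

# Single-frame leave-one-out shift from precomputed spectra.
loo_shift_one <- function(fts, axes, shifts, frame_index, w) {
  S <- 0
  for (f in seq_along(fts)) {
    if (f == frame_index) next
    S <- S + fts[[f]] * ramp_outer(axes$kx, axes$ky, shifts[f, 1],
                                   shifts[f, 2])
  }
  cc <- Re(stats::fft(Conj(S) * fts[[frame_index]] * w, inverse = TRUE))
  cc_peak_subpixel(cc)
}

#' Leave-one-out cross-correlation shift of one frame
#'
#' Locates the subpixel peak of the B-factor-weighted cross-correlation map
#' between one frame and the sum of all other frames, each shifted by its
#' current estimate. Subpixel localization by separable parabolic fits
#' around the integer peak.
#'
#' @param movie A [movie_stack()].
#' @param current_shifts A [shift_trajectory()] with the running estimates.
#' @param frame_index Frame to align (1-based).
#' @param bfactor B-factor in A^2.
#' @param res_frac Resolution limit of the correlation as a fraction of the
#'   Nyquist frequency.
#' @return Numeric \code{c(x, y)} shift in pixels.
#' @export
cc_shift_leave_one_out <- function(movie, current_shifts, frame_index,
                                   bfactor, res_frac = 1) {
  stopifnot(inherits(movie, "movie_stack"),
            frame_index >= 1, frame_index <= movie$NF)
  for (f in seq_len(movie$NF)) {
    if (stats::sd(movie$frames[, , f]) == 0) {
      stop("no signal: frame ", f, " has zero variance")
    }
  }
  fts <- lapply(seq_len(movie$NF),
                function(f) stats::fft(movie$frames[, , f]))
  w <- cc_weights(movie$nx, movie$ny, bfactor, movie$pixel_size, res_frac)
  loo_shift_one(fts, freq_axes(movie$nx, movie$ny), current_shifts$shifts,
                frame_index, w)
}

#' Align full frames of a movie
#'
#' Three iterations of leave-one-out cross-correlation alignment with the
#' resolution limit relaxed from 1/2 to 3/4 to the full working Nyquist.
#' The returned trajectory has zero mean over frames.
#'
#' @param movie A [movie_stack()] at the working (output) sampling.
#' @param config A [run_config()].
#' @return A [shift_trajectory()].
#' @export
align_full_frames <- function(movie, config = run_config()) {
  stopifnot(inherits(movie, "movie_stack"))
  sh <- loo_align(movie$frames, config$bfactor_initial, movie$pixel_size)
  sh <- sweep(sh, 2, colMeans(sh))
  shift_trajectory(sh)
}

#' Savitzky-Golay smoothing of a shift trajectory
#'
#' Smooths the x and y series independently with a Savitzky-Golay filter;
#' endpoints are handled by the polynomial fit on the truncated window.
#'
#' @param traj A [shift_trajectory()].
#' @param window Odd window length (<= number of frames).
#' @param order Polynomial order (< window).
#' @return The smoothed [shift_trajectory()].
#' @export
sg_smooth <- function(traj, window = 11, order = 3) {
  NF <- nrow(traj$shifts)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > NF) stop("window exceeds the number of frames")
  if (order >= window) stop("order must be < window")
  sm <- apply(traj$shifts, 2,
              function(v) signal::sgolayfilt(v, p = order, n = window))
  shift_trajectory(sm, traj$flagged)
}

# Effective SG window for NF frames: min(11, NF rounded down to odd).
default_sg_window <- function(NF, window = 11) {
  w <- min(window, if (NF %% 2 == 1) NF else NF - 1)
  if (w %% 2 == 0) w <- w - 1
  max(w, 3)
}

#' Detect and re-align outlier frames of a full-frame trajectory
#'
#' The raw trajectory is compared with its Savitzky-Golay-smoothed curve;
#' frames whose Euclidean deviation from the curve exceeds
#' \code{iqr_factor} times the interquartile range of all deviations are
#' re-aligned with twice the initial B-factor. A re-aligned shift still
#' deviating beyond the same bound is discarded and the raw shift accepted
#' as real motion; otherwise the re-aligned value replaces it. Unflagged
#' frames always keep their raw shifts; smoothing itself is not applied
#' unless \code{config$sg_enabled} is set. Deviations below an absolute
#' floor of 0.05 px (well under the alignment precision) are never flagged.
#'
#' @param movie The [movie_stack()] the trajectory came from.
#' @param raw A [shift_trajectory()] from [align_full_frames()].
#' @param config A [run_config()].
#' @return A [shift_trajectory()] with \code{flagged} marking re-aligned
#'   frames.
#' @export
resolve_shift_outliers <- function(movie, raw, config = run_config()) {
  NF <- nrow(raw$shifts)
  if (NF < 5) {
    message("fewer than 5 frames: IQR outlier step skipped")
    return(raw)
  }
  w <- default_sg_window(NF, config$sg_window)
  curve <- sg_smooth(raw, window = w, order = min(config$sg_order, w - 1))
  dev <- sqrt(rowSums((raw$shifts - curve$shifts)^2))
  iqr <- stats::IQR(dev)
  # absolute floor: deviations far below alignment precision (0.05 px) are
  # never outliers, whatever the relative spread
  bound <- max(config$iqr_factor * iqr, 0.05)
  flagged <- dev > bound
  out <- raw$shifts
  if (any(flagged)) {
    fts <- lapply(seq_len(movie$NF),
                  function(f) stats::fft(movie$frames[, , f]))
    axes <- freq_axes(movie$nx, movie$ny)
    w <- cc_weights(movie$nx, movie$ny, 2 * config$bfactor_initial,
                    movie$pixel_size)
    for (f in which(flagged)) {
      refined <- loo_shift_one(fts, axes, out, f, w)
      new_dev <- sqrt(sum((refined - curve$shifts[f, ])^2))
      if (new_dev <= bound) out[f, ] <- refined
    }
  }
  traj <- shift_trajectory(out, flagged)
  if (config$sg_enabled) {
    sm <- sg_smooth(traj, window = w, order = min(config$sg_order, w - 1))
    traj <- shift_trajectory(sm$shifts, flagged)
  }
  traj
}

#' Write a trajectory table beside the micrograph
#'
#' One row per frame: frame index, shift in Angstroms on both axes, and the
#' outlier flag. Shifts follow the zero-mean gauge over frames.
#'
#' @param traj A [shift_trajectory()].
#' @param pixel_size Working pixel size (A/pixel) for unit conversion.
#' @param path Output path (tab-separated text).
#' @export
write_trajectory_table <- function(traj, pixel_size, path) {
  df <- data.frame(frame = seq_len(nrow(traj$shifts)),
                   x_A = traj$shifts[, 1] * pixel_size,
                   y_A = traj$shifts[, 2] * pixel_size,
                   flagged = traj$flagged)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
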