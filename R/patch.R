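# ---- Patch alignment -------------------------------------------------------
#
# After full-frame alignment has removed the average motion, overlapping
# square patches are aligned independently over frames with the same
# leave-one-out engine; their trajectories are the local deformation
# residuals that the spline model is fitted to.

#' Default patch size from the output pixel size
#'
#' 1024 px below 0.5 A/pixel, 512 px between 0.5 and 2.0 A/pixel, and above
#' 2.0 A/pixel the 512-px patch scaled by the pixel size and rounded up to
#' the nearest multiple of 16.
#'
#' @param output_pixel_size Output pixel size in A/pixel.
#' @return Patch edge length in pixels.
#' @export
choose_patch_size <- function(output_pixel_size) {
  stopifnot(output_pixel_size > 0)
  if (output_pixel_size < 0.5) return(1024L)
  if (output_pixel_size <= 2.0) return(512L)
  as.integer(ceiling(512 * output_pixel_size / 16) * 16)
}

#' Build the patch grid for an image
#'
#' Default patch counts are the image dimensions divided by the patch size,
#' rounded up, which minimizes overlap while covering every pixel. Requesting
#' fewer patches enlarges them to \code{ceiling(dim / np)} so coverage is
#' kept without gaps; requesting more patches keeps the default size and
#' increases the overlap. Centers are spread evenly from a half-patch inset
#' to the opposite edge.
#'
#' @param nx,ny Image dimensions in pixels.
#' @param patch_size Square patch edge in pixels.
#' @param np_x,np_y Optional overrides of the per-axis patch counts.
#' @return An object of class \code{patch_grid} with fields
#'   \code{patch_size}, \code{np_x}, \code{np_y}, \code{centers} (NP x 2,
#'   0-based pixel coordinates, x varying fastest) and \code{starts}
#'   (NP x 2 integer crop offsets).
#' @export
build_patch_grid <- function(nx, ny, patch_size,
                             np_x = NULL, np_y = NULL) {
  stopifnot(patch_size >= 2)
  def_x <- ceiling(nx / patch_size)
  def_y <- ceiling(ny / patch_size)
  if (is.null(np_x)) np_x <- def_x
  if (is.null(np_y)) np_y <- def_y
  if (np_x < 1 || np_y < 1) stop("patch count override must be >= 1")
  size <- patch_size
  if (np_x < def_x || np_y < def_y) {
    size <- max(ceiling(nx / np_x) * (np_x < def_x),
                ceiling(ny / np_y) * (np_y < def_y), patch_size)
  }
  size <- min(size, nx, ny)
  centers_axis <- function(dim, np) {
    if (np == 1) (dim - 1) / 2
    else seq((size - 1) / 2, dim - 1 - (size - 1) / 2, length.out = np)
  }
  cx <- centers_axis(nx, np_x)
  cy <- centers_axis(ny, np_y)
  centers <- as.matrix(expand.grid(x = cx, y = cy))
  starts <- cbind(pmin(pmax(round(centers[, 1] - (size - 1) / 2), 0),
                       nx - size),
                  pmin(pmax(round(centers[, 2] - (size - 1) / 2), 0),
                       ny - size))
  structure(list(patch_size = as.integer(size),
                 np_x = as.integer(np_x), np_y = as.integer(np_y),
                 centers = centers, starts = starts),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch_grid: %d x %d patches of %d px\n",
              x$np_x, x$np_y, x$patch_size))
  invisible(x)
}

#' Per-patch, per-frame shift set
#'
#' @param x,y NP x NF matrices of shifts in pixels.
#' @param replaced Logical NP vector marking patches whose shift set was
#'   substituted from a neighbor.
#' @param zero_signal Logical NP vector marking flat patches aligned to zero.
#' @return An object of class \code{patch_shift_set}.
#' @export
patch_shift_set <- function(x, y, replaced = NULL, zero_signal = NULL) {
  stopifnot(all(dim(x) == dim(y)), all(is.finite(x)), all(is.finite(y)))
  np <- nrow(x)
  if (is.null(replaced)) replaced <- rep(FALSE, np)
  if (is.null(zero_signal)) zero_signal <- rep(FALSE, np)
  structure(list(x = x, y = y, replaced = replaced,
                 zero_signal = zero_signal),
            class = "patch_shift_set")
}

#' @export
print.patch_shift_set <- function(x, ...) {
  cat(sprintf("patch_shift_set: %d patches x %d frames, %d replaced\n",
              nrow(x$x), ncol(x$x), sum(x$replaced)))
  invisible(x)
}

# Apply a global trajectory to a movie: every frame is shifted by its
# (subpixel) estimate in Fourier space.
apply_global_alignment <- function(movie, traj) {
  out <- movie$frames
  for (f in seq_len(movie$NF)) {
    s <- traj$shifts[f, ]
    if (any(s != 0)) out[, , f] <- fourier_shift_image(out[, , f], s[1], s[2])
  }
  movie_stack(out, movie$pixel_size, movie$exposure_per_frame)
}

# Crop the patch stacks (list of c(size, size, NF) arrays) out of a
# globally-aligned frame array.
extract_patch_stacks <- function(frames, grid) {
  size <- grid$patch_size
  lapply(seq_len(nrow(grid$starts)), function(p) {
    x0 <- grid$starts[p, 1]; y0 <- grid$starts[p, 2]
    frames[(x0 + 1):(x0 + size), (y0 + 1):(y0 + size), , drop = FALSE]
  })
}

#' Align all patch stacks of a movie
#'
#' Frames are first shifted by the global trajectory; each patch stack is
#' then aligned with the same leave-one-out cross-correlation engine and
#' B-factor as the full-frame stage, and every patch trajectory is smoothed
#' with a Savitzky-Golay filter. The returned shifts are deformation
#' residuals after global alignment. Patches with zero variance are set to
#' zero shifts and flagged.
#'
#' @param movie A [movie_stack()] at the working sampling.
#' @param global_traj The full-frame [shift_trajectory()].
#' @param grid A [patch_grid()].
#' @param config A [run_config()].
#' @return A [patch_shift_set()].
#' @export
align_patch_stacks <- function(movie, global_traj, grid,
                               config = run_config()) {
  aligned <- apply_global_alignment(movie, global_traj)
  stacks <- extract_patch_stacks(aligned$frames, grid)
  NF <- movie$NF
  np <- length(stacks)
  sx <- matrix(0, np, NF)
  sy <- matrix(0, np, NF)
  zero_signal <- rep(FALSE, np)
  w <- default_sg_window(NF, config$sg_window)
  ord <- min(config$sg_order, w - 1)
  for (p in seq_len(np)) {
    if (all(abs(stacks[[p]] - mean(stacks[[p]])) < 1e-12)) {
      zero_signal[p] <- TRUE
      next
    }
    sh <- loo_align(stacks[[p]], config$bfactor_initial, movie$pixel_size)
    sm <- sg_smooth(shift_trajectory(sh), window = w, order = ord)
    sx[p, ] <- sm$shifts[, 1]
    sy[p, ] <- sm$shifts[, 2]
  }
  patch_shift_set(sx, sy, zero_signal = zero_signal)
}

#' Detect and replace unreliable patch trajectories
#'
#' For each patch the Euclidean shift difference between neighboring frames
#' \code{dS_fi = sqrt((x_{fi+1}-x_fi)^2 + (y_{fi+1}-y_fi)^2)} is computed,
#' and its sample standard deviation \code{sigma(pi)} summarizes the
#' trajectory jitter. Patches with \code{sigma} above
#' \code{Q3 + iqr_factor * IQR} of all sigmas have their whole shift set
#' replaced by that of the geometrically nearest non-outlier patch (ties
#' broken by lower patch index). Zero-signal patches are treated as
#' outliers.
#'
#' @param shifts A [patch_shift_set()].
#' @param grid The matching [patch_grid()].
#' @param iqr_factor IQR multiplier (default 1.5).
#' @return The repaired [patch_shift_set()] with \code{replaced} updated.
#' @export
replace_patch_outliers <- function(shifts, grid, iqr_factor = 1.5) {
  np <- nrow(shifts$x)
  if (np < 4) {
    message("fewer than 4 patches: outlier replacement skipped")
    return(shifts)
  }
  sigma <- vapply(seq_len(np), function(p) {
    dS <- sqrt(diff(shifts$x[p, ])^2 + diff(shifts$y[p, ])^2)
    stats::sd(dS)
  }, numeric(1))
  q <- stats::quantile(sigma, c(0.25, 0.75), names = FALSE)
  bound <- q[2] + iqr_factor * (q[2] - q[1])
  bad <- sigma > bound | shifts$zero_signal
  if (!any(bad)) return(shifts)
  if (all(bad)) stop("no reliable patch: every patch trajectory is an outlier")
  good <- which(!bad)
  out <- shifts
  for (p in which(bad)) {
    d2 <- (grid$centers[good, 1] - grid$centers[p, 1])^2 +
      (grid$centers[good, 2] - grid$centers[p, 2])^2
    nn <- good[which.min(d2)]          # which.min takes the first = lower index
    out$x[p, ] <- shifts$x[nn, ]
    out$y[p, ] <- shifts$y[nn, ]
    out$replaced[p] <- TRUE
  }
  out
}

#' Per-patch displacement statistics
#'
#' Displacement of each patch's last frame relative to its first frame,
#' converted to Angstroms, with the maximum, mean and standard deviation
#' over patches.
#'
#' @param shifts A [patch_shift_set()].
#' @param pixel_size Working pixel size in A/pixel.
#' @return List with \code{sh} (per-patch displacements, A), \code{max},
#'   \code{mean} and \code{sd}.
#' @export
patch_displacement_stats <- function(shifts, pixel_size) {
  NF <- ncol(shifts$x)
  sh <- sqrt((shifts$x[, NF] - shifts$x[, 1])^2 +
               (shifts$y[, NF] - shifts$y[, 1])^2) * pixel_size
  list(sh = sh, max = max(sh), mean = mean(sh), sd = stats::sd(sh))
}

#' Write the per-patch trajectory table
#'
#' @param shifts A [patch_shift_set()].
#' @param grid The matching [patch_grid()].
#' @param pixel_size Working pixel size (A/pixel).
#' @param path Output path (tab-separated text; one row per patch and frame).
#' @export
write_patch_table <- function(shifts, grid, pixel_size, path) {
  np <- nrow(shifts$x); NF <- ncol(shifts$x)
  df <- data.frame(patch = rep(seq_len(np), each = NF),
                   center_x = rep(grid$centers[, 1], each = NF),
                   center_y = rep(grid$centers[, 2], each = NF),
                   frame = rep(seq_len(NF), np),
                   x_A = as.vector(t(shifts$x)) * pixel_size,
                   y_A = as.vector(t(shifts$y)) * pixel_size,
                   replaced = rep(shifts$replaced, each = NF))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
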