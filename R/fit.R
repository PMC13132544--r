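# ---- Spline model refinement ----------------------------------------------
#
# Stage 3: least-squares fit of the knot values to the measured patch shifts
# (linear in the knot values, solved exactly per axis). Stage 4: refinement
# against the image data by maximizing the summed leave-one-out
# cross-correlation of spline-shifted patch frames, optimized with L-BFGS
# and an analytic gradient from the Fourier shift theorem.

# Design matrix of the spline model for all (patch, frame) combinations:
# rows ordered patch-fastest within each frame.
l1_design_matrix <- function(grid, centers, NF) {
  do.call(rbind, lapply(seq_len(NF), function(fi) {
    spline_design_rows(grid, centers[, 1], centers[, 2], fi)
  }))
}

#' Fit the spline model to patch shifts (least squares)
#'
#' Minimizes the summed squared difference between measured per-patch,
#' per-frame shifts and the spline prediction at each patch center. The
#' prediction is linear in the knot values, so the x and y problems are two
#' independent linear least-squares solves. A rank-deficient design (too few
#' patches/frames for the knot grid) is ridge-stabilized with a warning.
#'
#' @param patch_shifts A [patch_shift_set()].
#' @param grid A [knot_grid_3d()] giving the knot layout (values ignored).
#' @param patch_centers NP x 2 matrix of patch center coordinates (pixels).
#' @return List of class \code{spline_fit_result}: \code{grid} with fitted
#'   \code{Kx}, \code{Ky}; \code{l1_residual} (attained loss, px^2);
#'   \code{converged}.
#' @export
fit_spline_l1 <- function(patch_shifts, grid, patch_centers) {
  np <- nrow(patch_shifts$x); NF <- ncol(patch_shifts$x)
  stopifnot(nrow(patch_centers) == np)
  if (stats::sd(patch_centers[, 1]) == 0 && stats::sd(patch_centers[, 2]) == 0
      && np > 1) {
    stop("degenerate design: all patches colocated")
  }
  J <- l1_design_matrix(grid, patch_centers, NF)
  obs_x <- as.vector(patch_shifts$x)   # patch-fastest, frame-major
  obs_y <- as.vector(patch_shifts$y)
  qrJ <- qr(J)
  if (qrJ$rank < ncol(J)) {
    warning("under-determined spline fit (", nrow(J), " observations for ",
            ncol(J), " knot values per axis); ridge-stabilized")
    A <- crossprod(J) + diag(1e-8, ncol(J))
    kx <- solve(A, crossprod(J, obs_x))
    ky <- solve(A, crossprod(J, obs_y))
  } else {
    kx <- qr.coef(qrJ, obs_x)
    ky <- qr.coef(qrJ, obs_y)
  }
  dims <- dim(grid$Kx)
  out <- grid
  out$Kx <- array(kx, dims)
  out$Ky <- array(ky, dims)
  res <- sum((J %*% kx - obs_x)^2) + sum((J %*% ky - obs_y)^2)
  structure(list(grid = out, l1_residual = res, l2_value = NA_real_,
                 iterations = 0L, converged = TRUE),
            class = "spline_fit_result")
}

#' @export
print.spline_fit_result <- function(x, ...) {
  cat(sprintf("spline_fit_result: L1 = %.4g px^2, L2 = %.6g, %d iterations\n",
              x$l1_residual, x$l2_value, x$iterations))
  invisible(x)
}

# Frequency axes of a spectrum cropped from (nx, ny) to (mx, my): values in
# cycles per *original* pixel so that shifts stay in working pixels.
cropped_freq_axes <- function(nx, ny, mx, my) {
  list(kx = c(0:(ceiling(mx / 2) - 1), -(floor(mx / 2)):-1) / nx,
       ky = c(0:(ceiling(my / 2) - 1), -(floor(my / 2)):-1) / ny)
}

# Precompute the cross-correlation context for the L2 objective: per patch,
# the B-factor-weighted, band-limited spectra of every (globally aligned)
# patch frame, with the DC term removed so the correlation is zero-mean.
# The spectra are cropped to half Nyquist: the alignment B-factor leaves no
# usable amplitude beyond it and the crop cuts the work fourfold.
l2_context <- function(stacks, grid, centers, pixel_size, config) {
  NF <- dim(stacks[[1]])[3]
  n <- dim(stacks[[1]])[1]
  m <- max(16, floor(n / 4) * 2)          # half-Nyquist band limit
  ix <- crop_indices(n, m)
  axes <- cropped_freq_axes(n, n, m, m)
  g <- list(kx = matrix(axes$kx, m, m),
            ky = matrix(axes$ky, m, m, byrow = TRUE))
  w <- exp(-config$bfactor_initial * (g$kx^2 + g$ky^2) / pixel_size^2 / 4)
  w[1, 1] <- 0                            # zero-mean correlation
  keep <- vapply(stacks, function(s) stats::sd(as.vector(s)) > 1e-12,
                 logical(1))
  if (!all(keep)) message(sum(!keep), " flat patch(es) dropped from L2")
  fts <- lapply(stacks[keep], function(s) {
    lapply(seq_len(NF), function(f) stats::fft(s[, , f])[ix, ix] * w)
  })
  J <- l1_design_matrix(grid, centers, NF)    # rows: (patch, frame)
  list(fts = fts, keep = keep, J = J, g = g, axes = axes, NF = NF,
       np = sum(keep), n_knots = ncol(J))
}

# L2 objective and analytic gradient. par = c(Kx, Ky) as vectors.
l2_fn_gr <- function(ctx) {
  NF <- ctx$NF
  np_all <- length(ctx$keep)
  kept <- which(ctx$keep)
  twopi_kx <- 2 * pi * ctx$g$kx
  twopi_ky <- 2 * pi * ctx$g$ky
  shifts_from_par <- function(par) {
    nk <- ctx$n_knots
    sx <- matrix(ctx$J %*% par[1:nk], np_all, NF)
    sy <- matrix(ctx$J %*% par[(nk + 1):(2 * nk)], np_all, NF)
    list(sx = sx, sy = sy)
  }
  evaluate <- function(par, want_grad) {
    s <- shifts_from_par(par)
    val <- 0
    gsx <- matrix(0, np_all, NF)
    gsy <- matrix(0, np_all, NF)
    for (ip in seq_along(kept)) {
      p <- kept[ip]
      a <- vector("list", NF)
      n1 <- numeric(NF)
      for (f in seq_len(NF)) {
        ramp <- ramp_outer(ctx$axes$kx, ctx$axes$ky, s$sx[p, f], s$sy[p, f])
        a[[f]] <- ctx$fts[[ip]][[f]] * ramp
        n1[f] <- sqrt(sum(Mod(a[[f]])^2))
      }
      S <- Reduce(`+`, a)
      R <- lapply(a, function(af) S - af)
      cval <- vapply(seq_len(NF),
                     function(f) sum(Re(a[[f]] * Conj(R[[f]]))), numeric(1))
      n2 <- vapply(R, function(r) sqrt(sum(Mod(r)^2)), numeric(1))
      ok <- n1 > 0 & n2 > 0
      if (!all(ok)) next
      val <- val - sum(cval / (n1 * n2))
      if (want_grad) {
        A <- Reduce(`+`, lapply(seq_len(NF),
                                function(f) a[[f]] / (n1[f] * n2[f])))
        B <- Reduce(`+`, lapply(seq_len(NF),
                                function(f) cval[f] * R[[f]] / (n1[f] * n2[f]^3)))
        for (f in seq_len(NF)) {
          inner <- R[[f]] / (n1[f] * n2[f]) + A - B -
            a[[f]] / (n1[f] * n2[f]) + cval[f] * R[[f]] / (n1[f] * n2[f]^3)
          z <- Im(a[[f]] * Conj(inner))
          gsx[p, f] <- sum(twopi_kx * z)
          gsy[p, f] <- sum(twopi_ky * z)
        }
      }
    }
    grad <- NULL
    if (want_grad) {
      grad <- c(crossprod(ctx$J, as.vector(gsx)),
                crossprod(ctx$J, as.vector(gsy)))
    }
    list(value = val, grad = grad)
  }
  list(fn = function(par) evaluate(par, FALSE)$value,
       gr = function(par) evaluate(par, TRUE)$grad)
}

#' Refine the spline model against the image data
#'
#' Minimizes the negative sum over patches and frames of the zero-mean
#' normalized cross-correlation between each patch frame, rigidly shifted by
#' the spline prediction at the patch center, and the leave-one-out average
#' of the other shifted frames of the same patch stack. Patch shifts are
#' applied as Fourier phase ramps; the objective is optimized with L-BFGS
#' using the analytic gradient from the shift theorem. Patches with stronger
#' signal yield larger correlation magnitudes and so weigh more. Flat
#' patches are dropped with a notice.
#'
#' @param movie A [movie_stack()] at the working sampling.
#' @param grid A [knot_grid_3d()] initialized by [fit_spline_l1()].
#' @param patch_grid A [patch_grid()].
#' @param config A [run_config()].
#' @param global_traj The full-frame [shift_trajectory()] used to align the
#'   frames before patch extraction.
#' @return A \code{spline_fit_result} with the refined grid, the final
#'   \code{l2_value}, iteration count and convergence flag.
#' @export
refine_spline_l2 <- function(movie, grid, patch_grid, config = run_config(),
                             global_traj = NULL) {
  if (is.null(global_traj)) {
    global_traj <- shift_trajectory(matrix(0, movie$NF, 2))
  }
  aligned <- apply_global_alignment(movie, global_traj)
  stacks <- extract_patch_stacks(aligned$frames, patch_grid)
  ctx <- l2_context(stacks, grid, patch_grid$centers, movie$pixel_size,
                    config)
  obj <- l2_fn_gr(ctx)
  par0 <- c(as.vector(grid$Kx), as.vector(grid$Ky))
  v0 <- obj$fn(par0)
  if (!is.finite(v0)) stop("non-finite objective at initialization")
  opt <- stats::optim(par0, obj$fn, obj$gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iter,
                                     factr = 1e-6 / .Machine$double.eps))
  par <- if (opt$value <= v0) opt$par else par0
  value <- min(opt$value, v0)
  nk <- ctx$n_knots
  out <- grid
  out$Kx <- array(par[1:nk], dim(grid$Kx))
  out$Ky <- array(par[(nk + 1):(2 * nk)], dim(grid$Ky))
  structure(list(grid = out, l1_residual = NA_real_, l2_value = value,
                 iterations = opt$counts[["function"]],
                 converged = opt$convergence == 0),
            class = "spline_fit_result")
}

# ---- Warping and summation -------------------------------------------------

#' Warp a frame by a per-pixel displacement field
#'
#' Pull-back warp with bilinear interpolation:
#' \code{out(p) = in(p + u(p))}, so measured shifts (where content has moved
#' to) map features back to their reference positions. Samples falling
#' outside the input raster take the average density of the nearest image
#' edge row/column; the output raster equals the input raster.
#'
#' @param frame Numeric matrix (nx x ny).
#' @param ux,uy Displacement field matrices (pixels), same dimensions.
#' @return The warped matrix.
#' @export
warp_frame <- function(frame, ux, uy) {
  nx <- nrow(frame); ny <- ncol(frame)
  stopifnot(all(dim(ux) == c(nx, ny)), all(dim(uy) == c(nx, ny)),
            all(is.finite(ux)), all(is.finite(uy)))
  px <- matrix(0:(nx - 1), nx, ny) + ux
  py <- matrix(0:(ny - 1), nx, ny, byrow = TRUE) + uy
  out_left <- px < 0; out_right <- px > nx - 1
  out_bot <- py < 0; out_top <- py > ny - 1
  x0 <- pmin(pmax(floor(px), 0), nx - 2)
  y0 <- pmin(pmax(floor(py), 0), ny - 2)
  fx <- pmin(pmax(px - x0, 0), 1)
  fy <- pmin(pmax(py - y0, 0), 1)
  i0 <- x0 + 1; j0 <- y0 + 1
  idx <- function(i, j) (j - 1) * nx + i
  v <- (1 - fx) * (1 - fy) * frame[idx(i0, j0)] +
    fx * (1 - fy) * frame[idx(i0 + 1, j0)] +
    (1 - fx) * fy * frame[idx(i0, j0 + 1)] +
    fx * fy * frame[idx(i0 + 1, j0 + 1)]
  v <- matrix(v, nx, ny)
  # out-of-raster samples: average density of the nearest edge line
  if (any(out_left)) v[out_left] <- mean(frame[1, ])
  if (any(out_right)) v[out_right] <- mean(frame[nx, ])
  if (any(out_bot)) v[out_bot] <- mean(frame[, 1])
  if (any(out_top)) v[out_top] <- mean(frame[, ny])
  v
}

#' Sum motion-corrected frames into a micrograph
#'
#' Each frame is warped by the sum of its global shift and the spline
#' deformation field for that frame, then the frames are averaged.
#'
#' @param movie A [movie_stack()] at the working sampling.
#' @param global_traj The full-frame [shift_trajectory()].
#' @param model A fitted [knot_grid_3d()]; NULL applies global shifts only.
#' @return A [micrograph()].
#' @export
sum_corrected_frames <- function(movie, global_traj, model = NULL) {
  acc <- matrix(0, movie$nx, movie$ny)
  for (f in seq_len(movie$NF)) {
    if (is.null(model)) {
      ux <- matrix(global_traj$shifts[f, 1], movie$nx, movie$ny)
      uy <- matrix(global_traj$shifts[f, 2], movie$nx, movie$ny)
    } else {
      field <- eval_shift_field(model, f, nx = movie$nx, ny = movie$ny)
      ux <- field$ux + global_traj$shifts[f, 1]
      uy <- field$uy + global_traj$shifts[f, 2]
    }
    acc <- acc + warp_frame(movie$frames[, , f], ux, uy)
  }
  micrograph(acc / movie$NF, movie$pixel_size)
}

# ---- Parameter export ------------------------------------------------------

SPLINE_PARAM_VERSION <- "unbendr-spline-1"

#' Export refined spline parameters
#'
#' Writes a versioned JSON parameter file (image geometry, frame count,
#' knot positions per axis, and the Kx/Ky knot values at full precision)
#' that [import_spline_parameters()] and the strain-field generator consume.
#'
#' @param model A [knot_grid_3d()].
#' @param meta List of run metadata; must include \code{nx}, \code{ny},
#'   \code{pixel_size}, \code{NF}.
#' @param path Output path.
#' @export
export_spline_parameters <- function(model, meta, path) {
  stopifnot(inherits(model, "knot_grid_3d"))
  need <- c("nx", "ny", "pixel_size", "NF")
  if (!all(need %in% names(meta))) {
    stop("meta must include: ", paste(setdiff(need, names(meta)),
                                      collapse = ", "))
  }
  # doubles are written with %.17g so that re-parsing reproduces them
  # bit-exactly (the shortest-representation guarantee of 17 significant
  # digits)
  num <- function(x) {
    s <- sprintf("%.17g", x)
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ", "), "]")
  }
  lines <- c(
    "{",
    sprintf('  "version": "%s",', SPLINE_PARAM_VERSION),
    sprintf('  "nx": %d, "ny": %d,', as.integer(meta$nx),
            as.integer(meta$ny)),
    sprintf('  "pixel_size": %s,', num(meta$pixel_size)),
    sprintf('  "NF": %d,', as.integer(meta$NF)),
    sprintf('  "exposure_per_frame": %s,',
            num(if (is.null(meta$exposure_per_frame)) 0 else
              meta$exposure_per_frame)),
    sprintf('  "x_positions": %s,', num(model$x_positions)),
    sprintf('  "y_positions": %s,', num(model$y_positions)),
    sprintf('  "z_positions": %s,', num(model$z_positions)),
    sprintf('  "dim": [%s],', paste(dim(model$Kx), collapse = ", ")),
    sprintf('  "Kx": %s,', num(as.vector(model$Kx))),
    sprintf('  "Ky": %s', num(as.vector(model$Ky))),
    "}")
  writeLines(lines, path)
  invisible(path)
}

#' Import spline parameters exported by [export_spline_parameters()]
#'
#' @param path Parameter file path.
#' @return List with \code{model} (a [knot_grid_3d()]) and \code{meta}.
#' @export
import_spline_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != SPLINE_PARAM_VERSION) {
    stop("parameter file version mismatch: expected ", SPLINE_PARAM_VERSION,
         ", got ", if (is.null(obj$version)) "<none>" else obj$version)
  }
  need <- c("nx", "ny", "pixel_size", "NF", "x_positions", "y_positions",
            "z_positions", "dim", "Kx", "Ky")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("parameter file missing field(s): ", paste(missing, collapse = ", "))
  }
  model <- knot_grid_3d(obj$x_positions, obj$y_positions, obj$z_positions,
                        Kx = array(obj$Kx, obj$dim),
                        Ky = array(obj$Ky, obj$dim))
  meta <- obj[c("nx", "ny", "pixel_size", "NF", "exposure_per_frame")]
  list(model = model, meta = meta)
}
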