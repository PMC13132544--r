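# ---- Uniform cubic B-spline machinery -------------------------------------
#
# The deformation model is a 3D tensor-product spline: a uniform cubic
# B-spline along the exposure (z) axis and a uniform bicubic surface in the
# image plane. The model is parameterized by *knot values* (the values the
# spline passes through); control points are recovered from them through the
# passing matrix with free-end boundary conditions (zero second difference of
# the outermost control points), which makes the spline extrapolate linearly
# beyond the boundary knots.

#' The 4x4 cubic B-spline blending matrix
#'
#' Constant matrix \code{M} such that one curve segment with local parameter
#' \code{t} in \[0, 1\] and control points \code{Q1..Q4} evaluates to
#' \code{(1/6) * c(t^3, t^2, t, 1) \%*\% M \%*\% Q}.
#'
#' @return A 4x4 numeric matrix.
#' @export
bspline_blending_matrix <- function() {
  matrix(c(-1,  3, -3, 1,
            3, -6,  3, 0,
           -3,  0,  3, 0,
            1,  4,  1, 0), nrow = 4, byrow = TRUE)
}

#' Cox-de Boor recursion for B-spline basis functions
#'
#' Evaluates the \code{i}-th B-spline basis function of degree \code{d} at
#' parameter \code{t} on an arbitrary non-decreasing knot vector. The degree-0
#' base case is the half-open indicator on \code{[t_i, t_{i+1})}. Terms with
#' zero denominator are dropped (0/0 := 0).
#'
#' @param i Basis index (1-based into \code{knot_vector}).
#' @param d Degree (>= 0).
#' @param t Evaluation parameter (scalar).
#' @param knot_vector Non-decreasing numeric knot vector.
#' @return The basis value \code{B_i^d(t)}.
#' @export
cox_de_boor <- function(i, d, t, knot_vector) {
  if (is.unsorted(knot_vector)) {
    stop("knot_vector must be non-decreasing")
  }
  if (d < 0) stop("degree must be >= 0")
  if (d == 0) {
    return(as.numeric(t >= knot_vector[i] & t < knot_vector[i + 1]))
  }
  left <- 0
  den1 <- knot_vector[i + d] - knot_vector[i]
  if (den1 > 0) {
    left <- (t - knot_vector[i]) / den1 * cox_de_boor(i, d - 1, t, knot_vector)
  }
  right <- 0
  den2 <- knot_vector[i + d + 1] - knot_vector[i + 1]
  if (den2 > 0) {
    right <- (knot_vector[i + d + 1] - t) / den2 *
      cox_de_boor(i + 1, d - 1, t, knot_vector)
  }
  left + right
}

#' Evaluate one cubic B-spline curve segment in matrix form
#'
#' @param t Local parameter in \[0, 1\].
#' @param Q4 Numeric vector of the four control values for this segment.
#' @return The segment value \code{(1/6) [t^3 t^2 t 1] M Q4}.
#' @export
eval_cubic_segment <- function(t, Q4) {
  stopifnot(length(Q4) == 4)
  tv <- c(t^3, t^2, t, 1)
  drop(tv %*% bspline_blending_matrix() %*% Q4) / 6
}

#' Evaluate one bicubic B-spline surface segment in matrix form
#'
#' Tensor-product form \code{(1/36) [v^3 v^2 v 1] M Qgrid t(M) [u^3 u^2 u 1]'}
#' where rows of \code{Qgrid} vary along the v axis and columns along u.
#'
#' @param u,v Local parameters in \[0, 1\].
#' @param Qgrid 4x4 matrix of control values.
#' @return The surface value.
#' @export
eval_bicubic_segment <- function(u, v, Qgrid) {
  stopifnot(all(dim(Qgrid) == c(4, 4)))
  M <- bspline_blending_matrix()
  vv <- c(v^3, v^2, v, 1)
  uu <- c(u^3, u^2, u, 1)
  drop(vv %*% M %*% Qgrid %*% t(M) %*% uu) / 36
}

# Passing matrix for n knots with free-end boundary conditions: (n+2) control
# points; rows 2..n+1 are the interpolation relation K_k = (Q_k + 4Q_{k+1} +
# Q_{k+2})/6, rows 1 and n+2 enforce zero second difference of the boundary
# control points.
bspline_passing_matrix <- function(n) {
  stopifnot(n >= 2)
  Phi <- matrix(0, n + 2, n + 2)
  Phi[1, 1:3] <- c(1, -2, 1)
  for (k in seq_len(n)) {
    Phi[k + 1, k:(k + 2)] <- c(1, 4, 1) / 6
  }
  Phi[n + 2, n:(n + 2)] <- c(1, -2, 1)
  Phi
}

#' Solve B-spline control points from knot values (free-end)
#'
#' Solves the banded passing system: interior rows give
#' \code{K_k = (Q_k + 4 Q_{k+1} + Q_{k+2})/6}, boundary rows impose the
#' free-end condition \code{Q_{k-1} - 2 Q_k + Q_{k+1} = 0} at both ends, so
#' the curve extends linearly beyond the boundary knots.
#'
#' @param knot_values Numeric vector of knot values (length >= 2).
#' @return Numeric vector of \code{length(knot_values) + 2} control values.
#' @export
solve_control_points <- function(knot_values) {
  n <- length(knot_values)
  if (n < 2) stop("need at least 2 knot values")
  Phi <- bspline_passing_matrix(n)
  q <- tryCatch(solve(Phi, c(0, knot_values, 0)),
                error = function(e) stop("singular passing system: ",
                                         conditionMessage(e)))
  q
}

# Matrix mapping n knot values to n+2 control values.
control_solve_matrix <- function(n) {
  solve(bspline_passing_matrix(n))[, 2:(n + 1), drop = FALSE]
}

# Rows of basis weights over *control points* for arbitrary coordinates on a
# uniform knot grid kp (increasing, evenly spaced, length n >= 2). Points
# beyond the knot range get linearly extrapolated rows (value + slope at the
# boundary), realizing the free-end behavior.
bspline_basis_rows <- function(points, kp) {
  n <- length(kp)
  stopifnot(n >= 2)
  h <- if (n == 2) kp[2] - kp[1] else (kp[n] - kp[1]) / (n - 1)
  M <- bspline_blending_matrix()
  tau <- (points - kp[1]) / h            # coordinate in knot-spacing units
  seg <- pmin(pmax(floor(tau) + 1, 1), n - 1)
  tt <- tau - (seg - 1)
  B <- matrix(0, length(points), n + 2)
  for (m in seq_along(points)) {
    t0 <- tt[m]
    if (t0 < 0) {                         # below range: linear extension
      w <- c(0, 0, 0, 1) %*% M / 6 + t0 * (c(0, 0, 1, 0) %*% M / 6)
    } else if (t0 > 1) {                  # above range (only at seg n-1)
      w <- c(1, 1, 1, 1) %*% M / 6 + (t0 - 1) * (c(3, 2, 1, 0) %*% M / 6)
    } else {
      w <- c(t0^3, t0^2, t0, 1) %*% M / 6
    }
    B[m, seg[m]:(seg[m] + 3)] <- w
  }
  B
}

# Rows of evaluation weights over *knot values*: value(points) = R %*% K.
bspline_eval_matrix <- function(points, kp) {
  bspline_basis_rows(points, kp) %*% control_solve_matrix(length(kp))
}

#' Evaluate a 1D uniform cubic B-spline through knot values
#'
#' Interpolating spline with free-end boundary conditions; linear
#' extrapolation beyond the boundary knots.
#'
#' @param points Coordinates at which to evaluate.
#' @param knot_positions Evenly spaced increasing knot coordinates.
#' @param knot_values Values the spline passes through (same length).
#' @return Numeric vector of spline values at \code{points}.
#' @export
eval_spline_1d <- function(points, knot_positions, knot_values) {
  stopifnot(length(knot_positions) == length(knot_values))
  drop(bspline_eval_matrix(points, knot_positions) %*% knot_values)
}

# ---- 3D knot grid ----------------------------------------------------------

#' Construct a 3D deformation knot grid
#'
#' @param x_positions,y_positions Evenly spaced knot coordinates (pixels,
#'   0-based) along x and y; at least 4 each for a full bicubic surface
#'   (2 accepted for degenerate/test grids).
#' @param z_positions Evenly spaced knot coordinates along the exposure axis
#'   in frame units (frame \code{fi} has coordinate \code{fi}; the first knot
#'   usually sits at 0 = start of exposure).
#' @param Kx,Ky Arrays of knot shift values (pixels), dim
#'   \code{c(NKx, NKy, NKz)}. Default zero.
#' @return An object of class \code{knot_grid_3d}.
#' @export
knot_grid_3d <- function(x_positions, y_positions, z_positions,
                         Kx = NULL, Ky = NULL) {
  dims <- c(length(x_positions), length(y_positions), length(z_positions))
  if (any(dims < 2)) stop("each axis needs at least 2 knots")
  for (p in list(x_positions, y_positions, z_positions)) {
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("knot positions must be strictly increasing")
    }
    if (length(p) > 2 && max(abs(diff(diff(p)))) > 1e-6 * max(abs(diff(p)))) {
      stop("knot positions must be evenly spaced")
    }
  }
  if (is.null(Kx)) Kx <- array(0, dims)
  if (is.null(Ky)) Ky <- array(0, dims)
  stopifnot(all(dim(Kx) == dims), all(dim(Ky) == dims))
  structure(list(x_positions = as.numeric(x_positions),
                 y_positions = as.numeric(y_positions),
                 z_positions = as.numeric(z_positions),
                 Kx = Kx, Ky = Ky),
            class = "knot_grid_3d")
}

#' @export
print.knot_grid_3d <- function(x, ...) {
  cat(sprintf("knot_grid_3d: %d x %d x %d knots (x, y, z)\n",
              length(x$x_positions), length(x$y_positions),
              length(x$z_positions)))
  cat(sprintf("  max |Kx| = %.3f px, max |Ky| = %.3f px\n",
              max(abs(x$Kx)), max(abs(x$Ky))))
  invisible(x)
}

#' Build the default deformation knot grid for a movie
#'
#' In-plane knot counts default to two-thirds of the patch count per axis
#' (round half up), clamped to a minimum of four, and are spread evenly
#' across the image. Along the exposure axis one knot is placed every
#' \code{knot_exposure_spacing} electrons/A^2 of accumulated exposure:
#' \code{NKz = floor(total_exposure / spacing) + 1} knots (minimum 2) evenly
#' spanning the full exposure range, so e.g. a 40-frame movie with total
#' exposure 16 e-/A^2 gets a knot every 10 frames.
#'
#' @param np_x,np_y Patch counts per axis.
#' @param NF Number of frames.
#' @param exposure_per_frame Exposure per frame (e-/A^2).
#' @param nx,ny Image dimensions in pixels at the working sampling.
#' @param config A [run_config()].
#' @return A zero-initialized [knot_grid_3d()].
#' @export
build_default_knot_grid <- function(np_x, np_y, NF, exposure_per_frame,
                                    nx, ny, config = run_config()) {
  stopifnot(np_x >= 1, np_y >= 1, NF >= 2)
  nkx <- max(config$min_knots, floor(2 / 3 * np_x + 0.5))
  nky <- max(config$min_knots, floor(2 / 3 * np_y + 0.5))
  total_exposure <- NF * exposure_per_frame
  nkz <- if (exposure_per_frame > 0) {
    max(2, floor(total_exposure / config$knot_exposure_spacing) + 1)
  } else 2
  knot_grid_3d(x_positions = seq(0, nx - 1, length.out = nkx),
               y_positions = seq(0, ny - 1, length.out = nky),
               z_positions = seq(0, NF, length.out = nkz))
}

# Cardinal evaluation rows of the full 3D model for a set of (x, y) points at
# one z coordinate: value = rows %*% as.vector(K). Used by the least-squares
# fit and the field evaluator; vec(K) varies x fastest, then y, then z.
spline_design_rows <- function(grid, px, py, z) {
  rx <- bspline_eval_matrix(px, grid$x_positions)
  ry <- bspline_eval_matrix(py, grid$y_positions)
  rz <- drop(bspline_eval_matrix(z, grid$z_positions))
  nkx <- length(grid$x_positions); nky <- length(grid$y_positions)
  m <- length(px)
  out <- matrix(0, m, nkx * nky * length(grid$z_positions))
  xy <- matrix(0, m, nkx * nky)
  for (j in seq_len(nky)) {
    xy[, ((j - 1) * nkx + 1):(j * nkx)] <- rx * ry[, j]
  }
  for (k in seq_along(rz)) {
    out[, ((k - 1) * nkx * nky + 1):(k * nkx * nky)] <- xy * rz[k]
  }
  out
}

#' Evaluate the deformation shift field of one frame
#'
#' Step 1: for every in-plane knot thread the cubic B-spline along the
#' exposure axis is evaluated at the frame coordinate, giving the per-frame
#' 2D knot plane. Step 2: the bicubic surface through that plane is evaluated
#' at the requested coordinates. Beyond the boundary knots the free-end model
#' extrapolates linearly.
#'
#' @param grid A [knot_grid_3d()].
#' @param frame_index Frame number (1-based; coordinate on the z axis).
#' @param nx,ny Raster dimensions; used when \code{at} is NULL to evaluate
#'   the full raster at pixel coordinates \code{0:(nx-1)} x \code{0:(ny-1)}.
#' @param at Optional 2-column matrix of (x, y) pixel coordinates.
#' @return For a raster: list with \code{ux}, \code{uy} (nx x ny matrices,
#'   pixels). For points: list with \code{ux}, \code{uy} vectors.
#' @export
eval_shift_field <- function(grid, frame_index, nx = NULL, ny = NULL,
                             at = NULL) {
  if (frame_index < 0 || frame_index > max(grid$z_positions) + 1) {
    stop("frame index out of range of the model")
  }
  nkx <- length(grid$x_positions); nky <- length(grid$y_positions)
  nkz <- length(grid$z_positions)
  rz <- drop(bspline_eval_matrix(frame_index, grid$z_positions))
  plane_x <- matrix(matrix(grid$Kx, nkx * nky, nkz) %*% rz, nkx, nky)
  plane_y <- matrix(matrix(grid$Ky, nkx * nky, nkz) %*% rz, nkx, nky)
  if (is.null(at)) {
    stopifnot(!is.null(nx), !is.null(ny))
    rx <- bspline_eval_matrix(0:(nx - 1), grid$x_positions)
    ry <- bspline_eval_matrix(0:(ny - 1), grid$y_positions)
    list(ux = rx %*% plane_x %*% t(ry), uy = rx %*% plane_y %*% t(ry))
  } else {
    at <- as.matrix(at)
    rx <- bspline_eval_matrix(at[, 1], grid$x_positions)
    ry <- bspline_eval_matrix(at[, 2], grid$y_positions)
    list(ux = rowSums((rx %*% plane_x) * ry),
         uy = rowSums((rx %*% plane_y) * ry))
  }
}
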