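# Spline fitting (least squares and correlation refinement), warping, frame
# summation, and parameter export.

make_test_grid <- function(nx = 256, ny = 192, NF = 8, seed = 21) {
  g <- knot_grid_3d(seq(0, nx - 1, length.out = 4),
                    seq(0, ny - 1, length.out = 4),
                    seq(0, NF, length.out = 3))
  set.seed(seed)
  g$Kx <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  g$Ky <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  g
}

sample_patch_shifts <- function(grid, centers, NF) {
  x <- matrix(0, nrow(centers), NF)
  y <- matrix(0, nrow(centers), NF)
  for (f in seq_len(NF)) {
    s <- eval_shift_field(grid, f, at = centers)
    x[, f] <- s$ux
    y[, f] <- s$uy
  }
  patch_shift_set(x, y)
}

test_that("least-squares fit recovers a generating knot grid exactly", {
  NF <- 8
  truth <- make_test_grid(NF = NF)
  centers <- as.matrix(expand.grid(x = seq(20, 235, length.out = 6),
                                   y = seq(20, 170, length.out = 5)))
  ps <- sample_patch_shifts(truth, centers, NF)
  empty <- truth; empty$Kx[] <- 0; empty$Ky[] <- 0
  fit <- fit_spline_l1(ps, empty, centers)
  expect_lt(max(abs(fit$grid$Kx - truth$Kx)), 1e-6)
  expect_lt(max(abs(fit$grid$Ky - truth$Ky)), 1e-6)
  expect_lt(fit$l1_residual, 1e-10)
})

test_that("constant patch shifts give constant knot values", {
  NF <- 6
  grid <- make_test_grid(NF = NF)
  centers <- as.matrix(expand.grid(x = seq(10, 245, length.out = 5),
                                   y = seq(10, 180, length.out = 5)))
  ps <- patch_shift_set(matrix(1.25, 25, NF), matrix(-0.5, 25, NF))
  fit <- fit_spline_l1(ps, grid, centers)
  expect_equal(range(fit$grid$Kx), c(1.25, 1.25), tolerance = 1e-8)
  expect_equal(range(fit$grid$Ky), c(-0.5, -0.5), tolerance = 1e-8)
})

test_that("least-squares solution matches the normal-equations oracle", {
  NF <- 5
  truth <- make_test_grid(NF = NF, seed = 22)
  centers <- as.matrix(expand.grid(x = seq(15, 240, length.out = 6),
                                   y = seq(15, 175, length.out = 5)))
  ps <- sample_patch_shifts(truth, centers, NF)
  set.seed(23)
  ps$x <- ps$x + matrix(rnorm(length(ps$x), sd = 0.3), nrow(ps$x))
  ps$y <- ps$y + matrix(rnorm(length(ps$y), sd = 0.3), nrow(ps$y))
  empty <- truth; empty$Kx[] <- 0; empty$Ky[] <- 0
  fit <- fit_spline_l1(ps, empty, centers)
  # independent oracle: dense normal equations built row by row
  J <- NULL
  for (f in seq_len(NF)) {
    J <- rbind(J, unbendr:::spline_design_rows(empty, centers[, 1],
                                               centers[, 2], f))
  }
  kx_o <- solve(t(J) %*% J, t(J) %*% as.vector(ps$x))
  expect_lt(max(abs(as.vector(fit$grid$Kx) - kx_o)), 1e-8)
  # residual magnitude consistent with the injected noise: per-axis
  # expectation sigma^2 * (1 - p/n) with p knot values and n observations
  n_axis <- nrow(centers) * NF
  expected <- 0.3^2 * (1 - ncol(J) / n_axis)
  expect_lt(abs(fit$l1_residual / (2 * n_axis) - expected),
            0.3 * expected)
})

test_that("degenerate designs are rejected or stabilized", {
  NF <- 4
  grid <- make_test_grid(NF = NF)
  centers <- matrix(rep(c(100, 100), each = 6), 6, 2)
  ps <- patch_shift_set(matrix(0, 6, NF), matrix(0, 6, NF))
  expect_error(fit_spline_l1(ps, grid, centers), "colocated")
  few <- as.matrix(expand.grid(x = c(50, 200), y = c(50, 150)))
  ps2 <- patch_shift_set(matrix(0, 4, NF), matrix(0, 4, NF))
  expect_warning(fit_spline_l1(ps2, grid, few), "ridge")
})

test_that("correlation refinement has a correct analytic gradient", {
  spec <- small_spec(seed = 31)
  cfg <- small_config()
  truth <- make_ground_truth(spec, cfg, np_x = 4, np_y = 3)
  movie <- simulate_movie(truth$reference, truth, spec)
  grid <- build_patch_grid(spec$nx, spec$ny, 64)
  stacks <- unbendr:::extract_patch_stacks(movie$frames, grid)
  knots <- knot_grid_3d(seq(0, spec$nx - 1, length.out = 4),
                        seq(0, spec$ny - 1, length.out = 4),
                        c(0, spec$NF))
  ctx <- unbendr:::l2_context(stacks, knots, grid$centers,
                              spec$pixel_size, cfg)
  obj <- unbendr:::l2_fn_gr(ctx)
  set.seed(32)
  par <- rnorm(2 * ctx$n_knots, sd = 0.3)
  g_analytic <- obj$gr(par)
  idx <- c(1, 5, 17, ctx$n_knots + 3, 2 * ctx$n_knots)
  h <- 1e-5
  for (i in idx) {
    e <- rep(0, length(par)); e[i] <- h
    g_fd <- (obj$fn(par + e) - obj$fn(par - e)) / (2 * h)
    expect_lt(abs(g_analytic[i] - g_fd), 1e-4 * max(1, abs(g_fd)))
  }
})

test_that("refinement never worsens the objective and finds a local optimum", {
  spec <- small_spec(seed = 33)
  cfg <- small_config(max_iter = 60)
  truth <- make_ground_truth(spec, cfg, np_x = 4, np_y = 3)
  movie <- simulate_movie(truth$reference, truth, spec)
  grid <- build_patch_grid(spec$nx, spec$ny, 64)
  traj <- shift_trajectory(truth$drift)
  # monotone improvement from a noisy initialization
  init <- truth$grid
  set.seed(34)
  init$Kx <- init$Kx + array(rnorm(length(init$Kx), sd = 0.3), dim(init$Kx))
  init$Ky <- init$Ky + array(rnorm(length(init$Ky), sd = 0.3), dim(init$Ky))
  stacks <- unbendr:::extract_patch_stacks(
    unbendr:::apply_global_alignment(movie, traj)$frames, grid)
  ctx <- unbendr:::l2_context(stacks, init, grid$centers, spec$pixel_size,
                              cfg)
  obj <- unbendr:::l2_fn_gr(ctx)
  v_init <- obj$fn(c(as.vector(init$Kx), as.vector(init$Ky)))
  fit <- refine_spline_l2(movie, init, grid, cfg, traj)
  expect_lte(fit$l2_value, v_init)
  # the returned optimum beats knot perturbations of +-0.5 px
  par_opt <- c(as.vector(fit$grid$Kx), as.vector(fit$grid$Ky))
  v_opt <- obj$fn(par_opt)
  set.seed(35)
  for (i in 1:5) {
    pert <- par_opt
    j <- sample(length(pert), 1)
    pert[j] <- pert[j] + sample(c(-0.5, 0.5), 1)
    expect_lte(v_opt, obj$fn(pert) + 1e-9)
  }
})

test_that("stronger-signal patches weigh more in the objective", {
  # the same patch content at two contrast levels: misaligning the
  # high-contrast stack must cost more correlation than misaligning the
  # low-contrast one
  img <- blob_image(64, 64, n_blobs = 15)
  NF <- 4
  objective_change <- function(contrast) {
    set.seed(61)
    frames <- array(0, dim = c(64, 64, NF))
    for (f in 1:NF) {
      frames[, , f] <- contrast * img + rnorm(64 * 64, sd = 0.1)
    }
    grid <- build_patch_grid(64, 64, 64)
    knots <- knot_grid_3d(c(0, 63), c(0, 63), c(0, NF))
    ctx <- unbendr:::l2_context(list(frames), knots, grid$centers, 1.5,
                                run_config())
    obj <- unbendr:::l2_fn_gr(ctx)
    base <- rep(0, 2 * ctx$n_knots)
    # x-shift ramping from 0 to 20 px over the frames (a constant shift of
    # the whole stack would leave the relative alignment unchanged; the
    # ramp must be large on the scale of the B-filtered correlation length
    # to decorrelate the frames appreciably)
    pert <- base
    pert[5:8] <- 20                       # second z-knot plane of Kx
    obj$fn(pert) - obj$fn(base)
  }
  expect_gt(objective_change(1), objective_change(0.02))
})

test_that("warping: identity, translation, and approximate inverse", {
  img <- blob_image(96, 80, n_blobs = 15, sigma = 5)   # smooth test image
  z <- matrix(0, 96, 80)
  expect_equal(warp_frame(img, z, z), img)
  # uniform integer field samples the translated image in the interior
  t2 <- warp_frame(img, z + 2, z)
  expect_equal(t2[1:94, ], img[3:96, ], tolerance = 1e-12)
  # warp by u then by -u returns the original away from the edges
  xs <- matrix(0:95, 96, 80); ys <- matrix(0:79, 96, 80, byrow = TRUE)
  ux <- 1.5 * sin(2 * pi * xs / 96) * cos(2 * pi * ys / 80)
  uy <- -1.2 * cos(2 * pi * xs / 96) * sin(2 * pi * ys / 80)
  w <- warp_frame(img, ux, uy)
  back <- warp_frame(w, -ux, -uy)
  err <- (back - img)[5:92, 5:76]
  expect_lt(sqrt(mean(err^2)), 0.02 * stats::sd(img))
  # mean density is conserved for interior-dominated fields
  expect_lt(abs(mean(w) - mean(img)) / abs(mean(img)), 0.005)
})

test_that("summation without deformation model averages aligned frames", {
  img <- blob_image(96, 80)
  movie <- shifted_movie(img, matrix(0, 3, 2))
  traj <- shift_trajectory(matrix(0, 3, 2))
  mic <- sum_corrected_frames(movie, traj, NULL)
  expect_equal(mic$pixels, img, tolerance = 1e-10)
})

test_that("spline parameter files round-trip exactly and validate", {
  g <- make_test_grid()
  meta <- list(nx = 256, ny = 192, pixel_size = 1.5, NF = 8,
               exposure_per_frame = 1)
  path <- withr::local_tempfile(fileext = ".json")
  export_spline_parameters(g, meta, path)
  back <- import_spline_parameters(path)
  expect_identical(back$model$Kx, g$Kx)
  expect_identical(back$model$Ky, g$Ky)
  expect_equal(back$model$x_positions, g$x_positions)
  expect_equal(back$meta$NF, 8)
  # missing field
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$x_positions <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, path2, auto_unbox = TRUE, digits = NA)
  expect_error(import_spline_parameters(path2), "x_positions")
  # version mismatch
  obj2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj2$version <- "other-format-99"
  jsonlite::write_json(obj2, path2, auto_unbox = TRUE, digits = NA)
  expect_error(import_spline_parameters(path2), "version")
  expect_error(export_spline_parameters(g, list(nx = 1), path), "meta")
})
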