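# The 3D B-spline deformation model: basis recursion vs matrix form,
# control-point solve with free-end boundaries, knot-grid construction, and
# shift-field evaluation.

test_that("degree-0 basis is the half-open indicator", {
  kv <- c(0, 1, 2, 4, 7)
  expect_equal(cox_de_boor(2, 0, 1.5, kv), 1)
  expect_equal(cox_de_boor(2, 0, 2, kv), 0)    # right end excluded
  expect_equal(cox_de_boor(2, 0, 1, kv), 1)    # left end included
  expect_equal(cox_de_boor(2, 0, 0.5, kv), 0)
  expect_error(cox_de_boor(1, 3, 0.5, c(0, 2, 1, 3, 4, 5)), "non-decreasing")
})

test_that("cubic basis at a uniform interior knot gives 1/6, 4/6, 1/6", {
  kv <- 0:7
  expect_equal(cox_de_boor(1, 3, 3, kv), 1 / 6)
  expect_equal(cox_de_boor(2, 3, 3, kv), 4 / 6)
  expect_equal(cox_de_boor(3, 3, 3, kv), 1 / 6)
  expect_equal(cox_de_boor(4, 3, 3, kv), 0)
})

test_that("matrix form equals the Cox-de Boor recursion on uniform knots", {
  kv <- 0:7
  set.seed(11)
  for (i in 1:1000) {
    t <- runif(1)
    Q <- rnorm(4)
    mform <- eval_cubic_segment(t, Q)
    rec <- sum(vapply(1:4, function(j) Q[j] * cox_de_boor(j, 3, 3 + t, kv),
                      numeric(1)))
    expect_lt(abs(mform - rec), 1e-10)
  }
})

test_that("blending matrix bottom row gives the knot interpolation weights", {
  M <- bspline_blending_matrix()
  expect_equal(M[4, ], c(1, 4, 1, 0))
  expect_equal(drop(M %*% rep(1, 4)), c(0, 0, 0, 6))  # partition of unity
  expect_equal(eval_cubic_segment(0, c(0, 6, 0, 0)), 4)
})

test_that("cubic and bicubic segments reproduce constants", {
  for (t in c(0, 0.31, 0.77, 1)) {
    expect_equal(eval_cubic_segment(t, rep(2.5, 4)), 2.5)
  }
  Q <- matrix(-1.2, 4, 4)
  for (uv in list(c(0, 0), c(0.4, 0.9), c(1, 1))) {
    expect_equal(eval_bicubic_segment(uv[1], uv[2], Q), -1.2)
  }
})

test_that("bicubic segment is the tensor product of 1D segments", {
  set.seed(3)
  qv <- rnorm(4); qu <- rnorm(4)
  Q <- outer(qv, qu)                    # rows along v, columns along u
  for (i in 1:20) {
    u <- runif(1); v <- runif(1)
    expect_equal(eval_bicubic_segment(u, v, Q),
                 eval_cubic_segment(v, qv) * eval_cubic_segment(u, qu),
                 tolerance = 1e-12)
  }
  # corner weights
  set.seed(4)
  Qr <- matrix(rnorm(16), 4, 4)
  w <- c(1, 4, 1, 0)
  expect_equal(eval_bicubic_segment(0, 0, Qr),
               drop(w %*% Qr %*% w) / 36, tolerance = 1e-12)
  # transpose symmetry fixes the tensor-product convention
  expect_equal(eval_bicubic_segment(0.3, 0.8, t(Qr)),
               eval_bicubic_segment(0.8, 0.3, Qr), tolerance = 1e-12)
})

test_that("control-point solve honors interpolation and free ends", {
  expect_equal(solve_control_points(rep(3, 5)), rep(3, 7))
  # linear knot values give linear control points with the same slope
  K <- 2 * (1:6)
  q <- solve_control_points(K)
  expect_equal(diff(q), rep(2, 7))
  # defining relation: residual of K = (1/6) Phi Q
  set.seed(5)
  K <- rnorm(7)
  q <- solve_control_points(K)
  Phi <- unbendr:::bspline_passing_matrix(7)
  r <- Phi %*% q - c(0, K, 0)
  expect_lt(max(abs(r)), 1e-10 * max(1, max(abs(K))))
})

test_that("1D spline interpolates knots and extrapolates linearly", {
  kp <- seq(0, 12, length.out = 7)
  set.seed(6)
  K <- rnorm(7)
  expect_equal(eval_spline_1d(kp, kp, K), K, tolerance = 1e-10)
  # linear reproduction including beyond the boundary
  Kl <- 0.7 * kp + 1
  pts <- seq(-2.5, 14.5, by = 0.25)
  expect_equal(eval_spline_1d(pts, kp, Kl), 0.7 * pts + 1,
               tolerance = 1e-8)
  # extrapolation half a knot spacing beyond the end is linear
  h <- kp[2] - kp[1]
  end_val <- eval_spline_1d(kp[7], kp, K)
  slope <- (eval_spline_1d(kp[7], kp, K) -
              eval_spline_1d(kp[7] - 1e-5, kp, K)) / 1e-5
  expect_equal(eval_spline_1d(kp[7] + h / 2, kp, K),
               end_val + slope * h / 2, tolerance = 1e-6)
})

test_that("spline is C2: derivatives agree across segment boundaries", {
  kp <- seq(0, 10, length.out = 6)
  set.seed(7)
  K <- rnorm(6)
  h <- 1e-4
  for (knot in kp[2:5]) {
    f <- function(x) eval_spline_1d(x, kp, K)
    d1l <- (f(knot) - f(knot - h)) / h
    d1r <- (f(knot + h) - f(knot)) / h
    expect_lt(abs(d1l - d1r), 1e-3)      # first derivative continuous
    d2l <- (f(knot) - 2 * f(knot - h) + f(knot - 2 * h)) / h^2
    d2r <- (f(knot + 2 * h) - 2 * f(knot + h) + f(knot)) / h^2
    expect_lt(abs(d2l - d2r), 1e-2 * max(1, abs(d2l)))
  }
  # free end: second derivative vanishes at the outermost knots
  f <- function(x) eval_spline_1d(x, kp, K)
  d2 <- (f(kp[1] + 2 * h) - 2 * f(kp[1] + h) + f(kp[1])) / h^2
  expect_lt(abs(d2), 1e-3)
  d2 <- (f(kp[6]) - 2 * f(kp[6] - h) + f(kp[6] - 2 * h)) / h^2
  expect_lt(abs(d2), 1e-3)
})

test_that("quadratics are reproduced in the interior away from boundaries", {
  kp <- seq(0, 22, by = 2)               # 12 knots
  K <- 0.05 * kp^2 - kp + 2
  interior <- seq(8, 14, by = 0.25)
  got <- eval_spline_1d(interior, kp, K)
  want <- 0.05 * interior^2 - interior + 2
  expect_lt(max(abs(got - want)), 1e-3 * max(abs(want)))
})

test_that("default knot grid follows the configuration rules", {
  cfg <- run_config()
  # 40-frame movie, 16 e-/A^2 total: a knot every 10 frames
  g <- build_default_knot_grid(8, 6, 40, 0.4, 4044, 2873, cfg)
  expect_equal(length(g$z_positions), 5)
  expect_equal(unique(diff(g$z_positions)), 10)
  # minimum clamp: 2/3 of 4 patches is below the 4-knot floor
  g4 <- build_default_knot_grid(4, 4, 10, 1, 512, 512, cfg)
  expect_equal(length(g4$x_positions), 4)
  # exact two-thirds
  g12 <- build_default_knot_grid(12, 12, 10, 1, 512, 512, cfg)
  expect_equal(length(g12$x_positions), 8)
  # half-up rounding before the clamp: 2/3 * 8 = 5.33 -> 5
  g8 <- build_default_knot_grid(8, 8, 10, 1, 512, 512, cfg)
  expect_equal(length(g8$x_positions), 5)
  # knots span the image evenly
  expect_equal(g$x_positions[1], 0)
  expect_equal(g$x_positions[length(g$x_positions)], 4043)
})

test_that("3D field evaluation: constants, planes, and knot interpolation", {
  g <- knot_grid_3d(seq(0, 100, length.out = 4), seq(0, 80, length.out = 4),
                    seq(0, 24, length.out = 7))
  g$Kx[] <- 5; g$Ky[] <- -2
  f <- eval_shift_field(g, 7, nx = 21, ny = 17)
  expect_equal(range(f$ux), c(5, 5))
  expect_equal(range(f$uy), c(-2, -2))
  # knot values linear in x give a field linear in x
  for (k in 1:7) g$Kx[, , k] <- matrix(0.03 * g$x_positions, 4, 4)
  f <- eval_shift_field(g, 3, at = cbind(c(10, 50, 95.5), c(7, 40, 60)))
  expect_equal(f$ux, 0.03 * c(10, 50, 95.5), tolerance = 1e-8)
  # random grid evaluated at knot coordinates reproduces the knot values
  set.seed(8)
  g$Kx <- array(rnorm(4 * 4 * 7), dim = c(4, 4, 7))
  at <- as.matrix(expand.grid(x = g$x_positions, y = g$y_positions))
  f <- eval_shift_field(g, g$z_positions[4], at = at)
  expect_equal(matrix(f$ux, 4, 4), g$Kx[, , 4], tolerance = 1e-8)
  expect_error(eval_shift_field(g, 99, nx = 4, ny = 4), "out of range")
})
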