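# Strain-field quantification: deformation gradient, Green-Lagrange tensor,
# and the equivalent strain scalars.

field_from <- function(ux, uy) {
  structure(list(ux = ux, uy = uy, frame = 2, reference = 1,
                 unit = "pixel"), class = "shift_field")
}

# Independent matrix-algebra oracle for the equivalent strains: builds the
# deviatoric tensor explicitly as E - (tr E / 3) I and sums its squared
# entries (the off-diagonal appears twice).
strain_oracle <- function(E) {
  total <- sqrt(sum(E * E))
  D <- E - (sum(diag(E)) / 3) * diag(2)
  vm <- sqrt(2 / 3 * sum(D * D))
  c(total = total, vm = vm)
}

maps_from_tensor <- function(E) {
  m <- structure(list(Exx = matrix(E[1, 1], 1, 1),
                      Eyy = matrix(E[2, 2], 1, 1),
                      Exy = matrix(E[1, 2], 1, 1)),
                 class = "strain_maps")
  equivalent_strains(m)
}

test_that("zero displacement gives identity gradient and zero strain", {
  z <- matrix(0, 24, 20)
  maps <- equivalent_strains(deformation_tensors(field_from(z, z)))
  expect_equal(max(abs(maps$F11 - 1)), 0)
  expect_equal(max(abs(maps$F12)), 0)
  expect_equal(max(abs(maps$Exx)), 0)
  expect_equal(max(abs(maps$total_eq)), 0)
  expect_equal(max(abs(maps$vm_eq)), 0)
})

test_that("uniaxial stretch matches the closed form", {
  nx <- 30; ny <- 24
  xs <- matrix(0:(nx - 1), nx, ny)
  alpha <- 0.01
  maps <- deformation_tensors(field_from(alpha * xs, matrix(0, nx, ny)))
  want <- ((1 + alpha)^2 - 1) / 2        # 0.01005
  expect_equal(max(abs(maps$Exx - want)), 0, tolerance = 1e-12)
  expect_equal(want, 0.01005, tolerance = 1e-10)
  expect_lt(max(abs(maps$Eyy)), 1e-14)
  expect_lt(max(abs(maps$Exy)), 1e-14)
})

test_that("rigid rotation produces only second-order strain", {
  nx <- 40; ny <- 40
  xs <- matrix(0:(nx - 1), nx, ny) - (nx - 1) / 2
  ys <- matrix(0:(ny - 1), nx, ny, byrow = TRUE) - (ny - 1) / 2
  th <- 0.01
  ux <- (cos(th) - 1) * xs - sin(th) * ys
  uy <- sin(th) * xs + (cos(th) - 1) * ys
  maps <- deformation_tensors(field_from(ux, uy))
  expect_lt(max(abs(maps$Exx)), 5e-5)
  expect_lt(max(abs(maps$Eyy)), 5e-5)
  expect_lt(max(abs(maps$Exy)), 5e-5)
})

test_that("equivalent strains of canonical tensors", {
  gamma <- 0.004
  shear <- maps_from_tensor(matrix(c(0, gamma, gamma, 0), 2, 2))
  expect_equal(shear$total_eq[1, 1], sqrt(2) * gamma, tolerance = 1e-14)
  expect_equal(shear$vm_eq[1, 1], 2 * gamma / sqrt(3), tolerance = 1e-14)
  e <- 0.01
  uni <- maps_from_tensor(matrix(c(e, 0, 0, 0), 2, 2))
  expect_equal(uni$total_eq[1, 1], e, tolerance = 1e-14)
  expect_equal(uni$vm_eq[1, 1], e * sqrt(10 / 27), tolerance = 1e-14)
  # in-plane dilation keeps a nonzero von Mises value under the /3 trace
  # convention used here (asserted as implemented, not "fixed")
  dil <- maps_from_tensor(matrix(c(e, 0, 0, e), 2, 2))
  expect_equal(dil$vm_eq[1, 1], sqrt(2 / 3 * 2 * (e / 3)^2),
               tolerance = 1e-14)
  expect_gt(dil$vm_eq[1, 1], 0)
})

test_that("equivalent strains agree with the matrix-algebra oracle", {
  set.seed(41)
  for (i in 1:100) {
    E <- matrix(rnorm(3, sd = 0.02)[c(1, 2, 2, 3)], 2, 2)
    got <- maps_from_tensor(E)
    want <- strain_oracle(E)
    expect_lt(abs(got$total_eq[1, 1] - want["total"]), 1e-12)
    expect_lt(abs(got$vm_eq[1, 1] - want["vm"]), 1e-12)
  }
})

test_that("strains are non-negative and vanish only for zero tensors", {
  set.seed(42)
  for (i in 1:50) {
    E <- matrix(rnorm(3, sd = 0.05)[c(1, 2, 2, 3)], 2, 2)
    got <- maps_from_tensor(E)
    expect_gte(got$total_eq[1, 1], 0)
    expect_gte(got$vm_eq[1, 1], 0)
    if (any(E != 0)) expect_gt(got$total_eq[1, 1], 0)
  }
})

test_that("finite-difference gradients converge at second order", {
  f <- function(nx) {
    ny <- nx
    xs <- matrix(seq(0, 1, length.out = nx), nx, ny)
    ys <- matrix(seq(0, 1, length.out = ny), nx, ny, byrow = TRUE)
    h <- 1 / (nx - 1)
    ux <- 0.01 * xs^3 * ys
    # interior error of d(ux)/dx against the closed form 0.03 x^2 y
    g <- unbendr:::grad_xy(ux, h)
    err <- abs(g$dx - 0.03 * xs^2 * ys)
    max(err[3:(nx - 2), 3:(ny - 2)])
  }
  e1 <- f(21); e2 <- f(41)
  expect_gt(e1 / e2, 3)                  # halving h cuts the error ~4x
})

test_that("relative shift fields from a model", {
  g <- knot_grid_3d(seq(0, 63, length.out = 4), seq(0, 47, length.out = 4),
                    seq(0, 8, length.out = 3))
  # frame == reference gives the zero field
  f0 <- relative_shift_field(g, 5, 5, 64, 48)
  expect_equal(max(abs(f0$ux)), 0)
  # constant-in-z model: zero field for any pair
  g$Kx[] <- 3; g$Ky[] <- -1
  f1 <- relative_shift_field(g, 8, 1, 64, 48)
  expect_lt(max(abs(f1$ux)), 1e-10)
  expect_lt(max(abs(f1$uy)), 1e-10)
  # linear-in-z model: field is slope times the frame gap
  for (k in 1:3) { g$Kx[, , k] <- 0.25 * g$z_positions[k]; g$Ky[, , k] <- 0 }
  f2 <- relative_shift_field(g, 7, 2, 64, 48)
  expect_equal(max(abs(f2$ux - 0.25 * 5)), 0, tolerance = 1e-10)
  expect_error(relative_shift_field(g, 40, 1, 64, 48), "out of range")
})

test_that("strain map generation writes maps and summary", {
  g <- knot_grid_3d(seq(0, 63, length.out = 4), seq(0, 47, length.out = 4),
                    seq(0, 6, length.out = 2))
  dir <- withr::local_tempdir()
  par_path <- file.path(dir, "params.json")
  meta <- list(nx = 64, ny = 48, pixel_size = 1.5, NF = 6,
               exposure_per_frame = 1)
  # zero model: all maps zero
  export_spline_parameters(g, meta, par_path)
  s <- generate_strain_maps(par_path, out_prefix = file.path(dir, "zero"))
  expect_equal(s$max, rep(0, 4))
  expect_true(file.exists(file.path(dir, "zero_vm_eq.mrc")))
  expect_equal(max(abs(read_mrc(file.path(dir, "zero_vm_eq.mrc"))$data)), 0)
  # maps from an exported-then-imported model match the in-memory model
  set.seed(43)
  g$Kx <- array(rnorm(32, sd = 2), dim = c(4, 4, 2))
  g$Ky <- array(rnorm(32, sd = 2), dim = c(4, 4, 2))
  export_spline_parameters(g, meta, par_path)
  generate_strain_maps(par_path, out_prefix = file.path(dir, "rt"))
  field <- relative_shift_field(g, 6, 1, 64, 48)
  maps <- equivalent_strains(deformation_tensors(field))
  got <- read_mrc(file.path(dir, "rt_total_eq.mrc"))$data[, , 1]
  expect_equal(got, maps$total_eq, tolerance = 1e-6)
})

test_that("a rotating disk concentrates von Mises strain on its rim", {
  nx <- 64; ny <- 64
  xs <- matrix(0:(nx - 1), nx, ny) - 31.5
  ys <- matrix(0:(ny - 1), nx, ny, byrow = TRUE) - 31.5
  r <- sqrt(xs^2 + ys^2)
  inside <- r < 20
  th <- 0.02
  ux <- ifelse(inside, (cos(th) - 1) * xs - sin(th) * ys, 0)
  uy <- ifelse(inside, sin(th) * xs + (cos(th) - 1) * ys, 0)
  maps <- equivalent_strains(deformation_tensors(field_from(ux, uy)))
  rim <- abs(r - 20) < 2
  core <- r < 15
  outside <- r > 25
  expect_gt(mean(maps$vm_eq[rim]), 50 * mean(maps$vm_eq[core]))
  expect_gt(mean(maps$vm_eq[rim]), 50 * mean(maps$vm_eq[outside]))
})
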