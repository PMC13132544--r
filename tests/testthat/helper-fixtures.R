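# Fixtures built in code: deterministic blob images and small movies used
# across the unit tests. All sizes are kept small; the full-size standard
# fixture is exercised only by the end-to-end acceptance tests.

# Deterministic blob image (no RNG): quasi-random blob positions from a
# low-discrepancy sequence so every test sees the same content.
blob_image <- function(nx = 96, ny = 80, n_blobs = 25, sigma = 3,
                       contrast = 1) {
  img <- matrix(0, nx, ny)
  margin <- 4 * sigma
  g1 <- (sqrt(5) - 1) / 2; g2 <- sqrt(2) - 1
  for (i in seq_len(n_blobs)) {
    px <- margin + ((i * g1) %% 1) * (nx - 1 - 2 * margin)
    py <- margin + ((i * g2) %% 1) * (ny - 1 - 2 * margin)
    xs <- 0:(nx - 1); ys <- 0:(ny - 1)
    img <- img + contrast * outer(exp(-(xs - px)^2 / (2 * sigma^2)),
                                  exp(-(ys - py)^2 / (2 * sigma^2)))
  }
  img
}

# Movie whose frames are rigid (possibly subpixel) shifts of one image,
# optionally with seeded Gaussian noise. shifts: NF x 2 (where the content
# moved to, in pixels).
shifted_movie <- function(img, shifts, noise_sigma = 0, pixel_size = 1.5,
                          exposure_per_frame = 1, seed = 1) {
  NF <- nrow(shifts)
  frames <- array(0, dim = c(dim(img), NF))
  set.seed(seed)
  for (f in seq_len(NF)) {
    fr <- if (all(shifts[f, ] == 0)) img else
      unbendr:::fourier_shift_image(img, -shifts[f, 1], -shifts[f, 2])
    if (noise_sigma > 0) fr <- fr + rnorm(length(img), sd = noise_sigma)
    frames[, , f] <- fr
  }
  movie_stack(frames, pixel_size, exposure_per_frame)
}

# Small phantom spec for pipeline-level tests that do not need the
# full-size standard fixture. Any default can be overridden.
small_spec <- function(seed = 1, ...) {
  args <- list(nx = 256, ny = 256, NF = 10, n_particles = 120,
               noise_sigma = 0.2, drift_amplitude = 4,
               deformation_amplitude = 3, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

small_config <- function(...) {
  run_config(patch_size = 64, ...)
}
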