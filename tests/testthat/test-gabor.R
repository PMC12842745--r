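test_that("default bank has 24 kernels at the uniform orientation set", {
  bank <- build_gabor_bank(gabor_bank_config())
  expect_length(bank$kernels, 24)
  thetas <- unique(vapply(bank$kernels, `[[`, numeric(1), "theta"))
  expect_equal(sort(thetas), pi * (0:5) / 6)
  # scale-major channel order: c = scale * K + orientation
  sc <- vapply(bank$kernels, `[[`, numeric(1), "scale")
  ok <- vapply(bank$kernels, `[[`, numeric(1), "orientation")
  expect_equal(sc * 6 + ok, 0:23)
  # odd square kernels, finite taps
  for (k in bank$kernels) {
    expect_equal(nrow(k$taps), ncol(k$taps))
    expect_equal(nrow(k$taps) %% 2, 1)
    expect_true(all(is.finite(Mod(k$taps))))
  }
})

test_that("configuration errors are rejected", {
  expect_error(gabor_bank_config(n_scales = 0), "n_scales")
  expect_error(gabor_bank_config(gamma = 0), "gamma")
  expect_error(gabor_bank_config(frequencies = c(0.1, 0.3, 0.2, 0.4)), "monotone")
  expect_error(gabor_bank_config(frequencies = c(-0.1, 0.2, 0.3, 0.4)), "positive")
})

test_that("rotation identity and the theta + pi conjugacy hold", {
  # theta = 0: rotated coordinates are the identity, so taps are symmetric
  # about the carrier axis; theta_3 of K = 6 is pi/2
  cfg <- gabor_bank_config()
  bank <- build_gabor_bank(cfg)
  expect_equal(bank$kernels[[4]]$theta, pi / 2)
  # magnitudes at theta and theta + pi are identical tap-by-tap (conjugate
  # carrier), justifying orientation coverage of [0, pi)
  t1 <- mrisonify:::gabor_kernel_taps(0.2, pi / 5, 1, 1, 3)
  t2 <- mrisonify:::gabor_kernel_taps(0.2, pi / 5 + pi, 1, 1, 3)
  expect_equal(Mod(t1), Mod(t2), tolerance = 1e-12)
  expect_equal(t1, Conj(t2), tolerance = 1e-12)
})

test_that("energy maps: zero image, impulse image, shape and positivity", {
  bank <- small_bank()
  z <- compute_energy_maps(matrix(0, 20, 20), bank)
  expect_equal(dim(z$maps), c(20L, 20L, 6L))
  expect_true(all(z$maps == 0))

  # impulse at the centre reproduces each kernel magnitude envelope
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  em <- compute_energy_maps(img, bank)
  k <- bank$kernels[[6]]
  r <- (nrow(k$taps) - 1) %/% 2
  # convolution with a delta reproduces the kernel magnitude around the impulse
  got <- em$maps[11 + (-r:r), 11 + (-r:r), 6]
  expect_equal(got, Mod(k$taps), tolerance = 1e-10)
  expect_true(all(em$maps >= 0))
})

test_that("FFT and direct convolution agree to 1e-8 on 32x32 inputs", {
  set.seed(21)
  img <- matrix(runif(32 * 32), 32, 32)
  bank <- small_bank()
  fft_maps <- compute_energy_maps(img, bank, method = "fft")$maps
  dir_maps <- compute_energy_maps(img, bank, method = "direct")$maps
  expect_lt(max(abs(fft_maps - dir_maps)) / max(dir_maps), 1e-8)
})

test_that("a grating is detected by its own scale-orientation channel", {
  bank <- build_gabor_bank(gabor_bank_config())
  # f = 0.125 is scale index 2 on the ascending default ladder; theta = pi/3
  # is orientation index 2 -> channel 2*6 + 2 + 1 = 15 (1-based)
  img <- grating(128, 0.125, pi * 2 / 6)
  ce <- channel_energies(compute_energy_maps(normalize_slice(img), bank))
  expect_equal(which.max(ce$energy), 15L)
  # and a fine grating at theta = 0 -> scale 3 (f = 0.25), orientation 0
  img <- grating(128, 0.25, 0)
  ce <- channel_energies(compute_energy_maps(normalize_slice(img), bank))
  expect_equal(which.max(ce$energy), 3L * 6L + 0L + 1L)
})

test_that("energy maps scale linearly with image amplitude", {
  set.seed(5)
  img <- matrix(runif(40 * 40), 40, 40)
  bank <- small_bank()
  m1 <- compute_energy_maps(img, bank)$maps
  m2 <- compute_energy_maps(0.5 * img, bank)$maps
  expect_equal(m2, 0.5 * m1, tolerance = 1e-12)
})

test_that("rotating a texture by pi/K permutes orientation-channel energies", {
  bank <- build_gabor_bank(gabor_bank_config(n_scales = 2, n_orientations = 6,
                                             frequencies = c(0.0625, 0.125)))
  # Gaussian-windowed grating suppresses edge effects; rotating it by pi/6
  # shifts its energy profile one orientation slot
  e0 <- channel_energies(compute_energy_maps(
    grating(128, 0.125, pi / 6, windowed = TRUE), bank))$energy
  e1 <- channel_energies(compute_energy_maps(
    grating(128, 0.125, 2 * pi / 6, windowed = TRUE), bank))$energy
  perm <- c(6, 1:5) + 6   # scale-1 orientations shifted by one slot
  # pixel-grid anisotropy perturbs the tiny off-peak channels, so compare
  # the profiles relative to the dominant energy
  expect_lt(max(abs(e1[6 + 1:6] - e0[perm])) / max(e0), 0.05)
  expect_equal(which.max(e1[6 + 1:6]), which.max(e0[perm]))
})

test_that("undersized and unnormalized images are rejected", {
  bank <- build_gabor_bank(gabor_bank_config())   # max radius 68
  expect_error(compute_energy_maps(matrix(0.5, 30, 30), bank), "minimum size")
  expect_error(compute_energy_maps(matrix(2, 100, 100), small_bank()),
               "normalized")
})
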