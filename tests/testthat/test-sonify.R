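test_that("geometric frequency assignment hits both endpoints with constant ratio", {
  a <- assign_center_frequencies(24, 220, 3000, 1024, 16000)
  expect_equal(a$center_freqs[1], 220)
  expect_equal(a$center_freqs[24], 3000)
  ratios <- a$center_freqs[-1] / a$center_freqs[-24]
  expect_true(all(abs(ratios - (3000 / 220)^(1 / 23)) < 1e-9))
  expect_true(all(diff(a$center_freqs) > 0))
  # nearest-bin snapping
  expect_equal(a$bins, as.integer(round(a$center_freqs / (16000 / 1024))))
  # two channels -> the endpoints only
  expect_equal(assign_center_frequencies(2, 220, 3000)$center_freqs, c(220, 3000))
  expect_error(assign_center_frequencies(24, 220, 9000, 1024, 16000), "Nyquist")
})

test_that("spectrogram assembly is additive per bin and max-normalized", {
  a <- assign_center_frequencies(2, 1000, 1005, 1024, 16000)  # both -> same bin
  expect_equal(a$bins[1], a$bins[2])
  series <- rbind(c(1, 2, 3), c(4, 5, 6))
  spec <- build_spectrogram(series, a)
  row <- a$bins[1] + 1
  expect_equal(spec$S_mag[row, ], (series[1, ] + series[2, ]) / 9)  # additive, /max
  expect_equal(max(spec$S_mag), 1)
  expect_equal(sum(spec$S_mag > 0), 3)

  z <- build_spectrogram(matrix(0, 2, 3), a)
  expect_true(all(z$S_mag == 0))   # all-zero input survives normalization
  expect_equal(dim(z$S_mag), c(513L, 3L))
})

test_that("stft/istft round-trip reconstructs the interior of a signal", {
  y <- sin(2 * pi * 440 * (0:31999) / 16000)
  S <- stft(y, 1024, 500)
  expect_equal(nrow(S), 513)
  yr <- istft(S, 1024, 500)
  interior <- 1025:30000
  expect_lt(max(abs(yr[interior] - y[interior])), 1e-10)
})

test_that("Griffin-Lim converges, is seeded-deterministic, and maps silence to silence", {
  y <- sin(2 * pi * 440 * (0:31999) / 16000)
  S_mag <- Mod(stft(y, 1024, 500))
  e1 <- spectral_convergence(
    griffin_lim(S_mag, griffin_lim_config(1, seed = 5), n_fft = 1024, hop = 500),
    S_mag)
  e60 <- spectral_convergence(
    griffin_lim(S_mag, griffin_lim_config(60, seed = 5), n_fft = 1024, hop = 500),
    S_mag)
  expect_lt(e60, e1)

  g1 <- griffin_lim(S_mag, griffin_lim_config(10, seed = 7), n_fft = 1024, hop = 500)
  g2 <- griffin_lim(S_mag, griffin_lim_config(10, seed = 7), n_fft = 1024, hop = 500)
  expect_identical(g1$samples, g2$samples)

  silent <- griffin_lim(matrix(0, 513, 20), griffin_lim_config(5, seed = 1),
                        n_fft = 1024, hop = 500)
  expect_true(all(silent$samples == 0))
})

test_that("sonify meets its output contract", {
  cfg <- sonify_config(gabor = mid_bank_config(),
                       timing = sonification_timing(1, 16000, 500))
  ph <- small_phantoms(n_per_class = 2)
  w <- sonify(ph$images[1, , ], cfg)
  expect_s3_class(w, "audio_waveform")
  expect_equal(w$sample_rate, 16000)
  expect_equal(length(w$samples), 16000)           # trimmed to the duration
  expect_equal(max(abs(w$samples)), 0.95, tolerance = 1e-12)

  # determinism and input-scale invariance (max-normalized spectrogram)
  w2 <- sonify(ph$images[1, , ], cfg)
  expect_identical(w$samples, w2$samples)
  w3 <- sonify(0.5 * ph$images[1, , ], cfg)
  expect_equal(w3$samples, w$samples, tolerance = 1e-9)

  expect_true(all(sonify(matrix(0, 80, 80), cfg)$samples == 0))
})

test_that("coarse and fine textures sonify to different spectral centroids", {
  cfg <- sonify_config(gabor = mid_bank_config(),
                       timing = sonification_timing(1, 16000, 500))
  coarse <- sonify(grating(80, 0.0625, pi / 6), cfg)
  fine <- sonify(grating(80, 0.25, pi / 6), cfg)
  centroid <- function(w) {
    M <- Mod(stft(w$samples, 1024, 500))
    freqs <- (0:512) * 16000 / 1024
    sum(freqs * rowSums(M)) / sum(M)
  }
  expect_gt(centroid(fine), centroid(coarse))
})

test_that("hilbert and raster sonifications of an anisotropic texture differ", {
  cfg <- sonify_config(gabor = mid_bank_config(),
                       timing = sonification_timing(1, 16000, 500))
  img <- small_phantoms(n_per_class = 2)$images[2, , ]
  wh <- sonify(img, cfg, traversal = "hilbert")
  wr <- sonify(img, cfg, traversal = "raster")
  Sh <- Mod(stft(wh$samples, 1024, 500))
  Sr <- Mod(stft(wr$samples, 1024, 500))
  expect_gt(norm(Sh - Sr, "F"), 0)
})

test_that("WAV files round-trip within one quantization step", {
  tmp <- tempfile(fileext = ".wav")
  on.exit(unlink(tmp))

  # one second of silence
  write_wav(numeric(16000), tmp, sample_rate = 16000)
  r <- read_wav(tmp)
  expect_equal(r$sample_rate, 16000)
  expect_length(r$samples, 16000)
  expect_true(all(r$samples == 0))

  # full-scale tone within PCM quantization error
  y <- sin(2 * pi * 440 * (0:15999) / 16000)
  write_wav(y, tmp, sample_rate = 16000)
  expect_lt(max(abs(read_wav(tmp)$samples - y)), 2^-15)

  # sonified phantom output
  cfg <- sonify_config(gabor = mid_bank_config(),
                       timing = sonification_timing(1, 16000, 500))
  w <- sonify(small_phantoms(n_per_class = 2)$images[3, , ], cfg)
  write_wav(w, tmp)
  expect_lt(max(abs(read_wav(tmp)$samples - w$samples)), 2^-15)

  expect_error(suppressWarnings(read_wav(tempfile())), "cannot open")
})
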