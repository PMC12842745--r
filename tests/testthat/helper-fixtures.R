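# Shared fixtures, built in code at test time.

# small 2-scale bank whose kernels fit comfortably in 32x32 test images
small_bank <- function() {
  build_gabor_bank(gabor_bank_config(n_scales = 2, n_orientations = 3,
                                     frequencies = c(0.125, 0.25)))
}

# 3-scale bank for 80x80 phantoms (coarsest kernel radius 17)
mid_bank_config <- function() {
  gabor_bank_config(n_scales = 3, n_orientations = 6,
                    frequencies = 0.25 / 2^(2:0))
}

# oriented cosine grating with x = column, y = row
grating <- function(n, f, theta, windowed = FALSE) {
  g <- outer(0:(n - 1), 0:(n - 1), function(y, x) {
    0.5 + 0.5 * cos(2 * pi * f * (x * cos(theta) + y * sin(theta)))
  })
  if (windowed) {
    c0 <- (n - 1) / 2
    w <- outer(0:(n - 1), 0:(n - 1), function(y, x) {
      exp(-((x - c0)^2 + (y - c0)^2) / (2 * (n / 5)^2))
    })
    g <- g * w
  }
  g
}

# small phantom set shared by stream-level tests (80x80; full-size phantoms
# are exercised in the acceptance suite)
phantom_cache <- new.env(parent = emptyenv())
small_phantoms <- function(n_per_class = 40, delta = 1, seed = 101) {
  key <- sprintf("p%d_%g_%d", n_per_class, delta, seed)
  if (is.null(phantom_cache[[key]])) {
    phantom_cache[[key]] <- generate_phantoms(
      phantom_config(image_size = 80, n_per_class = n_per_class,
                     effect_size = delta, seed = seed))
  }
  phantom_cache[[key]]
}

# full-scale end-to-end runs (study conditions: n = 200 slices, 150x150,
# defaults throughout), cached so several acceptance checks share one run
e2e_cache <- new.env(parent = emptyenv())
e2e_run <- function(delta, seed = 42) {
  key <- sprintf("d%g_s%d", delta, seed)
  if (is.null(e2e_cache[[key]])) {
    cfg <- default_config()
    cfg$seed <- seed
    ph <- generate_phantoms(phantom_config(
      n_per_class = 100, effect_size = delta,
      seed = substream_seed(seed, "phantoms")))
    e2e_cache[[key]] <- dual_stream_cv(ph$images, ph$manifest$label,
                                       subjects = ph$manifest$subject_id,
                                       config = cfg)
  }
  e2e_cache[[key]]
}
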