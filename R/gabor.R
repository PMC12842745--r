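#' Gabor filter bank configuration
#'
#' The bank covers `n_scales` spatial frequencies and `n_orientations`
#' directions; orientations are \eqn{\theta_k = \pi k / K} for
#' `k = 0..K-1`, covering `[0, pi)` uniformly (a Gabor magnitude response is
#' identical at \eqn{\theta} and \eqn{\theta + \pi}, so half the circle
#' suffices). Frequencies are geometrically (octave) spaced; the default
#' ladder `0.03125, 0.0625, 0.125, 0.25` cycles/pixel runs coarse to fine so
#' that scale-major channel ordering places coarse structure at the low end of
#' the audio band. The envelope constants `gamma` and `eta` (both 1 by
#' default, isotropic) and the frequency values are not fixed by the method
#' itself and are exposed here.
#'
#' @param n_scales Number of spatial scales S (default 4).
#' @param n_orientations Number of orientations K (default 6).
#' @param frequencies Centre frequencies in cycles/pixel, one per scale,
#'   strictly monotone. Default: `0.25 / 2^((n_scales-1):0)` (ascending
#'   octaves ending near Nyquist/2).
#' @param gamma,eta Gaussian envelope constants along the carrier and its
#'   normal (unitless, > 0).
#' @param truncation_sd Kernel support radius in envelope standard
#'   deviations (default 3); the kernel side is forced odd.
#' @return An object of class `gabor_bank_config`.
#' @export
gabor_bank_config <- function(n_scales = 4, n_orientations = 6,
                              frequencies = NULL, gamma = 1, eta = 1,
                              truncation_sd = 3) {
  if (n_scales < 1 || n_scales != round(n_scales)) {
    stop("n_scales must be a positive integer", call. = FALSE)
  }
  if (n_orientations < 1 || n_orientations != round(n_orientations)) {
    stop("n_orientations must be a positive integer", call. = FALSE)
  }
  if (gamma <= 0 || eta <= 0) stop("gamma and eta must be > 0", call. = FALSE)
  if (truncation_sd <= 0) stop("truncation_sd must be > 0", call. = FALSE)
  if (is.null(frequencies)) {
    frequencies <- 0.25 / 2^((n_scales - 1):0)
  }
  if (length(frequencies) != n_scales) {
    stop("frequencies must have one value per scale", call. = FALSE)
  }
  if (any(frequencies <= 0)) stop("frequencies must be positive", call. = FALSE)
  d <- diff(frequencies)
  if (n_scales > 1 && !(all(d > 0) || all(d < 0))) {
    stop("frequencies must be strictly monotone", call. = FALSE)
  }
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 frequencies = as.numeric(frequencies),
                 gamma = gamma, eta = eta, truncation_sd = truncation_sd),
            class = "gabor_bank_config")
}

# Complex Gabor kernel taps for one scale/orientation.
# g(x, y) = f^2/(pi*gamma*eta) * exp(-f^2 (x'^2/gamma^2 + y'^2/eta^2)) * exp(2*pi*i*f*x')
# with x' = x cos(theta) + y sin(theta), y' = -x sin(theta) + y cos(theta).
gabor_kernel_taps <- function(f, theta, gamma, eta, truncation_sd) {
  sd_max <- max(gamma, eta) / (f * sqrt(2))   # envelope std dev in pixels
  r <- max(1L, as.integer(ceiling(truncation_sd * sd_max)))
  g <- seq.int(-r, r)
  x <- matrix(g, 2 * r + 1, 2 * r + 1, byrow = TRUE)   # x = column offset
  y <- matrix(g, 2 * r + 1, 2 * r + 1)                 # y = row offset
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  amp <- f^2 / (pi * gamma * eta)
  env <- amp * exp(-f^2 * (xr^2 / gamma^2 + yr^2 / eta^2))
  env * exp(2i * pi * f * xr)
}

#' Build the complex Gabor filter bank
#'
#' Constructs all `S * K` kernels (default 24 = 4 scales x 6 orientations).
#' Channel order is scale-major: channel `c = sigma * K + k` (0-based), i.e.
#' all orientations of the coarsest scale first.
#'
#' @param config A [gabor_bank_config()].
#' @return An object of class `gabor_bank`: list with `kernels` (each with
#'   complex `taps`, `scale`, `orientation`, `theta`, `frequency`), the
#'   `config`, and `max_radius`, the largest kernel half-width in pixels.
#' @export
build_gabor_bank <- function(config = gabor_bank_config()) {
  stopifnot(inherits(config, "gabor_bank_config"))
  S <- config$n_scales; K <- config$n_orientations
  kernels <- vector("list", S * K)
  for (s in seq_len(S) - 1L) {
    for (k in seq_len(K) - 1L) {
      theta <- pi * k / K
      taps <- gabor_kernel_taps(config$frequencies[s + 1L], theta,
                                config$gamma, config$eta, config$truncation_sd)
      kernels[[s * K + k + 1L]] <- structure(
        list(taps = taps, scale = s, orientation = k, theta = theta,
             frequency = config$frequencies[s + 1L]),
        class = "gabor_kernel")
    }
  }
  max_radius <- max(vapply(kernels, function(k) (nrow(k$taps) - 1L) %/% 2L,
                           integer(1)))
  structure(list(kernels = kernels, config = config, max_radius = max_radius,
                 fft_cache = new.env(parent = emptyenv())),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("Gabor bank: %d scales x %d orientations = %d complex kernels\n",
              x$config$n_scales, x$config$n_orientations, length(x$kernels)))
  cat(sprintf("frequencies (cycles/pixel): %s\n",
              paste(signif(x$config$frequencies, 4), collapse = ", ")))
  invisible(x)
}

# mirror-pad (no edge repetition) by m pixels on every side
reflect_pad <- function(img, m) {
  H <- nrow(img); W <- ncol(img)
  if (m > H - 1 || m > W - 1) {
    stop(sprintf("image of size %dx%d is smaller than the filter support; minimum size is %dx%d",
                 H, W, m + 1L, m + 1L), call. = FALSE)
  }
  ri <- c(rev(seq_len(m) + 1L), seq_len(H), H - seq_len(m))
  ci <- c(rev(seq_len(m) + 1L), seq_len(W), W - seq_len(m))
  img[ri, ci, drop = FALSE]
}

# next FFT-friendly size (factors 2,3,5)
next_fast_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Gabor energy maps of a slice
#'
#' Convolves the normalized slice with every complex kernel of the bank and
#' takes the magnitude of the complex response, yielding one nonnegative
#' energy map per scale-orientation channel with the same spatial shape as
#' the input (reflect padding at the borders).
#'
#' The default path computes the convolutions in the frequency domain (one
#' forward FFT of the padded image, one inverse FFT per kernel; kernel
#' spectra are cached on the bank per image size). `method = "direct"` is a
#' sliding-window reference implementation used for verification.
#'
#' @param image Numeric matrix with values in `[0, 1]` (see
#'   [normalize_slice()]), or a `slice_image`.
#' @param bank A `gabor_bank` from [build_gabor_bank()].
#' @param method `"fft"` (default) or `"direct"`.
#' @return An `energy_map_set`: list with `maps` (array `H x W x C`, channel
#'   `c = scale * K + orientation + 1`), and `config`.
#' @export
compute_energy_maps <- function(image, bank, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (inherits(image, "slice_image")) image <- image$pixels
  stopifnot(is.matrix(image), inherits(bank, "gabor_bank"))
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("image must be normalized to [0, 1]; see normalize_slice()", call. = FALSE)
  }
  H <- nrow(image); W <- ncol(image)
  C <- length(bank$kernels)
  maps <- array(0, dim = c(H, W, C))
  if (method == "direct") {
    for (ci in seq_len(C)) {
      maps[, , ci] <- Mod(conv2_same_direct(image, bank$kernels[[ci]]$taps))
    }
  } else {
    # group kernels by support radius (one per scale): each group gets the
    # smallest padded canvas that keeps circular wrap-around out of the crop
    radii <- vapply(bank$kernels, function(k) (nrow(k$taps) - 1L) %/% 2L,
                    integer(1))
    for (r in unique(radii)) {
      padded <- reflect_pad(image, r)
      D1 <- next_fast_size(nrow(padded))
      D2 <- next_fast_size(ncol(padded))
      canvas <- matrix(0, D1, D2)
      canvas[seq_len(nrow(padded)), seq_len(ncol(padded))] <- padded
      Fimg <- stats::fft(canvas)
      members <- which(radii == r)
      key <- paste0(r, ":", D1, "x", D2)
      kf <- bank$fft_cache[[key]]
      if (is.null(kf)) {
        kf <- lapply(bank$kernels[members],
                     function(k) kernel_fft(k$taps, D1, D2))
        bank$fft_cache[[key]] <- kf
      }
      for (j in seq_along(members)) {
        full <- stats::fft(Fimg * kf[[j]], inverse = TRUE) / (D1 * D2)
        maps[, , members[j]] <- Mod(full[r + seq_len(H), r + seq_len(W)])
      }
    }
  }
  structure(list(maps = maps, config = bank$config), class = "energy_map_set")
}

# FFT of a centred kernel on a D1 x D2 canvas (kernel origin wrapped to [1,1])
kernel_fft <- function(taps, D1, D2) {
  r <- (nrow(taps) - 1L) %/% 2L
  canvas <- matrix(0 + 0i, D1, D2)
  rows <- ((seq.int(-r, r)) %% D1) + 1L
  cols <- ((seq.int(-r, r)) %% D2) + 1L
  canvas[rows, cols] <- taps
  stats::fft(canvas)
}

# direct 'same' complex convolution with reflect padding (reference path)
conv2_same_direct <- function(image, taps) {
  r <- (nrow(taps) - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  padded <- reflect_pad(image, r)
  out <- matrix(0 + 0i, H, W)
  # convolution: out(p) = sum_k taps(k) * image(p - k)
  for (i in seq_len(nrow(taps))) {
    di <- i - r - 1L
    for (j in seq_len(ncol(taps))) {
      dj <- j - r - 1L
      out <- out + taps[i, j] *
        padded[(r - di) + seq_len(H), (r - dj) + seq_len(W)]
    }
  }
  out
}

#' Total energy per channel
#'
#' Sum of each energy map over all pixels; handy for finding the dominant
#' scale/orientation channel of a texture.
#'
#' @param maps An `energy_map_set`.
#' @return A tibble with columns `channel` (1-based), `scale`, `orientation`,
#'   `energy`.
#' @export
channel_energies <- function(maps) {
  stopifnot(inherits(maps, "energy_map_set"))
  C <- dim(maps$maps)[3]
  K <- maps$config$n_orientations
  tibble::tibble(channel = seq_len(C),
                 scale = (seq_len(C) - 1L) %/% K,
                 orientation = (seq_len(C) - 1L) %% K,
                 energy = apply(maps$maps, 3, sum))
}
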