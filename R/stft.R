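# Short-time Fourier analysis/synthesis used by the sonification stage.
# Frames are non-centred: frame t covers samples (t-1)*hop + 1 .. (t-1)*hop + n_fft,
# so a signal of length (T-1)*hop + n_fft yields exactly T frames and
# stft(istft(S)) preserves the frame count -- the property Griffin-Lim needs.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Short-time Fourier transform (one-sided)
#'
#' @param y Numeric signal.
#' @param n_fft FFT size (default 1024).
#' @param hop Hop size in samples (default 500).
#' @return Complex matrix `(n_fft/2 + 1) x T` of one-sided spectra
#'   (Hann-windowed, non-centred frames).
#' @export
stft <- function(y, n_fft = 1024, hop = 500) {
  if (length(y) < n_fft) stop("signal shorter than one FFT frame", call. = FALSE)
  n_frames <- 1L + (length(y) - n_fft) %/% hop
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(y[idx], n_fft, n_frames) * hann_window(n_fft)
  S <- stats::mvfft(frames)
  S[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]
}

#' Inverse short-time Fourier transform (overlap-add)
#'
#' Reconstructs a real signal of length `(T-1)*hop + n_fft` from a one-sided
#' complex spectrogram, using Hann-windowed overlap-add with squared-window
#' normalization.
#'
#' @param S Complex (or numeric) matrix `(n_fft/2 + 1) x T`.
#' @param n_fft FFT size.
#' @param hop Hop size in samples.
#' @return Numeric signal.
#' @export
istft <- function(S, n_fft = 1024, hop = 500) {
  F_bins <- n_fft %/% 2 + 1L
  stopifnot(nrow(S) == F_bins)
  n_frames <- ncol(S)
  full <- rbind(S, Conj(S[seq.int(F_bins - 1L, 2L), , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  w <- hann_window(n_fft)
  frames <- frames * w
  len <- (n_frames - 1L) * hop + n_fft
  y <- numeric(len)
  wsum <- numeric(len)
  for (t in seq_len(n_frames)) {
    sl <- (t - 1L) * hop + seq_len(n_fft)
    y[sl] <- y[sl] + frames[, t]
    wsum[sl] <- wsum[sl] + w^2
  }
  y / pmax(wsum, 1e-12)
}

#' Griffin-Lim configuration
#'
#' @param n_iterations Number of phase-refinement iterations (default 60).
#' @param seed RNG seed for the random phase initialization; fixing it makes
#'   reconstruction bit-reproducible.
#' @return An object of class `griffin_lim_config`.
#' @export
griffin_lim_config <- function(n_iterations = 60, seed = 1) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations), seed = seed),
            class = "griffin_lim_config")
}

# run code with a temporary RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Griffin-Lim phase reconstruction
#'
#' Estimates a waveform whose STFT magnitude matches a target magnitude
#' spectrogram: starting from seeded random phase, alternately inverts
#' (ISTFT) and re-analyses (STFT), keeping the analysed phase and re-imposing
#' the target magnitude each iteration. Deterministic for a fixed seed. An
#' all-zero spectrogram returns silence.
#'
#' @param spec A `composite_spectrogram` from [build_spectrogram()], or a
#'   plain nonnegative magnitude matrix `(n_fft/2 + 1) x T`.
#' @param config A [griffin_lim_config()].
#' @param n_fft,hop STFT parameters; taken from `spec` when it is a
#'   `composite_spectrogram`.
#' @return An `audio_waveform` (pre peak-normalization): list with `samples`
#'   and `sample_rate` (NA when the input is a bare matrix without timing).
#' @export
griffin_lim <- function(spec, config = griffin_lim_config(),
                        n_fft = NULL, hop = NULL) {
  if (inherits(spec, "composite_spectrogram")) {
    S_mag <- spec$S_mag
    if (is.null(n_fft)) n_fft <- spec$n_fft
    if (is.null(hop)) hop <- spec$hop
    sr <- spec$sample_rate
  } else {
    S_mag <- spec
    sr <- NA_real_
  }
  if (is.null(n_fft) || is.null(hop)) {
    stop("n_fft and hop are required for a bare magnitude matrix", call. = FALSE)
  }
  stopifnot(all(S_mag >= 0))
  phase <- with_seed(config$seed, {
    matrix(stats::runif(length(S_mag), -pi, pi), nrow(S_mag), ncol(S_mag))
  })
  # precomputed geometry shared by all iterations
  F_bins <- nrow(S_mag); n_frames <- ncol(S_mag)
  w <- hann_window(n_fft)
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  len <- (n_frames - 1L) * hop + n_fft
  wsum <- numeric(len)
  for (t in seq_len(n_frames)) {
    sl <- (t - 1L) * hop + seq_len(n_fft)
    wsum[sl] <- wsum[sl] + w^2
  }
  wsum <- pmax(wsum, 1e-12)
  mir <- seq.int(F_bins - 1L, 2L)
  # frames q hops apart never overlap, so overlap-add runs collision-free in
  # q vectorized scatters
  q <- as.integer(ceiling(n_fft / hop))
  groups <- split(seq_len(n_frames), (seq_len(n_frames) - 1L) %% q)
  synth <- function(Z) {
    full <- rbind(Z, Conj(Z[mir, , drop = FALSE]))
    frames <- (Re(stats::mvfft(full, inverse = TRUE)) / n_fft) * w
    y <- numeric(len)
    for (g in groups) {
      ii <- idx[, g]
      y[ii] <- y[ii] + frames[, g]
    }
    y / wsum
  }
  # the phase is carried as the complex spectrum itself; re-imposing the
  # target magnitude is S_mag * Z/|Z| (identical to S_mag * exp(i*Arg(Z))
  # away from exact zeros, and cheaper than Arg + exp)
  Z <- S_mag * exp(1i * phase)
  y <- NULL
  for (i in seq_len(config$n_iterations)) {
    y <- synth(Z)
    fr <- y[idx]
    dim(fr) <- c(n_fft, n_frames)
    Znew <- stats::mvfft(fr * w)[seq_len(F_bins), , drop = FALSE]
    Z <- S_mag * (Znew / pmax(Mod(Znew), 1e-300))
  }
  y <- synth(Z)
  structure(list(samples = y, sample_rate = sr), class = "audio_waveform")
}

#' Spectral convergence error
#'
#' Relative Frobenius distance between the STFT magnitude of a waveform and a
#' target magnitude spectrogram; the quantity Griffin-Lim drives down.
#'
#' @param y Numeric signal or `audio_waveform`.
#' @param S_mag Target magnitude matrix.
#' @param n_fft,hop STFT parameters.
#' @return A single numeric error.
#' @export
spectral_convergence <- function(y, S_mag, n_fft = 1024, hop = 500) {
  if (inherits(y, "audio_waveform")) y <- y$samples
  M <- Mod(stft(y, n_fft = n_fft, hop = hop))
  tc <- min(ncol(M), ncol(S_mag))
  norm(M[, seq_len(tc)] - S_mag[, seq_len(tc)], "F") / max(norm(S_mag, "F"), 1e-12)
}
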