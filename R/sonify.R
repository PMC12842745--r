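#' Assign geometric centre frequencies to the Gabor channels
#'
#' Places `C` channels on a geometric ladder from `f_min` to `f_max`
#' (inclusive endpoints, constant adjacent ratio `(f_max/f_min)^(1/(C-1))`),
#' and snaps each centre frequency to its nearest STFT bin. With scale-major
#' channel ordering and an ascending Gabor frequency ladder, coarse spatial
#' structure lands at the low end of the audio band and fine texture at the
#' high end.
#'
#' Note on units: the band defaults are 220 Hz and 3000 Hz. (A kHz reading of
#' the upper edge would exceed the Nyquist frequency of the 16 kHz signal,
#' so the band is in Hz.)
#'
#' @param n_channels Number of channels C (>= 2; default `S * K` = 24).
#' @param f_min,f_max Band edges in Hz; `0 < f_min < f_max < sample_rate/2`.
#' @param n_fft STFT size (default 1024).
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @return An object of class `frequency_assignment`: list with
#'   `center_freqs` (Hz), `bins` (0-based STFT bin indices), `f_min`,
#'   `f_max`, `n_fft`, `sample_rate`.
#' @export
assign_center_frequencies <- function(n_channels = 24, f_min = 220, f_max = 3000,
                                      n_fft = 1024, sample_rate = 16000) {
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (!(f_min > 0 && f_max > f_min)) stop("need 0 < f_min < f_max", call. = FALSE)
  if (f_max >= sample_rate / 2) {
    stop(sprintf("f_max = %g Hz is at or above the Nyquist frequency %g Hz",
                 f_max, sample_rate / 2), call. = FALSE)
  }
  cvec <- seq_len(n_channels) - 1L
  center_freqs <- f_min * (f_max / f_min)^(cvec / (n_channels - 1L))
  bin_hz <- sample_rate / n_fft
  bins <- as.integer(round(center_freqs / bin_hz))
  structure(list(center_freqs = center_freqs, bins = bins,
                 f_min = f_min, f_max = f_max,
                 n_fft = as.integer(n_fft), sample_rate = sample_rate),
            class = "frequency_assignment")
}

#' Assemble channel time series into a composite magnitude spectrogram
#'
#' Each channel's time series is added into the spectrogram row of its
#' assigned STFT bin (additive, so channels sharing a bin superpose), then
#' the whole array is max-normalized to `[0, 1]` (an all-zero input stays
#' zero). `normalize = "frame"` normalizes each time frame by its own
#' maximum instead.
#'
#' @param series A `channel_timeseries` from [path_to_timeseries()], or a
#'   plain nonnegative `C x T` matrix.
#' @param assignment A [assign_center_frequencies()] result with matching
#'   channel count.
#' @param hop Hop size in samples carried along for synthesis (default 500).
#' @param normalize `"global"` (default) or `"frame"`.
#' @return An object of class `composite_spectrogram`: list with `S_mag`
#'   (`(n_fft/2 + 1) x T`), `n_fft`, `hop`, `sample_rate`, `assignment`.
#' @export
build_spectrogram <- function(series, assignment, hop = 500,
                              normalize = c("global", "frame")) {
  normalize <- match.arg(normalize)
  values <- if (inherits(series, "channel_timeseries")) series$values else series
  stopifnot(inherits(assignment, "frequency_assignment"))
  if (nrow(values) != length(assignment$bins)) {
    stop(sprintf("series has %d channels but the assignment has %d",
                 nrow(values), length(assignment$bins)), call. = FALSE)
  }
  if (any(values < 0)) stop("channel series must be nonnegative", call. = FALSE)
  F_bins <- assignment$n_fft %/% 2 + 1L
  S <- matrix(0, F_bins, ncol(values))
  for (c in seq_len(nrow(values))) {
    row <- assignment$bins[c] + 1L
    S[row, ] <- S[row, ] + values[c, ]
  }
  if (normalize == "global") {
    mx <- max(S)
    if (mx > 0) S <- S / mx
  } else {
    mx <- apply(S, 2, max)
    pos <- mx > 0
    S[, pos] <- sweep(S[, pos, drop = FALSE], 2, mx[pos], "/")
  }
  structure(list(S_mag = S, n_fft = assignment$n_fft, hop = as.integer(hop),
                 sample_rate = assignment$sample_rate, assignment = assignment),
            class = "composite_spectrogram")
}

#' Sonification configuration
#'
#' Bundles all tunables of the image-to-audio pipeline. Defaults follow the
#' method's stated constants (16 kHz output, 4 x 6 Gabor bank, 220-3000 Hz
#' band) with the remaining free parameters (2 s duration, hop 500, 1024-pt
#' FFT, 60 Griffin-Lim iterations) chosen so the 24 geometric bands resolve
#' to distinct STFT bins.
#'
#' @param gabor A [gabor_bank_config()].
#' @param timing A [sonification_timing()].
#' @param f_min,f_max Audio band edges in Hz.
#' @param n_fft STFT size in samples.
#' @param griffin_lim A [griffin_lim_config()].
#' @param peak Peak amplitude target after normalization (default 0.95,
#'   headroom against PCM clipping).
#' @return An object of class `sonify_config`.
#' @export
sonify_config <- function(gabor = gabor_bank_config(),
                          timing = sonification_timing(),
                          f_min = 220, f_max = 3000, n_fft = 1024,
                          griffin_lim = griffin_lim_config(),
                          peak = 0.95) {
  if (timing$hop > n_fft) {
    stop("hop must not exceed n_fft (frames must overlap or abut)", call. = FALSE)
  }
  structure(list(gabor = gabor, timing = timing, f_min = f_min, f_max = f_max,
                 n_fft = as.integer(n_fft), griffin_lim = griffin_lim,
                 peak = peak),
            class = "sonify_config")
}

#' Sonify a 2D slice
#'
#' Full image-to-audio pipeline: min-max normalization, Gabor energy maps,
#' Hilbert (or raster) traversal restricted to the image, segmentation into
#' time frames, per-segment averaging into channel time series, geometric
#' frequency assignment, composite spectrogram, Griffin-Lim phase
#' reconstruction, peak normalization, and trimming to the requested
#' duration. Deterministic for a fixed Griffin-Lim seed; an all-zero slice
#' yields silence.
#'
#' @param image Numeric matrix (any intensity range; normalized internally)
#'   or a `slice_image`.
#' @param config A [sonify_config()].
#' @param traversal `"hilbert"` (default) or `"raster"` (the
#'   locality-ablation baseline).
#' @param bank Optional prebuilt `gabor_bank` (rebuilt from `config$gabor`
#'   when `NULL`); passing one amortizes kernel FFTs across many slices.
#' @return An `audio_waveform` with `samples` (peak <= `config$peak`) and
#'   `sample_rate`.
#' @export
sonify <- function(image, config = sonify_config(),
                   traversal = c("hilbert", "raster"), bank = NULL) {
  traversal <- match.arg(traversal)
  slice <- if (inherits(image, "slice_image")) image else normalize_slice(image)
  if (is.null(bank)) bank <- build_gabor_bank(config$gabor)
  maps <- compute_energy_maps(slice, bank)
  path <- if (traversal == "hilbert") {
    hilbert_path_for_image(slice$H, slice$W)
  } else {
    raster_path(slice$H, slice$W)
  }
  seg <- segment_path(path, config$timing)
  series <- path_to_timeseries(maps, seg)
  assignment <- assign_center_frequencies(
    n_channels = nrow(series$values),
    f_min = config$f_min, f_max = config$f_max,
    n_fft = config$n_fft, sample_rate = config$timing$sample_rate)
  spec <- build_spectrogram(series, assignment, hop = config$timing$hop)
  wave <- griffin_lim(spec, config$griffin_lim)
  n_target <- round(config$timing$duration_sec * config$timing$sample_rate)
  y <- wave$samples[seq_len(min(n_target, length(wave$samples)))]
  peak <- max(abs(y))
  if (peak > 0) y <- y * (config$peak / peak)
  structure(list(samples = y, sample_rate = config$timing$sample_rate),
            class = "audio_waveform")
}

#' @export
print.audio_waveform <- function(x, ...) {
  cat(sprintf("audio_waveform: %d samples @ %s Hz (%.3f s), peak %.3f\n",
              length(x$samples),
              ifelse(is.na(x$sample_rate), "?", format(x$sample_rate)),
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16-bit; the read/write
#' round trip error is at most half a quantization step (`< 2^-15`).
#'
#' @param waveform An `audio_waveform` (or numeric vector, in which case
#'   `sample_rate` must be given).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz when `waveform` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = NULL) {
  if (inherits(waveform, "audio_waveform")) {
    samples <- waveform$samples
    sample_rate <- waveform$sample_rate
  } else {
    samples <- waveform
  }
  if (is.null(sample_rate) || is.na(sample_rate)) {
    stop("sample_rate is required", call. = FALSE)
  }
  if (any(!is.finite(samples))) stop("waveform contains non-finite samples", call. = FALSE)
  q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV
#'
#' @param path File path.
#' @return An `audio_waveform` with samples in `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported", call. = FALSE)
      if (fmt[2] != 1L) stop("only mono WAV is supported", call. = FALSE)
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV is supported", call. = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(sample_rate)) stop("data chunk before fmt chunk", call. = FALSE)
      q <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little",
                   signed = TRUE)
      return(structure(list(samples = q / 32767, sample_rate = sample_rate),
                       class = "audio_waveform"))
    } else {
      readBin(con, "raw", size)
    }
  }
}
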