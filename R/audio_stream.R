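# Audio stream: frozen frame-level embedder -> pooled feature vector ->
# random forest classifier.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank, rows = bands, cols = FFT bins (one-sided)
mel_filterbank <- function(n_mels, n_fft, sample_rate, f_lo = 60, f_hi = NULL) {
  if (is.null(f_hi)) f_hi <- sample_rate / 2
  edges <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_mels + 2))
  bin_freqs <- (0:(n_fft %/% 2)) * sample_rate / n_fft
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel filterbank-statistics embedder
#'
#' A dependency-light frozen audio embedder: the waveform is cut into
#' analysis windows (default 0.96 s, hop 0.48 s); within each window,
#' short-time log-mel band energies are computed (default 32 triangular mel
#' bands on a 1024-point STFT) and summarized by their per-band mean and
#' standard deviation over time, giving one `2 * n_mels`-dimensional frame
#' embedding per window. Deterministic, no training, no model download.
#'
#' @param n_mels Number of mel bands (default 32; embedding dim `2 * n_mels`).
#' @param window_sec,hop_sec Embedder frame length and hop in seconds
#'   (defaults 0.96 / 0.48).
#' @param n_fft,stft_hop Inner STFT size and hop in samples.
#' @param sample_rate Expected input rate, Hz (inputs at other rates are
#'   linearly resampled).
#' @return An object of class `audio_embedder` with fields `id`, `dim`, and
#'   the frame function `fn(samples)`.
#' @export
logmel_embedder <- function(n_mels = 32, window_sec = 0.96, hop_sec = 0.48,
                            n_fft = 1024, stft_hop = 256, sample_rate = 16000) {
  fb <- mel_filterbank(n_mels, n_fft, sample_rate)
  win <- as.integer(round(window_sec * sample_rate))
  hop <- as.integer(round(hop_sec * sample_rate))
  fn <- function(samples) {
    n <- length(samples)
    if (n < win) {
      samples <- c(samples, numeric(win - n))   # zero-pad a short tail
      n <- win
    }
    starts <- seq.int(0L, n - win, by = hop)
    frames <- matrix(0, length(starts), 2L * n_mels)
    for (i in seq_along(starts)) {
      seg <- samples[starts[i] + seq_len(win)]
      M <- Mod(stft(seg, n_fft = n_fft, hop = stft_hop))
      loge <- log(fb %*% (M^2) + 1e-10)          # n_mels x time
      frames[i, ] <- c(rowMeans(loge), apply(loge, 1, stats::sd))
    }
    frames
  }
  structure(list(id = sprintf("logmel-%d", 2L * n_mels), dim = 2L * n_mels,
                 sample_rate = sample_rate, n_mels = n_mels,
                 filterbank = fb, fn = fn),
            class = "audio_embedder")
}

#' Pretrained audio embedder adapter
#'
#' Slot for a frozen pretrained audio network producing 1024-dimensional
#' frame embeddings (YAMNet-style). The backend `fn(samples)` returning an
#' `n_frames x 1024` matrix must be supplied by the user (e.g. wrapping a
#' local model runtime); without one the adapter reports its dimension but
#' refuses to embed.
#'
#' @param fn Optional backend function `function(samples) -> matrix`.
#' @param id Identifier string.
#' @return An `audio_embedder` with `dim = 1024`.
#' @export
pretrained_audio_embedder <- function(fn = NULL, id = "pretrained-1024") {
  if (is.null(fn)) {
    fn <- function(samples) {
      stop("no pretrained backend configured; supply `fn` or use logmel_embedder()",
           call. = FALSE)
    }
  }
  structure(list(id = id, dim = 1024L, sample_rate = 16000, fn = fn),
            class = "audio_embedder")
}

#' Embed a waveform
#'
#' Runs the frozen embedder on a 16 kHz mono waveform (other rates are
#' linearly resampled first) and pools the frame embeddings.
#'
#' @param waveform An `audio_waveform` or numeric vector at 16 kHz.
#' @param embedder An `audio_embedder` (default [logmel_embedder()]).
#' @param pooling `"mean"` (default; robust to duration differences) or
#'   `"flatten"` (concatenates frames; requires equal frame counts across a
#'   dataset, i.e. fixed-duration audio).
#' @return An object of class `audio_embedding`: list with `frames`
#'   (`n_frames x dim`), `pooled`, `embedder_id`, `pooling`.
#' @export
embed_audio <- function(waveform, embedder = logmel_embedder(),
                        pooling = c("mean", "flatten")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(embedder, "audio_embedder"))
  if (inherits(waveform, "audio_waveform")) {
    samples <- waveform$samples
    sr <- waveform$sample_rate
  } else {
    samples <- as.numeric(waveform)
    sr <- embedder$sample_rate
  }
  if (length(samples) == 0) stop("empty waveform", call. = FALSE)
  if (!is.na(sr) && sr != embedder$sample_rate) {
    n_out <- round(length(samples) * embedder$sample_rate / sr)
    samples <- stats::approx(seq_along(samples), samples, n = n_out)$y
  }
  frames <- embedder$fn(samples)
  pooled <- if (pooling == "mean") colMeans(frames) else as.numeric(t(frames))
  structure(list(frames = frames, pooled = pooled,
                 embedder_id = embedder$id, pooling = pooling),
            class = "audio_embedding")
}

#' Write / read a cached embedding matrix
#'
#' Stores pooled embeddings as a plain CSV matrix next to a JSON header
#' recording the embedder id, dimension and sample order, so expensive
#' embedding passes can be reused across runs.
#'
#' @param embeddings Numeric matrix (samples x features).
#' @param path CSV path; the header is written to `<path>.json`.
#' @param embedder_id Identifier of the producing embedder.
#' @param sample_ids Optional sample identifiers (defaults to row numbers).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path, embedder_id,
                             sample_ids = NULL) {
  stopifnot(is.matrix(embeddings))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(embeddings)))
  utils::write.table(embeddings, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(embedder_id = embedder_id,
                            dim = ncol(embeddings),
                            n_samples = nrow(embeddings),
                            sample_ids = sample_ids),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embeddings
#' @return `read_embeddings()`: list with `embeddings` (matrix) and the
#'   `header` list.
#' @export
read_embeddings <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  emb <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(emb) <- NULL
  if (ncol(emb) != header$dim || nrow(emb) != header$n_samples) {
    stop("embedding matrix does not match its JSON header", call. = FALSE)
  }
  list(embeddings = emb, header = header)
}

#' Random forest configuration for the audio stream
#'
#' @param n_trees Number of trees (default 100).
#' @param seed RNG seed for the forest.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), seed = seed),
            class = "forest_config")
}

#' Fit the audio-stream classifier
#'
#' Random forest on pooled audio embeddings, emitting class-1 probabilities.
#'
#' @param embeddings Numeric matrix (samples x features), or a list of
#'   `audio_embedding` objects (their pooled vectors are stacked; lengths
#'   must agree, otherwise use mean pooling or fixed-duration audio).
#' @param labels Binary labels.
#' @param config A [forest_config()].
#' @return An object of class `audio_classifier` with a fitted forest.
#' @export
fit_audio_classifier <- function(embeddings, labels, config = forest_config()) {
  if (is.list(embeddings) && !is.matrix(embeddings)) {
    lens <- vapply(embeddings, function(e) length(e$pooled), numeric(1))
    if (length(unique(lens)) != 1) {
      stop("embeddings have unequal lengths; use mean pooling or fix the audio duration",
           call. = FALSE)
    }
    embeddings <- do.call(rbind, lapply(embeddings, function(e) e$pooled))
  }
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  if (nrow(embeddings) != length(labels)) stop("embeddings/labels mismatch", call. = FALSE)
  forest <- with_seed(config$seed, {
    randomForest::randomForest(x = embeddings, y = factor(labels, levels = c(0, 1)),
                               ntree = config$n_trees)
  })
  structure(list(forest = forest, config = config, n_features = ncol(embeddings)),
            class = "audio_classifier")
}

#' @export
predict.audio_classifier <- function(object, embeddings, ...) {
  if (is.list(embeddings) && !is.matrix(embeddings)) {
    embeddings <- do.call(rbind, lapply(embeddings, function(e) e$pooled))
  }
  unname(stats::predict(object$forest, embeddings, type = "prob")[, "1"])
}
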