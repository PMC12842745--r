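#' Default pipeline configuration
#'
#' Nested configuration for every stage. Defaults reproduce the method's
#' stated constants: 16 kHz audio, 4 scales x 6 orientations, 220-3000 Hz
#' band, 100 forest trees, 5 folds, Adam with learning rate 1e-4 for 20
#' epochs at batch size 32. The remaining values (hop 500, 2 s duration,
#' 1024-point FFT, 60 Griffin-Lim iterations, envelope constants 1) are the
#' package defaults documented in the respective constructors.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    gabor = list(n_scales = 4L, n_orientations = 6L,
                 frequencies = 0.25 / 2^(3:0), gamma = 1, eta = 1,
                 truncation_sd = 3),
    timing = list(duration_sec = 2, sample_rate = 16000L, hop = 500L),
    band = list(f_min = 220, f_max = 3000),
    stft = list(n_fft = 1024L),
    griffin_lim = list(iters = 60L),
    traversal = "hilbert",
    cnn = list(learning_rate = 1e-4, epochs = 20L, batch_size = 32L),
    forest = list(n_trees = 100L),
    fusion = list(k_folds = 5L, lambda = 1e-4, threshold = 0.5),
    embedder = list(n_mels = 32L),
    phantoms = list(image_size = 150L, n_per_class = 100L, effect_size = 1,
                    texture_freq = c(0.07, 0.13),
                    ventricle_ratio = c(0.16, 0.30),
                    noise_sd = 0.04, slices_per_subject = 9L)
  ), class = "run_config")
}

check_config_keys <- function(cfg, ref, prefix = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(prefix, extra, collapse = ", ")), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) stop(sprintf("config key %s%s must be a block",
                                           prefix, k), call. = FALSE)
      check_config_keys(cfg[[k]], ref[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (any subset of the [default_config()] blocks), rejects
#' unknown keys, and merges over the defaults. `overrides` accepts
#' `"key.subkey=value"` strings (CLI `--set` style).
#'
#' @param path Optional YAML file path.
#' @param overrides Optional character vector of `key=value` overrides.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      check_config_keys(user, cfg)
      cfg <- merge_config(cfg, user)
    }
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("bad override '%s'; use key=value", ov),
                              call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    node <- cfg
    for (k in keys[-length(keys)]) {
      node <- node[[k]]
      if (is.null(node)) stop(sprintf("unknown config key: %s", kv[1]),
                              call. = FALSE)
    }
    leaf <- keys[length(keys)]
    if (is.null(node[[leaf]])) stop(sprintf("unknown config key: %s", kv[1]),
                                    call. = FALSE)
    val <- utils::type.convert(kv[2], as.is = TRUE)
    cfg <- modify_nested(cfg, keys, val)
  }
  class(cfg) <- "run_config"
  cfg
}

modify_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
  } else {
    lst[[keys[1]]] <- modify_nested(lst[[keys[1]]], keys[-1], value)
  }
  lst
}

#' Deterministic named seed substream
#'
#' Derives a stage seed from the single global seed and a stage name, so
#' every source of randomness (Griffin-Lim phase, CNN init/shuffling, forest,
#' folds, phantoms) flows from one seed yet stages can be rerun
#' independently.
#'
#' @param seed Global integer seed.
#' @param name Stage name.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 40503) %% 2147483646 + 1)
}

#' Build a sonification configuration from a pipeline config
#'
#' Assembles the [sonify_config()] for the sonification stage from the
#' nested `run_config` blocks, deriving the Griffin-Lim seed from the global
#' seed unless one is given.
#'
#' @param cfg A `run_config` from [load_config()] / [default_config()].
#' @param seed Optional explicit Griffin-Lim seed.
#' @return A `sonify_config`.
#' @export
sonify_config_from <- function(cfg, seed = NULL) {
  gl_seed <- if (is.null(seed)) substream_seed(cfg$seed, "griffin_lim") else seed
  sonify_config(
    gabor = gabor_bank_config(cfg$gabor$n_scales, cfg$gabor$n_orientations,
                              cfg$gabor$frequencies, cfg$gabor$gamma,
                              cfg$gabor$eta, cfg$gabor$truncation_sd),
    timing = sonification_timing(cfg$timing$duration_sec,
                                 cfg$timing$sample_rate, cfg$timing$hop),
    f_min = cfg$band$f_min, f_max = cfg$band$f_max,
    n_fft = cfg$stft$n_fft,
    griffin_lim = griffin_lim_config(cfg$griffin_lim$iters, gl_seed))
}

# stable hexadecimal FNV-1a hash of a config (for artifact stamping)
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
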