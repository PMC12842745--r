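# End-to-end orchestration: sonify every slice, run both streams with
# out-of-fold cross-validation, fit the logistic fusion, report metrics.

#' Sonify a set of slices
#'
#' @param images Array `(n, H, W)` with values in `[0, 1]`, or list of
#'   matrices.
#' @param config A `run_config`.
#' @param out_dir Optional directory to write one WAV per slice.
#' @param traversal `"hilbert"` or `"raster"` (defaults to the config value).
#' @return List of `audio_waveform`s (invisibly gains `paths` attribute when
#'   written).
#' @export
sonify_set <- function(images, config = default_config(), out_dir = NULL,
                       traversal = NULL) {
  if (is.list(images)) images <- aperm(simplify2array(images), c(3, 1, 2))
  if (is.null(traversal)) traversal <- config$traversal
  scfg <- sonify_config_from(config)
  bank <- build_gabor_bank(scfg$gabor)
  n <- dim(images)[1]
  waves <- vector("list", n)
  for (i in seq_len(n)) {
    waves[[i]] <- sonify(images[i, , ], scfg, traversal = traversal, bank = bank)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, sprintf("slice_%04d.wav", seq_len(n)))
    for (i in seq_len(n)) write_wav(waves[[i]], paths[i])
    attr(waves, "paths") <- paths
  }
  waves
}

# stream trainer factories (the closures oof_predictions() consumes)

image_stream_trainer <- function(config) {
  function(train_images, train_labels, seed) {
    model <- train_image_stream(
      train_images, train_labels,
      training_config(learning_rate = config$cnn$learning_rate,
                      epochs = config$cnn$epochs,
                      batch_size = config$cnn$batch_size, seed = seed))
    function(new_images) predict(model, new_images)
  }
}

audio_stream_trainer <- function(config) {
  function(train_embeddings, train_labels, seed) {
    clf <- fit_audio_classifier(train_embeddings, train_labels,
                                forest_config(config$forest$n_trees, seed))
    function(new_embeddings) predict(clf, new_embeddings)
  }
}

#' Dual-stream out-of-fold cross-validation
#'
#' The core of the dual-stream framework on in-memory data: sonifies every
#' slice, embeds the audio, builds a stratified (subject-grouped when
#' `subjects` is given) fold plan, produces out-of-fold probabilities from
#' both streams, fits the logistic fusion on the stacked pairs, and reports
#' per-stream and fused metrics.
#'
#' @param images Array `(n, H, W)`, intensities in `[0, 1]`.
#' @param labels Binary labels.
#' @param subjects Optional subject/group ids (prevents a subject's slices
#'   from spanning folds).
#' @param config A `run_config`.
#' @param waves Optional precomputed list of `audio_waveform`s (skips
#'   sonification).
#' @return List of class `dual_stream_cv`: `oof` tibble (`index`, `fold`,
#'   `label`, `p_image`, `p_audio`, `p_fusion`), `metrics` tibble (one row
#'   per stream and for the fusion), `fusion_model`, `fold_plan`, `config`.
#' @export
dual_stream_cv <- function(images, labels, subjects = NULL,
                           config = default_config(), waves = NULL) {
  labels <- as_binary_labels(labels)
  if (is.null(waves)) waves <- sonify_set(images, config)
  embedder <- logmel_embedder(n_mels = config$embedder$n_mels,
                              sample_rate = config$timing$sample_rate)
  emb <- do.call(rbind, lapply(waves, function(w) embed_audio(w, embedder)$pooled))
  plan <- make_fold_plan(labels, k = config$fusion$k_folds,
                         seed = substream_seed(config$seed, "folds"),
                         group_ids = subjects)
  stacked <- oof_predictions(
    streams = list(image = images, audio = emb),
    labels = labels, plan = plan,
    trainers = list(image = image_stream_trainer(config),
                    audio = audio_stream_trainer(config)),
    seed = config$seed)
  fusion <- fit_fusion(stacked, lambda = config$fusion$lambda)
  # fused performance is estimated leakage-free: the meta-classifier
  # evaluated on fold k was fitted on the other folds' OOF pairs
  stacked$p_fusion <- crossfit_fusion(stacked, lambda = config$fusion$lambda)
  th <- config$fusion$threshold
  metrics <- rbind(
    cbind(stream = "image", compute_metrics(stacked$label, stacked$p_image, th)),
    cbind(stream = "audio", compute_metrics(stacked$label, stacked$p_audio, th)),
    cbind(stream = "fusion", compute_metrics(stacked$label, stacked$p_fusion, th)))
  structure(list(oof = stacked, metrics = tibble::as_tibble(metrics),
                 fusion_model = fusion, fold_plan = plan, config = config),
            class = "dual_stream_cv")
}

#' @export
print.dual_stream_cv <- function(x, ...) {
  cat("dual-stream out-of-fold cross-validation\n")
  print(as.data.frame(x$metrics[, c("stream", "accuracy", "sensitivity",
                                    "specificity", "auc")]), row.names = FALSE)
  invisible(x)
}

read_manifest_images <- function(manifest) {
  stopifnot(all(c("path", "label") %in% names(manifest)))
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing) > 0) {
    stop(sprintf("manifest file not found: %s", missing[1]), call. = FALSE)
  }
  slices <- lapply(manifest$path, function(p) read_slice_image(p)$pixels)
  aperm(simplify2array(slices), c(3, 1, 2))
}

#' Train the full dual-stream pipeline from a manifest
#'
#' Loads the slices listed in a manifest (columns `path`, `label`, optional
#' `subject_id`), sonifies them into `<out_dir>/wav/`, runs
#' [dual_stream_cv()], refits both streams on all training data (the
#' deployment models), and writes every artifact to `out_dir`: the OOF
#' table, metrics JSON, serialized models with a JSON sidecar (config hash
#' and seed), the resolved config, and a plain-text log.
#'
#' @param manifest Data frame or path to a manifest CSV.
#' @param config A `run_config`.
#' @param out_dir Run directory to create.
#' @return The run directory path, invisibly; see the written artifacts.
#' @export
run_pipeline <- function(manifest, config = default_config(), out_dir) {
  t_start <- Sys.time()
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  hash <- config_hash(config)
  logf("run start; config hash %s, seed %d, n = %d slices",
       hash, config$seed, nrow(manifest))
  images <- read_manifest_images(manifest)
  labels <- as_binary_labels(manifest$label)
  subjects <- if ("subject_id" %in% names(manifest)) manifest$subject_id else NULL
  logf("loaded %d slices (%dx%d)", dim(images)[1], dim(images)[2], dim(images)[3])
  waves <- sonify_set(images, config, out_dir = file.path(out_dir, "wav"))
  logf("sonified %d slices at %d Hz", length(waves), config$timing$sample_rate)
  cv <- dual_stream_cv(images, labels, subjects, config, waves = waves)
  logf("out-of-fold AUC: image %.3f, audio %.3f, fused %.3f",
       cv$metrics$auc[1], cv$metrics$auc[2], cv$metrics$auc[3])
  # deployment models refitted on all training data
  final_image <- train_image_stream(
    images, labels,
    training_config(config$cnn$learning_rate, config$cnn$epochs,
                    config$cnn$batch_size,
                    seed = substream_seed(config$seed, "image_final")))
  embedder <- logmel_embedder(n_mels = config$embedder$n_mels,
                              sample_rate = config$timing$sample_rate)
  emb <- do.call(rbind, lapply(waves, function(w) embed_audio(w, embedder)$pooled))
  final_audio <- fit_audio_classifier(
    emb, labels, forest_config(config$forest$n_trees,
                               substream_seed(config$seed, "forest_final")))
  logf("refit deployment models on all %d samples", length(labels))
  utils::write.csv(cv$oof, file.path(out_dir, "oof.csv"), row.names = FALSE)
  jsonlite::write_json(cv$metrics, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.csv(cv$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  write_embeddings(emb, file.path(out_dir, "embeddings.csv"),
                   embedder_id = embedder$id,
                   sample_ids = basename(manifest$path))
  saveRDS(list(image = final_image, audio = final_audio,
               fusion = cv$fusion_model, embedder_n_mels = config$embedder$n_mels),
          file.path(out_dir, "models.rds"))
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            trained = format(t_start),
                            n_samples = length(labels)),
                       file.path(out_dir, "models.json"), auto_unbox = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  logf("run complete in %.1f s", as.numeric(difftime(Sys.time(), t_start, "secs")))
  invisible(out_dir)
}

#' Evaluate a trained run on a test manifest
#'
#' Loads the deployment models from a [run_pipeline()] directory, sonifies
#' and scores the test slices through both streams and the fusion, and
#' writes a metrics report.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param manifest Test manifest (data frame or CSV path) with `path` and
#'   `label`.
#' @param report Optional path for a JSON metrics report.
#' @return List with `predictions` tibble and `metrics` tibble.
#' @export
evaluate_pipeline <- function(run_dir, manifest, report = NULL) {
  models <- readRDS(file.path(run_dir, "models.rds"))
  config <- load_config(file.path(run_dir, "config.yaml"))
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  images <- read_manifest_images(manifest)
  labels <- as_binary_labels(manifest$label)
  waves <- sonify_set(images, config)
  embedder <- logmel_embedder(n_mels = models$embedder_n_mels,
                              sample_rate = config$timing$sample_rate)
  emb <- do.call(rbind, lapply(waves, function(w) embed_audio(w, embedder)$pooled))
  p_image <- predict(models$image, images)
  p_audio <- predict(models$audio, emb)
  p_fusion <- predict_fusion(models$fusion, p_image, p_audio)
  th <- config$fusion$threshold
  metrics <- rbind(
    cbind(stream = "image", compute_metrics(labels, p_image, th)),
    cbind(stream = "audio", compute_metrics(labels, p_audio, th)),
    cbind(stream = "fusion", compute_metrics(labels, p_fusion, th)))
  out <- list(predictions = tibble::tibble(path = manifest$path, label = labels,
                                           p_image = p_image, p_audio = p_audio,
                                           p_fusion = p_fusion),
              metrics = tibble::as_tibble(metrics))
  if (!is.null(report)) {
    jsonlite::write_json(out$metrics, report, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
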