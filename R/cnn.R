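#' Image-stream network architecture
#'
#' Describes the lightweight attention-fusion network used on 2D slices:
#' three depthwise-separable convolution blocks (3x3 kernels, 32/64/128
#' filters, ReLU, 2x2 max-pool with floor division), a per-block branch
#' (flatten, dense 32, layer normalization), branch stacking, a shared
#' dense(32, ReLU) and shared dense(1) producing one logit per branch,
#' softmax attention over the three logits, an attention-weighted sum of the
#' stacked branch vectors, and a final dense(1, sigmoid) output.
#'
#' Grayscale slices are replicated to three channels to match the
#' `150 x 150 x 3` input.
#'
#' @param input_shape Integer vector `c(H, W, channels)`; default
#'   `c(150, 150, 3)`.
#' @param filters Per-block filter counts; default `c(32, 64, 128)`.
#' @param dense_units Branch embedding width; default 32.
#' @return An object of class `cnn_spec`.
#' @export
cnn_architecture <- function(input_shape = c(150, 150, 3),
                             filters = c(32, 64, 128), dense_units = 32) {
  stopifnot(length(input_shape) == 3, input_shape[3] == 3,
            length(filters) == 3, dense_units >= 1)
  H <- input_shape[1]; W <- input_shape[2]
  pooled <- list()
  h <- H; w <- W
  for (i in 1:3) {
    h <- h %/% 2L; w <- w %/% 2L
    pooled[[i]] <- c(h, w, filters[i])
  }
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 pooled_shapes = pooled,
                 flatten_sizes = vapply(pooled, prod, numeric(1))),
            class = "cnn_spec")
}

#' Per-layer parameter and shape table
#'
#' Reproduces the architecture table of the image stream: every layer with
#' its output shape and trainable parameter count. Separable convolutions
#' count `3*3*C_in` depthwise taps, `C_in*C_out` pointwise weights and
#' `C_out` biases; dense layers `n_in*n_out + n_out`; layer normalization
#' `2 * width`.
#'
#' @param spec A [cnn_architecture()].
#' @return A tibble with columns `layer`, `output_shape`, `params`,
#'   `connected_to`.
#' @export
cnn_layer_table <- function(spec = cnn_architecture()) {
  stopifnot(inherits(spec, "cnn_spec"))
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  f <- spec$filters; d <- spec$dense_units
  cin <- c(3L, f[1], f[2])
  sep_params <- 9L * cin + cin * f + f
  conv_shapes <- character(3); pool_shapes <- character(3)
  h <- H; w <- W
  for (i in 1:3) {
    conv_shapes[i] <- sprintf("%dx%dx%d", h, w, f[i])
    h <- h %/% 2L; w <- w %/% 2L
    pool_shapes[i] <- sprintf("%dx%dx%d", h, w, f[i])
  }
  flat <- spec$flatten_sizes
  dense_params <- flat * d + d
  tibble::tibble(
    layer = c("Input",
              "Sep_Conv2D_B1", "Max_Pooling_B1",
              "Sep_Conv2D_B2", "Max_Pooling_B2",
              "Sep_Conv2D_B3", "Max_Pooling_B3",
              "Flatten_B1", "Flatten_B2", "Flatten_B3",
              "Dense_B1", "Dense_B2", "Dense_B3",
              "Layer_Normalization_B1", "Layer_Normalization_B2",
              "Layer_Normalization_B3",
              "Stacked", "TimeDistributed_Dense_32_ReLU",
              "TimeDistributed_Dense_1_Linear", "Attention_Weights_SoftMax",
              "Fused_Weighted_Sum", "Output"),
    output_shape = c(sprintf("%dx%dx%d", H, W, 3L),
                     conv_shapes[1], pool_shapes[1],
                     conv_shapes[2], pool_shapes[2],
                     conv_shapes[3], pool_shapes[3],
                     format(flat, big.mark = ",", trim = TRUE),
                     rep(as.character(d), 3),
                     rep(as.character(d), 3),
                     sprintf("3x%d", d), sprintf("3x%d", d), "3x1", "3x1",
                     as.character(d), "1"),
    params = as.integer(c(0, sep_params[1], 0, sep_params[2], 0,
                          sep_params[3], 0, 0, 0, 0,
                          dense_params, rep(2L * d, 3),
                          0, d * d + d, d + 1L, 0, 0, d + 1L)),
    connected_to = c("-", "Input", "Sep_Conv2D_B1", "Max_Pooling_B1",
                     "Sep_Conv2D_B2", "Max_Pooling_B2", "Sep_Conv2D_B3",
                     "Max_Pooling_B1", "Max_Pooling_B2", "Max_Pooling_B3",
                     "Flatten_B1", "Flatten_B2", "Flatten_B3",
                     "Dense_B1", "Dense_B2", "Dense_B3",
                     "N1, N2, N3", "Stacked", "TD_1", "TD_2",
                     "Stacked + SoftMax", "Fused"))
}

#' Count trainable parameters
#'
#' @param x A `cnn_spec` or a built `cnn_model` (counted from its actual
#'   weight arrays).
#' @return A list with `per_layer` (tibble from [cnn_layer_table()]) and
#'   `total`.
#' @export
count_parameters <- function(x = cnn_architecture()) {
  if (inherits(x, "cnn_model")) {
    tab <- cnn_layer_table(x$spec)
    total <- sum(vapply(x$weights, length, numeric(1)))
    if (total != sum(tab$params)) {
      stop("weight arrays disagree with the architecture table", call. = FALSE)
    }
  } else {
    tab <- cnn_layer_table(x)
    total <- sum(tab$params)
  }
  list(per_layer = tab, total = as.integer(total))
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build (initialize) the image-stream model
#'
#' Glorot-uniform weight initialization, zero biases, unit layer-norm gains;
#' seeded and reproducible.
#'
#' @param spec A [cnn_architecture()].
#' @param seed Integer RNG seed for the initialization.
#' @return An object of class `cnn_model`: list with `spec`, `weights`
#'   (named list of numeric matrices), `seed`, `trained`.
#' @export
build_image_model <- function(spec = cnn_architecture(), seed = 1) {
  stopifnot(inherits(spec, "cnn_spec"))
  f <- spec$filters; d <- spec$dense_units
  cin <- c(3L, f[1], f[2])
  flat <- spec$flatten_sizes
  weights <- with_seed(seed, {
    w <- list()
    for (i in 1:3) {
      w[[paste0("dw", i)]] <- glorot_uniform(9, cin[i], 9, 9)
      w[[paste0("pw", i)]] <- glorot_uniform(cin[i], f[i], cin[i], f[i])
      w[[paste0("b", i)]] <- matrix(0, f[i], 1)
    }
    for (i in 1:3) {
      w[[paste0("Wd", i)]] <- glorot_uniform(flat[i], d, flat[i], d)
      w[[paste0("bd", i)]] <- matrix(0, d, 1)
    }
    for (i in 1:3) {
      w[[paste0("g", i)]] <- matrix(1, d, 1)
      w[[paste0("be", i)]] <- matrix(0, d, 1)
    }
    w$Wt1 <- glorot_uniform(d, d, d, d)
    w$bt1 <- matrix(0, d, 1)
    w$wt2 <- glorot_uniform(d, 1, d, 1)
    w$bt2 <- matrix(0, 1, 1)
    w$wo <- glorot_uniform(d, 1, d, 1)
    w$bo <- matrix(0, 1, 1)
    w
  })
  structure(list(spec = spec, weights = weights, seed = seed, trained = FALSE,
                 history = NULL),
            class = "cnn_model")
}

# stack images into the (H*W*3, n) column layout the C++ core expects
# (one sample per column; grayscale inputs replicated across three channels)
images_to_matrix <- function(images, spec) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  if (is.list(images)) {
    images <- simplify2array(images)          # H x W x n
    images <- aperm(images, c(3, 1, 2))
  }
  dm <- dim(images)
  if (length(dm) == 3L) {
    if (dm[2] != H || dm[3] != W) {
      stop(sprintf("images are %dx%d but the model expects %dx%d",
                   dm[2], dm[3], H, W), call. = FALSE)
    }
    n <- dm[1]
    plane <- matrix(aperm(images, c(2, 3, 1)), H * W, n)   # column per sample
    X <- rbind(plane, plane, plane)
  } else if (length(dm) == 4L && dm[4] == 3L) {
    n <- dm[1]
    X <- matrix(0, H * W * 3, n)
    for (c in 1:3) {
      X[(c - 1) * H * W + seq_len(H * W), ] <-
        matrix(aperm(images[, , , c, drop = FALSE], c(2, 3, 1)), H * W, n)
    }
  } else {
    stop("images must be an (n, H, W) or (n, H, W, 3) array or list of matrices",
         call. = FALSE)
  }
  X
}

#' Training configuration for the image stream
#'
#' Defaults follow the study settings: Adam, learning rate 1e-4, 20 epochs,
#' binary cross-entropy, batch size 32.
#'
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed RNG seed controlling initialization and shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 20L,
                            batch_size = 32L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "training_config")
}

#' Train the image stream
#'
#' Fits the attention-fusion network with Adam on binary cross-entropy.
#' Deterministic for a fixed seed (single-threaded, seeded initialization and
#' shuffling).
#'
#' @param images `(n, H, W)` or `(n, H, W, 3)` array (or list of matrices),
#'   intensities in `[0, 1]`.
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @param config A [training_config()].
#' @param val_images,val_labels Optional held-out data; when given, the
#'   result carries validation probabilities.
#' @return A trained `cnn_model` with `history` (tibble: epoch, loss,
#'   accuracy) and, if validation data was supplied, `val_predictions`
#'   (tibble: probability, label).
#' @export
train_image_stream <- function(images, labels, config = training_config(),
                               val_images = NULL, val_labels = NULL) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  dm <- if (is.list(images)) c(length(images), dim(images[[1]])) else dim(images)
  spec <- cnn_architecture(input_shape = c(dm[2], dm[3], 3L))
  model <- build_image_model(spec, seed = config$seed)
  X <- images_to_matrix(images, model$spec)
  if (ncol(X) != length(labels)) stop("images/labels length mismatch", call. = FALSE)
  n <- ncol(X)
  perms <- with_seed(config$seed + 1L, {
    t(replicate(config$epochs, sample.int(n) - 1L))
  })
  if (config$epochs == 1L) perms <- matrix(perms, nrow = 1)
  fit <- cnn_train_cpp(model$weights, X, as.numeric(labels), perms,
                       config$batch_size, config$learning_rate,
                       0.9, 0.999, 1e-8,
                       model$spec$input_shape[1], model$spec$input_shape[2])
  model$weights <- fit$weights
  model$trained <- TRUE
  model$config <- config
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = as.numeric(fit$loss),
                                  accuracy = as.numeric(fit$accuracy))
  if (!is.null(val_images)) {
    p <- predict(model, val_images)
    model$val_predictions <- tibble::tibble(
      probability = p,
      label = if (is.null(val_labels)) NA_real_ else as_binary_labels(val_labels))
  }
  model
}

#' Predict slice probabilities
#'
#' @param object A trained (or freshly built) `cnn_model`.
#' @param images Images as in [train_image_stream()].
#' @param ... Unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.cnn_model <- function(object, images, ...) {
  X <- images_to_matrix(images, object$spec)
  as.numeric(cnn_predict_cpp(object$weights, X,
                             object$spec$input_shape[1],
                             object$spec$input_shape[2]))
}

#' @export
print.cnn_model <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf("attention-fusion CNN (%s input), %s trainable parameters%s\n",
              paste(x$spec$input_shape, collapse = "x"),
              format(cp$total, big.mark = ","),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

#' Softmax attention fusion of branch vectors
#'
#' Reference implementation of the attention head: weights are the softmax of
#' the branch logits and the fused vector is the weight-weighted sum of the
#' branch vectors (a convex combination).
#'
#' @param branch_vectors Numeric matrix, one row per branch (e.g. `3 x 32`).
#' @param logits One logit per branch.
#' @return List with `weights` (softmax, sums to 1) and `fused` (vector of
#'   `ncol(branch_vectors)`).
#' @export
attention_fuse <- function(branch_vectors, logits) {
  stopifnot(is.matrix(branch_vectors), nrow(branch_vectors) == length(logits),
            all(is.finite(branch_vectors)), all(is.finite(logits)))
  e <- exp(logits - max(logits))
  wts <- e / sum(e)
  list(weights = wts, fused = as.numeric(crossprod(branch_vectors, wts)))
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels", call. = FALSE)
    labels <- as.integer(labels) - 1L
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  labels
}
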