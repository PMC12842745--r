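# Stacked-generalization fusion: stratified (optionally grouped) folds,
# out-of-fold stream probabilities, logistic meta-classifier.

#' Stratified K-fold plan
#'
#' Assigns samples to `k` disjoint folds with per-fold class counts within
#' one of proportional. When `group_ids` are given (e.g. subject identifiers
#' for the nine slices of one scan), all samples of a group land in the same
#' fold, preventing within-subject leakage; stratification is then
#' approximate at the group level.
#'
#' @param labels Binary labels.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the shuffling.
#' @param group_ids Optional vector of group identifiers, same length as
#'   `labels`.
#' @return An object of class `fold_plan`: list with `assignments` tibble
#'   (`index`, `label`, `group`, `fold`), `k`, `stratified`, `grouped`.
#' @export
make_fold_plan <- function(labels, k = 5, seed = 1, group_ids = NULL) {
  labels <- as_binary_labels(labels)
  n <- length(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  fold <- integer(n)
  if (is.null(group_ids)) {
    if (any(table(labels) < k)) {
      stop(sprintf("each class needs at least k = %d members", k), call. = FALSE)
    }
    with_seed(seed, {
      for (cl in c(0, 1)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  } else {
    stopifnot(length(group_ids) == n)
    glab <- tapply(labels, group_ids, function(x) round(mean(x)))
    for (cl in c(0, 1)) {
      if (sum(glab == cl) < k) {
        stop(sprintf("each class needs at least k = %d groups", k), call. = FALSE)
      }
    }
    counts <- numeric(k)
    with_seed(seed, {
      for (cl in c(0, 1)) {
        gs <- sample(names(glab)[glab == cl])
        for (g in gs) {
          members <- which(group_ids == g)
          target <- which.min(counts)       # keep fold sizes balanced
          fold[members] <- target
          counts[target] <- counts[target] + length(members)
        }
      }
    })
  }
  structure(list(assignments = tibble::tibble(
    index = seq_len(n), label = labels,
    group = if (is.null(group_ids)) NA else group_ids,
    fold = fold),
    k = as.integer(k), stratified = TRUE, grouped = !is.null(group_ids)),
    class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  tab <- table(fold = x$assignments$fold, label = x$assignments$label)
  cat(sprintf("%d-fold %s%s plan, n = %d\n", x$k,
              if (x$stratified) "stratified" else "",
              if (x$grouped) " grouped" else "", nrow(x$assignments)))
  print(tab)
  invisible(x)
}

subset_samples <- function(data, idx) {
  if (is.matrix(data)) return(data[idx, , drop = FALSE])
  if (is.array(data)) {
    nd <- length(dim(data))
    return(do.call(`[`, c(list(data, idx), rep(list(quote(expr = )), nd - 1),
                          list(drop = FALSE))))
  }
  if (is.list(data)) return(data[idx])
  data[idx]
}

#' Out-of-fold stream predictions
#'
#' For every fold `f`, each stream's trainer is fitted on all other folds and
#' predicts fold `f`, so each sample receives exactly one probability per
#' stream from models that never saw it -- the leakage-free inputs to the
#' stacked meta-classifier.
#'
#' A trainer is a function `function(train_data, train_labels, seed)`
#' returning a prediction function `function(new_data) -> probabilities`.
#'
#' @param streams Named list of per-stream data objects (matrix/array with
#'   samples in the first dimension, or a list).
#' @param labels Binary labels.
#' @param plan A [make_fold_plan()].
#' @param trainers Named list of trainers matching `streams`.
#' @param seed Base seed; fold `f` of stream `s` trains with a seed derived
#'   from it.
#' @return A `stacked_prediction` tibble: `index`, `fold`, `label`, and one
#'   `p_<stream>` column per stream.
#' @export
oof_predictions <- function(streams, labels, plan, trainers, seed = 1) {
  stopifnot(inherits(plan, "fold_plan"), is.list(streams), is.list(trainers),
            identical(sort(names(streams)), sort(names(trainers))))
  labels <- as_binary_labels(labels)
  asg <- plan$assignments
  stopifnot(nrow(asg) == length(labels))
  out <- tibble::tibble(index = asg$index, fold = asg$fold, label = labels)
  for (s in names(streams)) {
    p <- rep(NA_real_, nrow(asg))
    for (f in seq_len(plan$k)) {
      tr <- which(asg$fold != f)
      te <- which(asg$fold == f)
      fit <- tryCatch(
        trainers[[s]](subset_samples(streams[[s]], tr), labels[tr],
                      seed = substream_seed(seed, paste0(s, "_fold", f))),
        error = function(e) {
          stop(sprintf("stream '%s' trainer failed on fold %d: %s",
                       s, f, conditionMessage(e)), call. = FALSE)
        })
      p[te] <- fit(subset_samples(streams[[s]], te))
    }
    out[[paste0("p_", s)]] <- p
  }
  class(out) <- c("stacked_prediction", class(out))
  out
}

#' Fit the logistic fusion meta-classifier
#'
#' Logistic regression on the stacked out-of-fold stream probabilities
#' \eqn{p = \sigma(w^T z + b)}, fitted with a very weak ridge penalty
#' (`lambda = 1e-4`, effectively maximum likelihood but stable under perfect
#' separation -- a two-feature model cannot meaningfully overfit).
#'
#' @param stacked A `stacked_prediction` from [oof_predictions()], or any
#'   data frame with a `label` column and two `p_*` columns.
#' @param lambda Ridge strength (default 1e-4).
#' @return An object of class `fusion_model`: list with `w` (named
#'   2-vector), `b`, `feature_names`, `lambda`.
#' @export
fit_fusion <- function(stacked, lambda = 1e-4) {
  pcols <- grep("^p_", names(stacked), value = TRUE)
  if (length(pcols) < 2) stop("need at least two stream probability columns",
                              call. = FALSE)
  y <- as_binary_labels(stacked$label)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  x <- as.matrix(stacked[, pcols])
  # glmnet warns on very small folds ("fewer than 8 observations"); tiny
  # smoke-scale fits are legitimate here and the ridge keeps them stable
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = lambda, standardize = FALSE))
  co <- as.numeric(stats::coef(fit))
  structure(list(w = stats::setNames(co[-1], pcols), b = co[1],
                 feature_names = pcols, lambda = lambda),
            class = "fusion_model")
}

#' Cross-fitted fused out-of-fold probabilities
#'
#' Leakage-free evaluation of the fusion itself: for every fold, the
#' logistic meta-classifier is fitted on the stacked out-of-fold pairs of
#' the *other* folds and predicts the held-out fold. Evaluating the
#' deployment meta-classifier (fitted on all pairs) on its own training
#' pairs would be slightly optimistic -- with few effective samples (e.g.
#' grouped subjects) that optimism is visible at chance level, so
#' performance estimates use these cross-fitted probabilities instead.
#'
#' @param stacked A `stacked_prediction` from [oof_predictions()] (needs the
#'   `fold` column).
#' @param lambda Ridge strength passed to [fit_fusion()].
#' @return Numeric vector of fused probabilities, aligned with `stacked`.
#' @export
crossfit_fusion <- function(stacked, lambda = 1e-4) {
  stopifnot("fold" %in% names(stacked))
  pcols <- grep("^p_", names(stacked), value = TRUE)
  out <- rep(NA_real_, nrow(stacked))
  for (f in unique(stacked$fold)) {
    te <- stacked$fold == f
    m <- fit_fusion(stacked[!te, , drop = FALSE], lambda = lambda)
    z <- as.matrix(stacked[te, pcols])
    out[te] <- as.numeric(1 / (1 + exp(-(z %*% m$w + m$b))))
  }
  out
}

#' Fused probability
#'
#' @param model A [fit_fusion()] model.
#' @param p_image,p_audio Stream probabilities in `[0, 1]` (order must match
#'   the columns the model was fitted on).
#' @return Fused probabilities \eqn{\sigma(w^T z + b)} in `(0, 1)`.
#' @export
predict_fusion <- function(model, p_image, p_audio) {
  stopifnot(inherits(model, "fusion_model"))
  z <- cbind(p_image, p_audio)
  if (any(z < -1e-9 | z > 1 + 1e-9)) stop("inputs must be probabilities in [0, 1]",
                                          call. = FALSE)
  as.numeric(1 / (1 + exp(-(z %*% model$w + model$b))))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("logistic fusion: p = sigmoid(%s + %.4f)\n",
              paste(sprintf("%.4f*%s", x$w, x$feature_names), collapse = " + "),
              x$b))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fusion model
#' @param x A `fusion_model`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.fusion_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$feature_names),
                 estimate = c(x$b, unname(x$w)))
}

#' One-row fusion model summary
#' @param x A `fusion_model`.
#' @param ... Unused.
#' @return Tibble with coefficient magnitudes and the ridge strength.
#' @export
glance.fusion_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$w), lambda = x$lambda,
                 max_abs_weight = max(abs(x$w)))
}
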