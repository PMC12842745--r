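test_that("stratified fold plans are balanced, disjoint and covering", {
  y <- rep(c(0, 1), each = 50)
  plan <- make_fold_plan(y, k = 5, seed = 3)
  asg <- plan$assignments
  tab <- table(asg$fold, asg$label)
  expect_true(all(tab == 10))                       # 10 of each class per fold
  expect_equal(sort(asg$index), 1:100)              # disjoint cover
  expect_error(make_fold_plan(c(0, 0, 0, 1), k = 5), "at least k")
})

test_that("grouped fold plans never split a subject across folds", {
  # nine slices per subject, as in per-scan slice sets
  subjects <- rep(sprintf("s%02d", 1:20), each = 9)
  y <- rep(rep(c(0, 1), each = 10), each = 9)
  plan <- make_fold_plan(y, k = 5, seed = 7, group_ids = subjects)
  asg <- plan$assignments
  # brute force: every subject's slices land in exactly one fold
  for (s in unique(subjects)) {
    expect_length(unique(asg$fold[asg$group == s]), 1L)
  }
  expect_equal(sort(asg$index), seq_along(y))
  expect_true(all(table(asg$fold) > 0))
})

test_that("OOF predictions cover each sample exactly once, from unseen-fold models", {
  y <- rep(c(0, 1), each = 15)
  x <- matrix(seq_along(y), ncol = 1)
  plan <- make_fold_plan(y, k = 5, seed = 1)

  # constant trainer
  const_trainer <- function(data, labels, seed) function(new) rep(0.5, nrow(new))
  oof <- oof_predictions(list(s1 = x, s2 = x), y, plan,
                         list(s1 = const_trainer, s2 = const_trainer))
  expect_equal(oof$p_s1, rep(0.5, 30))
  expect_equal(oof$p_s2, rep(0.5, 30))
  expect_equal(sort(oof$index), 1:30)
  expect_equal(oof$fold, plan$assignments$fold)

  # a trainer that records its training rows must never see the test fold
  seen_trainer <- function(data, labels, seed) {
    train_rows <- data[, 1]
    function(new) as.numeric(new[, 1] %in% train_rows)
  }
  oof <- oof_predictions(list(s1 = x, s2 = x), y, plan,
                         list(s1 = seen_trainer, s2 = seen_trainer))
  expect_true(all(oof$p_s1 == 0))   # no OOF sample was in its own training set
})

test_that("leakage canary: memorizing trainer scores at chance on permuted labels", {
  set.seed(5)
  n <- 200
  y <- mrisonify:::with_seed(5, sample(rep(c(0, 1), each = n / 2)))
  x <- matrix(seq_len(n), ncol = 1)
  # memorizes exact training labels; predicts 0.5 for unseen inputs
  memorizer <- function(data, labels, seed) {
    memory <- stats::setNames(labels, data[, 1])
    function(new) {
      key <- as.character(new[, 1])
      out <- unname(memory[key])
      out[is.na(out)] <- 0.5
      out
    }
  }
  plan <- make_fold_plan(y, k = 5, seed = 11)
  oof <- oof_predictions(list(s1 = x, s2 = x), y, plan,
                         list(s1 = memorizer, s2 = memorizer))
  # all OOF predictions are the unseen fallback -> AUC is the tie value 0.5
  expect_equal(auc_score(y, oof$p_s1), 0.5, tolerance = 0.05)
})

test_that("logistic fusion follows the sigmoid(w'z + b) contract", {
  m <- structure(list(w = c(p_image = 0, p_audio = 0), b = 0,
                      feature_names = c("p_image", "p_audio"), lambda = 1e-4),
                 class = "fusion_model")
  expect_equal(predict_fusion(m, c(0.1, 0.9), c(0.8, 0.3)), c(0.5, 0.5))

  m$w[] <- c(4, 4); m$b <- -4
  expect_equal(predict_fusion(m, 0.5, 0.5), 0.5)
  # symmetric weights -> swapping the streams changes nothing
  expect_equal(predict_fusion(m, 0.2, 0.7), predict_fusion(m, 0.7, 0.2))
  # monotone in each argument for positive weights
  expect_gt(predict_fusion(m, 0.8, 0.3), predict_fusion(m, 0.4, 0.3))

  expect_error(predict_fusion(m, 1.5, 0.5), "probabilities")
})

test_that("fusion exploits an informative stream and ignores noise", {
  set.seed(8)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  stacked <- tibble::tibble(
    label = y,
    p_image = ifelse(y == 1, runif(n, 0.55, 0.95), runif(n, 0.05, 0.45)),
    p_audio = runif(n))
  fit <- fit_fusion(stacked)
  p <- predict_fusion(fit, stacked$p_image, stacked$p_audio)
  expect_equal(mean((p >= 0.5) == y), 1.0)       # separating stream dominates
  expect_gt(fit$w["p_image"], abs(fit$w["p_audio"]))

  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "p_image", "p_audio"))
  expect_equal(glance(fit)$n_features, 2L)

  expect_error(fit_fusion(stacked[y == 1, ]), "both classes")
})

test_that("cross-fitted fusion is leakage-free fold by fold", {
  set.seed(12)
  n <- 100
  stacked <- tibble::tibble(
    fold = rep(1:5, each = n / 5),
    label = rep(c(0, 1), n / 2),
    p_image = runif(n), p_audio = runif(n))
  p <- crossfit_fusion(stacked)
  expect_true(all(p > 0 & p < 1))
  # fold k predictions reproduce a meta-model fitted without fold k
  for (f in c(1, 4)) {
    m <- fit_fusion(stacked[stacked$fold != f, ])
    expect_equal(p[stacked$fold == f],
                 predict_fusion(m, stacked$p_image[stacked$fold == f],
                                stacked$p_audio[stacked$fold == f]))
  }
})

test_that("stacking rarely hurts: fused AUC >= best stream - 0.02 over 20 replicates", {
  # surrogate stream trainers (logistic on 1-D features) keep this cheap
  logit_trainer <- function(data, labels, seed) {
    df <- data.frame(x = data[, 1], y = labels)
    fit <- suppressWarnings(stats::glm(y ~ x, df, family = stats::binomial()))
    function(new) {
      as.numeric(stats::predict(fit, data.frame(x = new[, 1]), type = "response"))
    }
  }
  worst_margin <- Inf
  for (rep in 1:20) {
    y <- mrisonify:::with_seed(rep, sample(rep(c(0, 1), each = 40)))
    x1 <- matrix(mrisonify:::with_seed(rep + 100, rnorm(80, mean = 1.4 * y)), ncol = 1)
    x2 <- matrix(mrisonify:::with_seed(rep + 200, rnorm(80, mean = 0.7 * y)), ncol = 1)
    plan <- make_fold_plan(y, k = 5, seed = rep)
    oof <- oof_predictions(list(a = x1, b = x2), y, plan,
                           list(a = logit_trainer, b = logit_trainer), seed = rep)
    fused <- predict_fusion(fit_fusion(oof), oof$p_a, oof$p_b)
    margin <- auc_score(y, fused) - max(auc_score(y, oof$p_a),
                                        auc_score(y, oof$p_b))
    worst_margin <- min(worst_margin, margin)
  }
  expect_gte(worst_margin, -0.02)
})
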