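test_that("phantom sets are reproducible and carry subject/segment structure", {
  cfg <- phantom_config(image_size = 64, n_per_class = 20, seed = 5)
  a <- generate_phantoms(cfg)
  b <- generate_phantoms(cfg)
  expect_identical(a$images, b$images)
  expect_equal(dim(a$images), c(40L, 64L, 64L))
  expect_true(all(a$images >= 0 & a$images <= 1))
  expect_equal(sum(a$manifest$label == 0), 20)
  # nine slices per subject (last subject of each class may be partial)
  sizes <- table(a$manifest$subject_id)
  expect_true(all(sizes <= 9))
  expect_equal(sort(unique(a$manifest$segment)), 4:12)
})

test_that("zero effect size makes the classes statistically indistinguishable", {
  ph <- generate_phantoms(phantom_config(image_size = 48, n_per_class = 60,
                                         effect_size = 0, seed = 13))
  y <- ph$manifest$label
  m0 <- apply(ph$images[y == 0, , ], c(2, 3), mean)
  m1 <- apply(ph$images[y == 1, , ], c(2, 3), mean)
  s0 <- apply(ph$images[y == 0, , ], c(2, 3), stats::sd)
  # pixelwise two-sample t statistics should be null-distributed
  tstat <- (m1 - m0) / (s0 * sqrt(2 / 60))
  pvals <- 2 * stats::pt(-abs(tstat), df = 118)
  expect_gt(stats::median(pvals), 0.2)
})

test_that("full effect size is linearly separable from raw pixels", {
  ph <- generate_phantoms(phantom_config(image_size = 48, n_per_class = 100,
                                         effect_size = 1, seed = 17))
  y <- ph$manifest$label
  X <- matrix(ph$images, nrow = 200)
  tr <- mrisonify:::with_seed(1, sort(sample(200, 140)))
  te <- setdiff(1:200, tr)
  fit <- glmnet::glmnet(X[tr, ], factor(y[tr]), family = "binomial",
                        alpha = 0, lambda = 0.05)
  p <- as.numeric(stats::predict(fit, X[te, ], type = "response"))
  expect_gte(auc_score(y[te], p), 0.95)
})

test_that("sonified-stream difficulty rises with the effect size", {
  # miniature monotonicity check of the generator's separation knob through
  # the sonification path: out-of-fold audio AUC at effect sizes 0, 0.5, 1
  # (80x80 slices, 3-scale bank, 1 s audio keep this affordable)
  scfg <- sonify_config(gabor = mid_bank_config(),
                        timing = sonification_timing(1, 16000, 500))
  bank <- build_gabor_bank(scfg$gabor)
  embedder <- logmel_embedder()
  trainer <- function(data, labels, seed) {
    clf <- fit_audio_classifier(data, labels, forest_config(100, seed))
    function(new) predict(clf, new)
  }
  # one slice per subject: ungrouped folds stay leakage-free, so the delta=0
  # endpoint sits at chance instead of reflecting subject memorization
  aucs <- vapply(c(0, 0.5, 1), function(d) {
    ph <- generate_phantoms(phantom_config(image_size = 80, n_per_class = 30,
                                           effect_size = d, seed = 61,
                                           slices_per_subject = 1))
    emb <- do.call(rbind, lapply(seq_len(60), function(i) {
      embed_audio(sonify(ph$images[i, , ], scfg, bank = bank), embedder)$pooled
    }))
    y <- ph$manifest$label
    plan <- make_fold_plan(y, k = 3, seed = 62)
    oof <- oof_predictions(list(audio = emb), y, plan,
                           list(audio = trainer), seed = 63)
    auc_score(y, oof$p_audio)
  }, numeric(1))
  inversions <- pmax(0, -diff(aucs))
  expect_lte(sum(inversions > 0), 1)        # at most one inversion...
  expect_lte(max(inversions), 0.02)         # ...and a small one
  expect_gt(aucs[3] - aucs[1], 0.3)         # strong overall separation gain
})

test_that("phantoms write valid PNGs and a manifest", {
  dir <- file.path(tempdir(), "phantom_out")
  on.exit(unlink(dir, recursive = TRUE))
  ph <- generate_phantoms(phantom_config(image_size = 32, n_per_class = 3,
                                         seed = 2), dir = dir)
  expect_true(all(file.exists(ph$manifest$path)))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6)
  back <- read_slice_image(ph$manifest$path[1])
  expect_equal(back$H, 32)
  # 8-bit quantization round trip
  expect_lt(max(abs(back$pixels - normalize_slice(ph$images[1, , ])$pixels)),
            2 / 255)
})

test_that("entropy ranking matches a histogram oracle, with stated edge cases", {
  set.seed(41)
  slices <- array(runif(10 * 24 * 24), c(10, 24, 24))
  ranked <- select_slices_by_entropy(slices, mask_threshold = -Inf)
  oracle <- vapply(1:10, function(i) {
    counts <- tabulate(pmin(255, floor(slices[i, , ] * 256)) + 1, nbins = 256)
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }, numeric(1))
  expect_equal(ranked$entropy, sort(oracle, decreasing = TRUE))
  expect_equal(ranked$slice, order(-oracle))

  # constant slice: entropy 0, ranked last
  slices[1, , ] <- 0.5
  ranked <- select_slices_by_entropy(slices, mask_threshold = -Inf)
  expect_equal(ranked$slice[nrow(ranked)], 1L)
  expect_equal(ranked$entropy[nrow(ranked)], 0)
  # a slice hitting all 256 bins equally often scores the maximum 8 bits
  uni <- array((matrix(0:255, 16, 16) + 0.5) / 256, c(1, 16, 16))
  expect_equal(select_slices_by_entropy(uni, mask_threshold = -Inf)$entropy, 8)

  expect_error(select_slices_by_entropy(slices, mask_threshold = 2), "empty")
})
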