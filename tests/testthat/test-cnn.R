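test_that("layer table reproduces the published architecture exactly", {
  cp <- count_parameters(cnn_architecture())
  tab <- cp$per_layer
  get <- function(layer) tab$params[tab$layer == layer]
  expect_equal(get("Sep_Conv2D_B1"), 155L)
  expect_equal(get("Sep_Conv2D_B2"), 2400L)
  expect_equal(get("Sep_Conv2D_B3"), 8896L)
  expect_equal(get("Dense_B1"), 5760032L)
  expect_equal(get("Dense_B2"), 2803744L)
  expect_equal(get("Dense_B3"), 1327136L)
  expect_equal(get("Layer_Normalization_B1"), 64L)
  expect_equal(get("TimeDistributed_Dense_32_ReLU"), 1056L)
  expect_equal(get("TimeDistributed_Dense_1_Linear"), 33L)
  expect_equal(get("Output"), 33L)
  expect_equal(cp$total, 9903677L)

  # shape ladder 150 -> 75 -> 37 -> 18 and the flatten sizes
  shape <- function(layer) tab$output_shape[tab$layer == layer]
  expect_equal(shape("Max_Pooling_B1"), "75x75x32")
  expect_equal(shape("Max_Pooling_B2"), "37x37x64")
  expect_equal(shape("Max_Pooling_B3"), "18x18x128")
  expect_equal(shape("Flatten_B1"), "180,000")
  expect_equal(shape("Flatten_B2"), "87,616")
  expect_equal(shape("Flatten_B3"), "41,472")
})

test_that("built model weights agree with the table, layer by layer and in total", {
  m <- build_image_model(seed = 1)
  w <- m$weights
  expect_equal(length(w$dw1) + length(w$pw1) + length(w$b1), 155L)
  expect_equal(length(w$dw2) + length(w$pw2) + length(w$b2), 2400L)
  expect_equal(length(w$dw3) + length(w$pw3) + length(w$b3), 8896L)
  expect_equal(length(w$Wd1) + length(w$bd1), 5760032L)
  expect_equal(length(w$Wd2) + length(w$bd2), 2803744L)
  expect_equal(length(w$Wd3) + length(w$bd3), 1327136L)
  expect_equal(length(w$g1) + length(w$be1), 64L)
  expect_equal(length(w$Wt1) + length(w$bt1), 1056L)
  expect_equal(length(w$wt2) + length(w$bt2), 33L)
  expect_equal(length(w$wo) + length(w$bo), 33L)
  expect_equal(count_parameters(m)$total, 9903677L)
})

test_that("forward pass emits probabilities strictly inside (0, 1)", {
  m <- build_image_model(seed = 2)
  imgs <- array(0.5, dim = c(2, 150, 150))   # constant input
  p <- predict(m, imgs)
  expect_true(all(p > 0 & p < 1))
})

test_that("analytic gradients match finite differences", {
  m <- build_image_model(cnn_architecture(input_shape = c(32, 32, 3)), seed = 3)
  set.seed(7)
  imgs <- array(runif(6 * 32 * 32), c(6, 32, 32))
  y <- c(0, 1, 1, 0, 1, 0)
  X <- mrisonify:::images_to_matrix(imgs, m$spec)
  lg <- mrisonify:::cnn_loss_grads_cpp(m$weights, X, y, 32, 32)
  set.seed(11)
  h <- 2e-3
  for (nm in c("dw2", "pw1", "Wd1", "g1", "Wt1", "wo", "bd3")) {
    k <- sample(length(m$weights[[nm]]), 1)
    wp <- m$weights; wp[[nm]][k] <- wp[[nm]][k] + h
    wm <- m$weights; wm[[nm]][k] <- wm[[nm]][k] - h
    fd <- (mrisonify:::cnn_loss_grads_cpp(wp, X, y, 32, 32)$loss -
             mrisonify:::cnn_loss_grads_cpp(wm, X, y, 32, 32)$loss) / (2 * h)
    expect_equal(lg$grads[[nm]][k], fd, tolerance = 0.05)
  }
})

test_that("attention fusion is a normalized convex combination", {
  b <- matrix(rnorm(3 * 32), 3, 32)
  eq <- attention_fuse(b, c(1, 1, 1))
  expect_equal(eq$weights, rep(1 / 3, 3))
  expect_equal(eq$fused, colMeans(b))

  sat <- attention_fuse(b, c(50, 0, 0))
  expect_equal(sat$fused, b[1, ], tolerance = 1e-9)

  set.seed(13)
  for (i in 1:25) {
    logits <- rnorm(3, sd = 4)
    f <- attention_fuse(b, logits)
    expect_equal(sum(f$weights), 1, tolerance = 1e-12)
    expect_true(all(f$fused >= apply(b, 2, min) - 1e-12))
    expect_true(all(f$fused <= apply(b, 2, max) + 1e-12))
  }
})

test_that("softmax weights are normalized over many random draws", {
  set.seed(17)
  b <- matrix(rnorm(3 * 32), 3, 32)
  s <- replicate(1000, sum(attention_fuse(b, rnorm(3, sd = 10))$weights))
  expect_true(all(abs(s - 1) < 1e-12))
})

test_that("training learns separable phantoms and is seeded-deterministic", {
  ph <- small_phantoms(n_per_class = 24, delta = 1, seed = 31)
  y <- ph$manifest$label
  cfg <- training_config(epochs = 20, seed = 5)
  fit <- train_image_stream(ph$images, y, cfg)
  expect_gte(fit$history$accuracy[20], 0.95)
  expect_lt(fit$history$loss[20], fit$history$loss[1])

  # prediction invariant to batch composition
  p_all <- predict(fit, ph$images[1:7, , ])
  p_one <- vapply(1:7, function(i) predict(fit, ph$images[i, , , drop = FALSE]),
                  numeric(1))
  expect_equal(p_all, p_one, tolerance = 1e-6)

  fit2 <- train_image_stream(ph$images, y, cfg)
  expect_identical(fit$weights, fit2$weights)

  expect_error(train_image_stream(ph$images[y == 1, , ], y[y == 1], cfg),
               "both classes")
})

test_that("label-permuted training yields chance-level validation AUC", {
  ph <- small_phantoms(n_per_class = 75, delta = 1, seed = 37)
  y <- ph$manifest$label
  perm <- mrisonify:::with_seed(99, sample(y))   # break image-label pairing
  tr <- c(1:25, 76:100); te <- setdiff(seq_along(y), tr)
  fit <- train_image_stream(ph$images[tr, , ], perm[tr],
                            training_config(epochs = 20, seed = 8),
                            val_images = ph$images[te, , ], val_labels = perm[te])
  auc <- auc_score(fit$val_predictions$label, fit$val_predictions$probability)
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})
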