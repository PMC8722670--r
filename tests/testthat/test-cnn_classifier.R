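make_class_images <- function(n_per_class, dims = c(16L, 16L), sep = 0.4) {
  lo <- lapply(seq_len(n_per_class), function(i)
    scanpath_image(matrix(runif(prod(dims), 0, 0.5 - sep / 2), dims[2], dims[1]),
                   list(participant_id = paste0("n", i))))
  hi <- lapply(seq_len(n_per_class), function(i)
    scanpath_image(matrix(runif(prod(dims), 0.5 + sep / 2, 1), dims[2], dims[1]),
                   list(participant_id = paste0("a", i))))
  list(images = c(lo, hi), labels = rep(c(0, 1), each = n_per_class))
}

test_that("model configuration enforces the pooling-divisibility constraint", {
  cfg <- cnn_config()
  expect_equal(length(cfg$filters), 4)        # 4 conv + 4 pool blocks
  expect_equal(cfg$epochs, 3)
  expect_equal(cfg$folds, 3)
  expect_error(cnn_config(input_dims = c(100, 100)), "divisible")
  expect_silent(cnn_config(input_dims = c(64, 64)))
})

test_that("the network has the configured layer structure and seeded init is reproducible", {
  cfg <- cnn_config(input_dims = c(32, 32), filters = c(4, 4, 8, 8), hidden = 16)
  set.seed(123)
  w1 <- scanscreen:::init_weights(cfg)
  set.seed(123)
  w2 <- scanscreen:::init_weights(cfg)
  expect_identical(w1, w2)
  expect_length(w1$conv, 4)                   # 4 convolution layers
  expect_equal(vapply(w1$conv, function(l) nrow(l$W), 0L), c(4L, 4L, 8L, 8L))
  expect_equal(dim(w1$W1), c(16L, (32 / 16)^2 * 8))  # dense over 4x-pooled map
  expect_equal(dim(w1$W2), c(1L, 16L))        # 2 fully connected layers total
})

test_that("training is seed-deterministic and learns a separable problem", {
  set.seed(20)
  d <- make_class_images(8)
  cfg <- cnn_config(input_dims = c(16, 16), filters = c(4, 4), hidden = 8,
                    epochs = 4, batch_size = 4, seed = 99)
  f1 <- scanpath_cnn(d$images, d$labels, cfg)
  f2 <- scanpath_cnn(d$images, d$labels, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$train_loss, f2$train_loss)
  expect_length(f1$train_loss, 4)
  expect_lt(tail(f1$train_loss, 1), f1$train_loss[1] + 0.05)
  expect_gte(evaluate_scores(predict(f1, d$images), d$labels)$auc, 0.9)
  expect_error(scanpath_cnn(d$images, rep(1, 16), cfg), "both classes")
})

test_that("prediction is deterministic, order-preserving and in [0, 1]", {
  set.seed(21)
  d <- make_class_images(4)
  cfg <- cnn_config(input_dims = c(16, 16), filters = c(4, 4), hidden = 8,
                    epochs = 1, batch_size = 4, seed = 7)
  fit <- scanpath_cnn(d$images, d$labels, cfg)
  p <- predict(fit, d$images)
  expect_length(p, 8)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(fit, d$images))
  expect_equal(p[3], predict(fit, d$images[[3]]))
  expect_equal(rev(p), predict(fit, rev(d$images)))
  expect_error(predict(fit, scanpath_image(matrix(0.5, 8, 8))), "expected")
})

test_that("ROC evaluation matches hand-computable cases and the pROC reference", {
  expect_equal(evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(evaluate_scores(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  ev <- evaluate_scores(c(0.9, 0.35, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(ev$auc, 0.75)
  expect_equal(ev$accuracy, 0.75)   # threshold 0.5: one positive missed
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$precision, 1)
  expect_error(evaluate_scores(c(0.5, 0.6), c(1, 1)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    sc <- runif(60)
    lb <- rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(evaluate_scores(sc, lb)$auc, ref, tolerance = 1e-9)
  }
})

test_that("participant folds are disjoint, stratified and keep augmented images with their child", {
  p <- data.frame(participant_id = sprintf("p%02d", 1:59),
                  group = rep(c("ASD", "non-ASD"), c(29, 30)))
  m <- cohort_manifest(p)
  folds <- participant_split(m, k = 3, seed = 17)
  expect_length(folds, 3)
  sizes <- vapply(folds, function(f) length(f$test), 0L)
  expect_true(all(sizes %in% c(19L, 20L)))
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), sort(p$participant_id))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), p$participant_id)
  }
  expect_error(participant_split(cohort_manifest(
    data.frame(participant_id = c("a", "b", "c"),
               group = c("ASD", "ASD", "non-ASD"))), k = 3),
    "at least")
})

test_that("cross-validation records per-fold losses and refuses degenerate folds", {
  set.seed(22)
  p <- data.frame(participant_id = c(paste0("a", 1:4), paste0("n", 1:4)),
                  group = rep(c("ASD", "non-ASD"), each = 4))
  m <- cohort_manifest(p)
  imgs <- c(lapply(1:8, function(i)
              scanpath_image(matrix(runif(256, 0.5, 1), 16, 16),
                             list(participant_id = paste0("a", (i - 1) %% 4 + 1)))),
            lapply(1:8, function(i)
              scanpath_image(matrix(runif(256, 0, 0.5), 16, 16),
                             list(participant_id = paste0("n", (i - 1) %% 4 + 1)))))
  cfg <- cnn_config(input_dims = c(16, 16), filters = c(4, 4), hidden = 8,
                    epochs = 2, folds = 2, batch_size = 4, seed = 5)
  cv <- train_crossval(imgs, m, cfg, split_mode = "participant")
  expect_length(cv$folds, 2)
  folds <- participant_split(m, k = 2, seed = cfg$seed)
  for (i in seq_along(cv$folds)) {
    expect_length(cv$folds[[i]]$model$train_loss, 2)
    expect_true(all(cv$folds[[i]]$test_pid %in% folds[[i]]$test))
  }
  expect_equal(cv$summary$metric, c("auc", "accuracy", "recall", "precision"))
  # precision (and its SD) can be undefined in a fold with no positive call
  ok <- !is.na(cv$summary$mean)
  expect_true(all(cv$summary$mean[ok] >= 0 & cv$summary$mean[ok] <= 1))
  expect_true(all(is.na(cv$summary$sd) | cv$summary$sd >= 0))

  # image-wise mode also runs and uses every image exactly once as test
  cv2 <- train_crossval(imgs, m, cfg, split_mode = "image")
  expect_equal(sum(vapply(cv2$folds, function(f) length(f$scores), 0L)), 16L)

  # images from one class only cannot be cross-validated
  expect_error(train_crossval(imgs[1:8], m, cfg, split_mode = "participant"),
               "single-class")
})
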