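#' Configuration of the scanpath CNN
#'
#' The classifier is a small convolutional network: four 3x3 convolution
#' layers each followed by 2x2 max-pooling (and dropout), then two fully
#' connected layers ending in a single sigmoid unit. Only the layer-type
#' counts are architectural commitments; filter counts, dense width,
#' dropout rates, optimizer and learning rate are tunable here.
#'
#' @param input_dims input raster `c(width, height)`; each dimension must be
#'   divisible by `2^length(filters)` so the pooling chain stays integral.
#' @param filters convolution filter counts per block (length sets the
#'   number of conv/pool blocks; default 4 blocks of 32, 32, 64, 64).
#' @param hidden width of the fully connected hidden layer.
#' @param dropout_conv dropout rate after each pooling layer.
#' @param dropout_fc dropout rate before the output layer.
#' @param epochs training epochs per fold (default 3).
#' @param folds cross-validation folds (default 3).
#' @param validation_fraction fraction of training images held out for loss
#'   monitoring.
#' @param batch_size,learning_rate Adam minibatch size and step size.
#' @param class_weights if TRUE, weight the loss inversely to class
#'   frequency (off by default).
#' @param seed integer seed governing initialisation, shuffling and dropout.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_dims = c(256L, 256L),
                       filters = c(32L, 32L, 64L, 64L),
                       hidden = 512L,
                       dropout_conv = 0.25, dropout_fc = 0.5,
                       epochs = 3L, folds = 3L,
                       validation_fraction = 0.2,
                       batch_size = 16L, learning_rate = 1e-3,
                       class_weights = FALSE, seed = 1L) {
  stopifnot(length(input_dims) == 2L, epochs >= 1L, folds >= 1L,
            validation_fraction >= 0, validation_fraction < 1,
            length(filters) >= 1L, hidden >= 1L)
  div <- 2^length(filters)
  if (any(input_dims %% div != 0))
    stop(sprintf("config error: input dims must be divisible by %d (one halving per pooling layer)", div))
  structure(list(input_dims = as.integer(input_dims),
                 filters = as.integer(filters), hidden = as.integer(hidden),
                 dropout_conv = dropout_conv, dropout_fc = dropout_fc,
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# He-initialised weights; deterministic under set.seed upstream
init_weights <- function(config) {
  f <- config$filters
  chans <- c(1L, f)
  conv <- lapply(seq_along(f), function(l) {
    fan_in <- chans[l] * 9
    list(W = matrix(stats::rnorm(f[l] * fan_in, 0, sqrt(2 / fan_in)),
                    f[l], fan_in),
         b = numeric(f[l]))
  })
  flat <- prod(config$input_dims / 2^length(f)) * f[length(f)]
  list(conv = conv,
       W1 = matrix(stats::rnorm(config$hidden * flat, 0, sqrt(2 / flat)),
                   config$hidden, flat),
       b1 = numeric(config$hidden),
       W2 = matrix(stats::rnorm(config$hidden, 0, sqrt(2 / config$hidden)),
                   1, config$hidden),
       b2 = 0)
}

images_to_cube <- function(images, dims) {
  W <- dims[1]; H <- dims[2]
  arr <- array(0, dim = c(H, W, max(1L, length(images))))
  for (i in seq_along(images)) {
    px <- if (inherits(images[[i]], "scanpath_image")) images[[i]]$pixels
          else images[[i]]
    if (nrow(px) != H || ncol(px) != W)
      stop(sprintf("image %d is %dx%d, expected %dx%d (resize first)",
                   i, ncol(px), nrow(px), W, H))
    arr[, , i] <- px
  }
  arr
}

image_labels <- function(images, manifest) {
  pid <- vapply(images, function(im) im$meta$participant_id, "")
  grp <- manifest$participants$group[match(pid, manifest$participants$participant_id)]
  if (any(is.na(grp))) stop("image participant not found in manifest")
  list(pid = pid, y = as.numeric(grp == "ASD"))
}

#' Fit the scanpath CNN
#'
#' Trains the convolutional classifier on a set of preprocessed scanpath
#' images. An optional validation set is scored for loss monitoring after
#' each epoch. Fully deterministic given `config$seed`.
#'
#' @param images list of `scanpath_image` at the configured input size.
#' @param labels numeric 0/1 vector (1 = ASD).
#' @param config a [cnn_config()].
#' @param val_images,val_labels optional held-out set for loss monitoring.
#' @return An object of class `scanpath_cnn` with elements `weights`,
#'   `config`, `train_loss`, `val_loss` and `n_train`.
#' @export
scanpath_cnn <- function(images, labels, config = cnn_config(),
                         val_images = NULL, val_labels = NULL) {
  stopifnot(length(images) == length(labels), length(images) >= 2L,
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  set.seed(config$seed)
  w0 <- init_weights(config)
  X <- images_to_cube(images, config$input_dims)
  Xv <- if (length(val_images))
    images_to_cube(val_images, config$input_dims)
  else array(0, dim = c(dim(X)[1], dim(X)[2], 0))
  yv <- if (length(val_images)) as.numeric(val_labels) else numeric(0)
  cw <- if (config$class_weights) {
    p1 <- mean(labels)
    c(1 / (2 * (1 - p1)), 1 / (2 * p1))
  } else c(1, 1)
  fit <- .cnn_train_cpp(X, as.numeric(labels), Xv, yv, w0,
                        config$epochs, config$batch_size,
                        config$learning_rate, config$dropout_conv,
                        config$dropout_fc, cw)
  structure(list(weights = fit$weights, config = config,
                 train_loss = unlist(fit$train_loss),
                 val_loss = unlist(fit$val_loss),
                 n_train = length(images)),
            class = "scanpath_cnn")
}

#' @export
print.scanpath_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<scanpath_cnn> %d conv blocks (%s filters) + dense %d + sigmoid\n",
              length(cfg$filters), paste(cfg$filters, collapse = "/"),
              cfg$hidden))
  cat(sprintf("  input %dx%d, trained on %d images for %d epochs; final loss %.4f\n",
              cfg$input_dims[1], cfg$input_dims[2], x$n_train, cfg$epochs,
              utils::tail(x$train_loss, 1)))
  invisible(x)
}

#' @export
summary.scanpath_cnn <- function(object, ...) {
  cat("Training loss by epoch:", sprintf("%.4f", object$train_loss), "\n")
  if (length(object$val_loss))
    cat("Validation loss by epoch:", sprintf("%.4f", object$val_loss), "\n")
  invisible(object)
}

#' Predict ASD probability for scanpath images
#'
#' @param object a fitted [scanpath_cnn()].
#' @param images list of `scanpath_image` (or pixel matrices) at the model's
#'   input size.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0,1]`, one per image, in
#'   input order.
#' @export
predict.scanpath_cnn <- function(object, images, ...) {
  if (inherits(images, "scanpath_image") || is.matrix(images))
    images <- list(images)
  X <- images_to_cube(images, object$config$input_dims)
  as.numeric(.cnn_predict_cpp(X, object$weights))
}

#' Class-stratified participant-wise cross-validation folds
#'
#' Partitions participant IDs (never images) into `k` folds, stratified by
#' group, so that no participant's images — nor any augmented variant of
#' them — can appear on both sides of a split.
#'
#' @param manifest a [cohort_manifest()].
#' @param k number of folds (default 3).
#' @param seed integer RNG seed.
#' @return list of `k` elements, each `list(train = ids, test = ids)`.
#' @export
participant_split <- function(manifest, k = 3L, seed = 1L) {
  stopifnot(inherits(manifest, "cohort_manifest"), k >= 2L)
  p <- manifest$participants
  set.seed(seed)
  assign_folds <- function(ids) {
    if (length(ids) < k)
      stop(sprintf("need at least %d participants per class, got %d",
                   k, length(ids)))
    ids <- sample(ids)
    split(ids, rep_len(seq_len(k), length(ids)))
  }
  folds_by_group <- lapply(split(p$participant_id, p$group), assign_folds)
  lapply(seq_len(k), function(i) {
    test <- unlist(lapply(folds_by_group, `[[`, i), use.names = FALSE)
    list(train = setdiff(p$participant_id, test), test = test)
  })
}

#' ROC analysis of classifier scores
#'
#' Builds the ROC curve by sweeping a threshold over the unique scores,
#' computes AUC by the trapezoidal rule, and reports accuracy, recall
#' (sensitivity) and precision at the 0.5 threshold.
#'
#' @param scores numeric classifier probabilities.
#' @param labels 0/1 truth; both classes must be present.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `accuracy`, `recall`, `precision`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes required for ROC analysis")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1) / npos, 0)
  fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0) / nneg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pred <- as.numeric(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc,
       accuracy = mean(pred == labels),
       recall = tp / npos,
       precision = if (sum(pred == 1) > 0) tp / sum(pred == 1) else NA_real_,
       n_pos = npos, n_neg = nneg)
}

#' Cross-validated training and evaluation of the scanpath CNN
#'
#' Runs k-fold cross-validation in either of two split modes:
#' `"image"` stratifies folds over images (the optimistic protocol, since
#' one participant's images can appear on both sides), while
#' `"participant"` partitions over participant IDs so the model is always
#' tested on unseen children. Augmented images follow their source
#' participant and are used for training only. Within each training fold,
#' `validation_fraction` of the images is held out for loss monitoring.
#'
#' @param images list of preprocessed `scanpath_image`s whose `meta` carries
#'   `participant_id`.
#' @param manifest a [cohort_manifest()] supplying group labels.
#' @param config a [cnn_config()].
#' @param split_mode `"participant"` or `"image"`.
#' @param augmented optional list of augmented variants (metadata must carry
#'   `participant_id`); training-side only.
#' @return An object of class `cnn_cv`: per-fold models and evaluations plus
#'   a `summary` data.frame of mean and SD for AUC, accuracy, recall and
#'   precision.
#' @export
train_crossval <- function(images, manifest, config = cnn_config(),
                           split_mode = c("participant", "image"),
                           augmented = list()) {
  split_mode <- match.arg(split_mode)
  stopifnot(length(images) >= config$folds)
  lab <- image_labels(images, manifest)
  alab <- if (length(augmented)) image_labels(augmented, manifest)
  set.seed(config$seed)
  if (split_mode == "participant") {
    folds <- participant_split(manifest, config$folds, seed = config$seed)
    fold_sets <- lapply(folds, function(f) {
      list(train = which(lab$pid %in% f$train),
           test = which(lab$pid %in% f$test),
           train_aug = if (length(augmented)) which(alab$pid %in% f$train)
                       else integer(0))
    })
  } else {
    # stratified over images
    fold_id <- integer(length(images))
    for (cls in unique(lab$y)) {
      idx <- sample(which(lab$y == cls))
      fold_id[idx] <- rep_len(seq_len(config$folds), length(idx))
    }
    fold_sets <- lapply(seq_len(config$folds), function(i) {
      tr <- which(fold_id != i)
      list(train = tr, test = which(fold_id == i),
           train_aug = if (length(augmented))
             which(alab$pid %in% lab$pid[tr]) else integer(0))
    })
  }
  fold_results <- lapply(seq_along(fold_sets), function(i) {
    fs <- fold_sets[[i]]
    tr_imgs <- c(images[fs$train], augmented[fs$train_aug])
    tr_y <- c(lab$y[fs$train], if (length(fs$train_aug)) alab$y[fs$train_aug])
    if (length(unique(tr_y)) < 2L) stop("single-class training fold")
    if (length(unique(lab$y[fs$test])) < 2L)
      stop("single-class test fold; too few participants")
    set.seed(config$seed + i)
    n_val <- floor(config$validation_fraction * length(tr_imgs))
    vi <- if (n_val >= 1L) sample(seq_along(tr_imgs), n_val) else integer(0)
    ti <- setdiff(seq_along(tr_imgs), vi)
    if (length(unique(tr_y[ti])) < 2L) { ti <- seq_along(tr_imgs); vi <- integer(0) }
    cfg <- config; cfg$seed <- config$seed + i
    model <- scanpath_cnn(tr_imgs[ti], tr_y[ti], cfg,
                          val_images = tr_imgs[vi], val_labels = tr_y[vi])
    scores <- predict(model, images[fs$test])
    ev <- evaluate_scores(scores, lab$y[fs$test])
    list(model = model, evaluation = ev, scores = scores,
         test_labels = lab$y[fs$test], test_pid = lab$pid[fs$test])
  })
  metrics <- c("auc", "accuracy", "recall", "precision")
  tab <- sapply(metrics, function(m)
    vapply(fold_results, function(f) f$evaluation[[m]], 0))
  # precision is NA in a fold with no positive prediction; aggregate over
  # the folds that define it
  structure(list(folds = fold_results, split_mode = split_mode,
                 config = config,
                 summary = data.frame(metric = metrics,
                                      mean = colMeans(tab, na.rm = TRUE),
                                      sd = apply(tab, 2, stats::sd,
                                                 na.rm = TRUE))),
            class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  cat(sprintf("<cnn_cv> %d-fold %s-wise cross-validation (%d epochs/fold)\n",
              length(x$folds), x$split_mode, x$config$epochs))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.3f (SD %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' @export
plot.cnn_cv <- function(x, ...) {
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "False-positive rate",
                 ylab = "True-positive rate",
                 main = sprintf("ROC, %s-wise %d-fold CV", x$split_mode,
                                length(x$folds)), ...)
  graphics::abline(0, 1, lty = 3, col = "gray")
  for (i in seq_along(x$folds)) {
    r <- x$folds[[i]]$evaluation$roc
    graphics::lines(r$fpr, r$tpr, col = i)
  }
  auc <- x$summary$mean[x$summary$metric == "auc"]
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("mean AUC = %.2f", auc))
  invisible(x)
}
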