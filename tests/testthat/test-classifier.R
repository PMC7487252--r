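toy_spec <- function() {
  architecture_spec("custom", input_shape = c(8L, 8L, 3L),
                    layers = list(layer_conv(2), layer_maxpool(),
                                  layer_flatten(), layer_dense(8),
                                  layer_dropout(), layer_output(2)))
}

toy_dataset <- function(n_per_class = 20L, seed = 1L) {
  # separable by intensity: dark vs bright 8x8 patches
  with_seed_local <- stomatadetect:::with_fixed_seed
  with_seed_local(seed, {
    X <- cbind(matrix(runif(64 * n_per_class, 0, 0.4), 64),
               matrix(runif(64 * n_per_class, 0.6, 1), 64))
    label <- factor(rep(c("negative", "positive"), each = n_per_class),
                    levels = c("negative", "positive"))
    structure(list(X = X, label = label,
                   meta = data.frame(image_id = "toy",
                                     x0 = 0L, y0 = 0L)[rep(1, 2 * n_per_class), ],
                   class_counts = table(label),
                   provenance = list()),
              class = "patch_dataset")
  })
}

test_that("backpropagation gradients match finite differences", {
  spec <- toy_spec()
  defs <- stomatadetect:::layer_def_matrix(spec)
  w <- stomatadetect:::cnn_init_cpp(defs, 42L)
  set.seed(1)
  X <- matrix(runif(64 * 6), 64, 6)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  g <- stomatadetect:::cnn_gradients_cpp(w, defs, X, y)
  loss_at <- function(w) stomatadetect:::cnn_gradients_cpp(w, defs, X, y)$loss
  eps <- 1e-3
  for (li in seq_along(w)) {
    if (is.null(w[[li]])) next
    for (k in c(1L, length(w[[li]]$W))) {
      wp <- w; wp[[li]]$W[k] <- wp[[li]]$W[k] + eps
      wm <- w; wm[[li]]$W[k] <- wm[[li]]$W[k] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      ana <- g$grads[[li]]$W[k]
      expect_equal(ana, num, tolerance = 0.02)
    }
  }
})

test_that("untrained classifiers honor the softmax scoring contract", {
  spec <- toy_spec()
  clf <- build_classifier(spec, training_hyperparams("custom", seed = 3L))
  expect_false(clf$trained)
  expect_identical(clf$num_params$total, count_parameters(spec)$total)
  probs <- stomatadetect:::cnn_predict_cpp(
    clf$weights, stomatadetect:::layer_def_matrix(spec),
    matrix(runif(64 * 5), 64, 5), 8L)
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-5)
  expect_true(all(probs >= 0 & probs <= 1))
  # blank patch scores a finite confidence, complement of the absence score
  blank <- stomatadetect:::new_patch("z", 0L, 0L, 8L, matrix(0, 8, 8))
  s <- score_patch(clf, blank)
  expect_true(is.finite(s) && s >= 0 && s <= 1)
})

test_that("patch size is enforced at scoring time", {
  clf <- build_classifier(toy_spec(), training_hyperparams("custom"))
  wrong <- stomatadetect:::new_patch("z", 0L, 0L, 6L, matrix(0, 6, 6))
  expect_error(score_patch(clf, wrong), "expects 8 x 8")
})

test_that("training is deterministic and better than chance on easy data", {
  ds <- toy_dataset()
  clf0 <- build_classifier(toy_spec(),
                           training_hyperparams("custom", learning_rate = 1e-3,
                                                batch_size = 8L,
                                                dropout_rate = 0.1,
                                                seed = 11L))
  a <- train_classifier(clf0, ds, epochs = 2L)
  b <- train_classifier(clf0, ds, epochs = 2L)
  expect_identical(a$history, b$history)
  expect_true(a$trained)
  longer <- train_classifier(clf0, ds, epochs = 30L)
  expect_gt(tail(longer$history$accuracy, 1), 0.5)
})

test_that("single-class datasets are rejected", {
  ds <- toy_dataset()
  keep <- ds$label == "negative"
  ds$X <- ds$X[, keep]
  ds$label <- ds$label[keep]
  clf <- build_classifier(toy_spec(), training_hyperparams("custom"))
  expect_error(train_classifier(clf, ds), "both positive and negative")
})

test_that("vgg19 builds with a frozen conv base and warns about weights", {
  expect_warning(clf <- build_classifier(architecture_spec("vgg19")),
                 "randomly initialized")
  expect_identical(clf$num_params$frozen, 20024384)
  expect_identical(clf$num_params$trainable, 27273218)
})

test_that("a briefly trained classifier separates stomata from background", {
  fx <- fixture_classifier()
  clf <- fx$clf
  expect_gt(tail(clf$history$accuracy, 1), 0.9)
  # held-out patch accuracy on fresh scenes
  ds_out <- build_training_set(fx$heldout, patch_config(120L, 30L),
                               neg_pos_ratio = 6, seed = 2L)
  conf <- stomatadetect:::score_patch_matrix(clf, ds_out$X)
  pred <- ifelse(conf >= 0.5, "positive", "negative")
  acc <- mean(pred == as.character(ds_out$label))
  expect_gt(acc, 0.9)
  # canonical stoma patch outscores pure background
  pos_idx <- which(ds_out$label == "positive")[1]
  neg_idx <- which(ds_out$label == "negative")[1]
  expect_gt(conf[pos_idx], conf[neg_idx])
  # scoring is pure: identical call, identical confidence (bit for bit);
  # batch composition may shift single-precision sums at the 1e-7 level
  once <- stomatadetect:::score_patch_matrix(clf, ds_out$X[, 1, drop = FALSE])
  again <- stomatadetect:::score_patch_matrix(clf, ds_out$X[, 1, drop = FALSE])
  expect_identical(once, again)
  expect_equal(once, conf[1], tolerance = 1e-5)
})
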