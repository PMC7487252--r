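## Patch classifiers: the bridge between architecture specs and the
## package's numerical backend (src/cnn.cpp). Pixels reach the network as
## [0, 1] grayscale replicated to three channels.

layer_type_code <- c(conv3x3_valid = 0L, conv3x3_same = 1L, maxpool2x2 = 2L,
                     flatten = 3L, dense = 4L, softmax_output = 5L,
                     dropout = 6L)

## Integer layer-definition matrix consumed by the C++ backend.
layer_def_matrix <- function(spec) {
  shp <- spec$input_shape
  n <- length(spec$layers)
  M <- matrix(0L, n, 9L)
  colnames(M) <- c("type", "in_h", "in_w", "in_c", "out_h", "out_w", "out_c",
                   "units", "trainable")
  for (i in seq_len(n)) {
    l <- spec$layers[[i]]
    out <- spec$shapes[[i]]
    M[i, ] <- c(layer_type_code[[l$kind]], shp, out, l$units,
                as.integer(i > spec$frozen_prefix))
    shp <- out
  }
  M
}

#' Build a patch classifier
#'
#' Instantiates an [architecture_spec()] as a scorable classifier with
#' seeded He-initialized weights. For `vgg19` no pretrained convolutional
#' weights ship with the package, so the (frozen) convolutional base is
#' randomly initialized and a warning is emitted; the dense head is
#' trainable either way.
#'
#' @param spec An [architecture_spec()].
#' @param hyper A [training_hyperparams()]; its seed drives initialization.
#' @return An object of class `"stoma_classifier"` with elements `spec`,
#'   `hyper`, `weights`, `trained`, `history` and `num_params`.
#' @export
build_classifier <- function(spec, hyper = training_hyperparams(spec$name)) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(hyper, "training_hyperparams"))
  if (spec$name == "vgg19") {
    warning(paste("no pretrained convolutional weights available;",
                  "the frozen vgg19 base is randomly initialized"),
            call. = FALSE)
  }
  defs <- layer_def_matrix(spec)
  weights <- cnn_init_cpp(defs, hyper$seed)
  structure(list(spec = spec, hyper = hyper, weights = weights,
                 trained = FALSE, history = NULL,
                 num_params = count_parameters(spec)),
            class = "stoma_classifier")
}

#' @export
print.stoma_classifier <- function(x, ...) {
  cat(sprintf("stoma_classifier '%s' (%s; %s parameters, %s trainable)\n",
              x$spec$name, if (x$trained) "trained" else "untrained",
              format(x$num_params$total, big.mark = ","),
              format(x$num_params$trainable, big.mark = ",")))
  invisible(x)
}

#' Train a patch classifier
#'
#' Seeded mini-batch training with Adam, dropout on the dense layers and
#' on-the-fly dihedral augmentation. Epochs and batch size default to the
#' classifier's hyperparameters but can be overridden for reduced-scale
#' runs. Returns the classifier with updated weights and a per-epoch
#' loss/accuracy history; a fixed seed reproduces the history exactly.
#'
#' @param clf A [build_classifier()] result.
#' @param ds A [build_training_set()] patch dataset with both classes.
#' @param epochs,batch_size,learning_rate,seed Optional overrides.
#' @return The trained `"stoma_classifier"` (with `history` data.frame).
#' @export
train_classifier <- function(clf, ds, epochs = NULL, batch_size = NULL,
                             learning_rate = NULL, seed = NULL) {
  stopifnot(inherits(clf, "stoma_classifier"), inherits(ds, "patch_dataset"))
  if (nlevels(droplevels(ds$label)) < 2L) {
    stop("training requires both positive and negative patches", call. = FALSE)
  }
  hyper <- clf$hyper
  if (!is.null(epochs)) hyper$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) hyper$batch_size <- as.integer(batch_size)
  if (!is.null(learning_rate)) hyper$learning_rate <- learning_rate
  if (!is.null(seed)) hyper$seed <- as.integer(seed)
  P <- clf$spec$input_shape[1L]
  if (nrow(ds$X) != P * P) {
    stop(sprintf("dataset patches have %d pixels but the network expects %d x %d",
                 nrow(ds$X), P, P), call. = FALSE)
  }
  y <- as.integer(ds$label == "positive")
  fit <- cnn_train_cpp(clf$weights, layer_def_matrix(clf$spec), ds$X, y,
                       list(learning_rate = hyper$learning_rate,
                            beta1 = hyper$beta1, beta2 = hyper$beta2,
                            batch_size = hyper$batch_size,
                            epochs = hyper$epochs,
                            dropout_rate = hyper$dropout_rate,
                            augment = hyper$augment, seed = hyper$seed))
  clf$weights <- fit$weights
  clf$trained <- TRUE
  clf$hyper <- hyper
  clf$history <- data.frame(epoch = seq_along(fit$loss), loss = fit$loss,
                            accuracy = fit$accuracy)
  clf
}

## Scores a matrix of flattened patches (P*P x n, column-major pixels);
## returns the presence-class probability per patch.
score_patch_matrix <- function(clf, X) {
  P <- clf$spec$input_shape[1L]
  if (nrow(X) != P * P) {
    stop(sprintf("patch has %d pixels; the classifier expects %d x %d input",
                 nrow(X), P, P), call. = FALSE)
  }
  probs <- cnn_predict_cpp(clf$weights, layer_def_matrix(clf$spec), X)
  probs[, 2L]
}

#' Score a single patch
#'
#' Returns the presence-class probability in `[0, 1]`; the two softmax
#' outputs sum to one, so the absence score is its complement. Patches must
#' match the network's input size exactly.
#'
#' @param clf A `"stoma_classifier"` or [oracle_classifier()].
#' @param p A `"patch"` with pixels (for the oracle, pixel-free patches
#'   with coordinates suffice).
#' @return Confidence in `[0, 1]` that the patch fully contains a stoma.
#' @export
score_patch <- function(clf, p) UseMethod("score_patch")

#' @export
score_patch.stoma_classifier <- function(clf, p) {
  stopifnot(inherits(p, "patch"))
  if (is.null(p$pixels)) stop("patch has no pixels to score", call. = FALSE)
  score_patch_matrix(clf, matrix(as.vector(p$pixels), ncol = 1L))
}

#' Geometric oracle classifier
#'
#' A reference classifier that scores a window 1.0 exactly when it fully
#' contains an annotated stoma (the same containment rule as
#' [label_patch()]) and 0.0 otherwise. It looks at coordinates, not pixels,
#' and is used to validate the detection geometry independently of any
#' trained network.
#'
#' @param anns [stoma_annotations()] ground truth.
#' @return An object of class `"oracle_classifier"`.
#' @export
oracle_classifier <- function(anns) {
  structure(list(anns = anns), class = "oracle_classifier")
}

#' @export
score_patch.oracle_classifier <- function(clf, p) {
  stopifnot(inherits(p, "patch"))
  anns <- clf$anns[clf$anns$image_id == p$image_id, , drop = FALSE]
  if (label_window_grid(data.frame(x0 = p$x0, y0 = p$y0), anns, p$size)) 1 else 0
}
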