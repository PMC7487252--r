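## Declarative CNN architecture specs and an exact, framework-free
## parameter counter. Shapes chain from the 120 x 120 x 3 patch input:
## 3x3 valid convolutions shrink (h, w) by 2, 'same' convolutions keep
## them, and 2x2 max pools floor-halve them. Parameter arithmetic is
## integer-exact: conv = 3*3*c_in*c_out + c_out, dense = (n_in + 1)*n_out.

#' Layer constructors for architecture specs
#'
#' Small helpers building the layer list of an [architecture_spec()].
#' `layer_conv()` is a 3x3 convolution (ReLU) with `"valid"` or `"same"`
#' padding; `layer_maxpool()` a 2x2/stride-2 max pool; `layer_dense()` a
#' fully connected ReLU layer; `layer_output()` a fully connected softmax
#' layer; `layer_dropout()` an (inference-transparent) dropout layer whose
#' rate comes from the training hyperparameters.
#'
#' @param filters,units Output channels / neurons.
#' @param padding `"valid"` or `"same"`.
#' @return A layer description (named list).
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv <- function(filters, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  list(kind = if (padding == "valid") "conv3x3_valid" else "conv3x3_same",
       units = as.integer(filters))
}
#' @rdname layers
#' @export
layer_maxpool <- function() list(kind = "maxpool2x2", units = 0L)
#' @rdname layers
#' @export
layer_flatten <- function() list(kind = "flatten", units = 0L)
#' @rdname layers
#' @export
layer_dense <- function(units) list(kind = "dense", units = as.integer(units))
#' @rdname layers
#' @export
layer_dropout <- function() list(kind = "dropout", units = 0L)
#' @rdname layers
#' @export
layer_output <- function(units = 2L) {
  list(kind = "softmax_output", units = as.integer(units))
}

vgg19_conv_base <- function() {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  layers <- list()
  for (blk in widths) {
    for (k in blk) layers[[length(layers) + 1L]] <- layer_conv(k, "same")
    layers[[length(layers) + 1L]] <- layer_maxpool()
  }
  layers
}

#' Patch-classifier architecture specifications
#'
#' Three reference architectures for the 120 x 120 x 3 patch input:
#'
#' * `basic_shallow` — three 3x3 valid convolutions (8, 16, 32 filters),
#'   each followed by a 2x2 max pool, then two dense layers of 32 neurons
#'   and a 2-way softmax; 180,242 parameters, all trainable.
#' * `basic_deep` — same topology with 32-64-128 filters and two dense
#'   layers of 1,024 neurons; 23,297,090 parameters.
#' * `vgg19` — the standard VGG19 convolutional base (16 3x3 'same'
#'   convolutions in 5 pooled blocks; 20,024,384 parameters, frozen) with a
#'   4096-2048-2 dense head (27,273,218 trainable); 47,297,602 in total.
#'
#' @param name One of `"basic_shallow"`, `"basic_deep"`, `"vgg19"`, or
#'   `"custom"` (then `layers` must be given).
#' @param input_shape Integer `(height, width, channels)`; default
#'   `c(120, 120, 3)`.
#' @param layers For `name = "custom"`, a list built from the
#'   [layer constructors][layers].
#' @param frozen_prefix Number of leading layers whose parameters are not
#'   trained (defaults: 0, except the 21-layer conv base of `vgg19`).
#' @return An object of class `"architecture_spec"` with the resolved
#'   per-layer shape chain.
#' @examples
#' count_parameters(architecture_spec("basic_shallow"))$total
#' @export
architecture_spec <- function(name = c("basic_shallow", "basic_deep", "vgg19",
                                       "custom"),
                              input_shape = c(120L, 120L, 3L),
                              layers = NULL, frozen_prefix = NULL) {
  name <- match.arg(name)
  if (name == "basic_shallow") {
    layers <- list(layer_conv(8), layer_maxpool(), layer_conv(16),
                   layer_maxpool(), layer_conv(32), layer_maxpool(),
                   layer_flatten(), layer_dense(32), layer_dropout(),
                   layer_dense(32), layer_dropout(), layer_output(2))
    if (is.null(frozen_prefix)) frozen_prefix <- 0L
  } else if (name == "basic_deep") {
    layers <- list(layer_conv(32), layer_maxpool(), layer_conv(64),
                   layer_maxpool(), layer_conv(128), layer_maxpool(),
                   layer_flatten(), layer_dense(1024), layer_dropout(),
                   layer_dense(1024), layer_dropout(), layer_output(2))
    if (is.null(frozen_prefix)) frozen_prefix <- 0L
  } else if (name == "vgg19") {
    base <- vgg19_conv_base()
    layers <- c(base, list(layer_flatten(), layer_dense(4096), layer_dropout(),
                           layer_dense(2048), layer_dropout(), layer_output(2)))
    if (is.null(frozen_prefix)) frozen_prefix <- length(base)
  } else {
    if (is.null(layers)) stop("custom architecture requires 'layers'", call. = FALSE)
    if (is.null(frozen_prefix)) frozen_prefix <- 0L
  }
  spec <- structure(list(name = name, layers = layers,
                         input_shape = as.integer(input_shape),
                         frozen_prefix = as.integer(frozen_prefix)),
                    class = "architecture_spec")
  spec$shapes <- resolve_shapes(spec)  # validates the chain
  spec
}

## Walks the shape chain, erroring with the offending layer's index/kind.
resolve_shapes <- function(spec) {
  shp <- spec$input_shape  # (h, w, c); flat layers use c(1, 1, n)
  flat <- FALSE
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    bad <- function(msg) stop(sprintf("layer %d (%s): %s", i, l$kind, msg),
                              call. = FALSE)
    if (l$kind %in% c("conv3x3_valid", "conv3x3_same")) {
      if (flat) bad("convolution after flatten")
      if (l$kind == "conv3x3_valid") {
        if (shp[1] < 3 || shp[2] < 3) bad(sprintf(
          "input %d x %d too small for a 3x3 valid convolution", shp[1], shp[2]))
        shp <- c(shp[1] - 2L, shp[2] - 2L, l$units)
      } else {
        shp <- c(shp[1], shp[2], l$units)
      }
    } else if (l$kind == "maxpool2x2") {
      if (flat) bad("pooling after flatten")
      if (shp[1] < 2 || shp[2] < 2) bad("input too small for a 2x2 pool")
      shp <- c(shp[1] %/% 2L, shp[2] %/% 2L, shp[3])
    } else if (l$kind == "flatten") {
      if (flat) bad("repeated flatten")
      shp <- c(1L, 1L, shp[1] * shp[2] * shp[3])
      flat <- TRUE
    } else if (l$kind %in% c("dense", "softmax_output")) {
      if (!flat) bad("dense layer requires a preceding flatten")
      shp <- c(1L, 1L, l$units)
    } else if (l$kind == "dropout") {
      if (!flat) bad("dropout is only placed after dense layers here")
    } else bad("unknown layer kind")
    out[[i]] <- shp
  }
  out
}

#' @export
print.architecture_spec <- function(x, ...) {
  p <- count_parameters(x)
  cat(sprintf("architecture '%s': %d layers, input %s; %s parameters (%s trainable)\n",
              x$name, length(x$layers),
              paste(x$input_shape, collapse = "x"),
              format(p$total, big.mark = ","),
              format(p$trainable, big.mark = ",")))
  invisible(x)
}

#' Exact parameter count of an architecture
#'
#' Counts weights and biases per layer by pure integer arithmetic
#' (convolution: `3*3*c_in*c_out + c_out`; dense/softmax:
#' `(n_in + 1)*n_out`), resolving shapes from the input. Trainable excludes
#' the frozen prefix. No numerical backend is involved.
#'
#' @param spec An [architecture_spec()].
#' @return List with `total`, `trainable`, `frozen` and a `per_layer`
#'   data.frame (`layer`, `kind`, `out_shape`, `params`, `trainable`).
#' @examples
#' count_parameters(architecture_spec("vgg19"))
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  shp <- spec$input_shape
  flat_in <- NULL
  rows <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    out <- spec$shapes[[i]]
    params <- 0
    if (l$kind %in% c("conv3x3_valid", "conv3x3_same")) {
      params <- 3 * 3 * shp[3] * l$units + l$units
    } else if (l$kind %in% c("dense", "softmax_output")) {
      params <- (shp[3] + 1) * l$units
    }
    rows[[i]] <- data.frame(
      layer = i, kind = l$kind,
      out_shape = paste(out, collapse = "x"), params = params,
      trainable = i > spec$frozen_prefix & params > 0,
      stringsAsFactors = FALSE)
    shp <- out
  }
  per_layer <- do.call(rbind, rows)
  total <- sum(per_layer$params)
  trainable <- sum(per_layer$params[per_layer$trainable])
  list(total = total, trainable = trainable, frozen = total - trainable,
       per_layer = per_layer)
}

#' Training hyperparameters
#'
#' Per-architecture defaults: Adam with learning rate 5e-4 / 5e-5 / 5e-6,
#' batch size 32 / 64 / 128 and 200 / 200 / 50 epochs for
#' `basic_shallow` / `basic_deep` / `vgg19`; `beta1 = 0.9`,
#' `beta2 = 0.999`, dropout 0.5 on the dense layers, dihedral augmentation
#' on. Any field can be overridden for desk-scale runs.
#'
#' @param arch Architecture name the defaults are keyed on.
#' @param learning_rate,batch_size,epochs,dropout_rate,augment,seed
#'   Overrides of the per-architecture defaults.
#' @param beta1,beta2 Adam moment decay rates.
#' @return An object of class `"training_hyperparams"`.
#' @export
training_hyperparams <- function(arch = c("basic_shallow", "basic_deep",
                                          "vgg19", "custom"),
                                 learning_rate = NULL, batch_size = NULL,
                                 epochs = NULL, beta1 = 0.9, beta2 = 0.999,
                                 dropout_rate = 0.5, augment = TRUE,
                                 seed = 1L) {
  arch <- match.arg(arch)
  defaults <- list(
    basic_shallow = list(lr = 5e-4, batch = 32L, epochs = 200L),
    basic_deep    = list(lr = 5e-5, batch = 64L, epochs = 200L),
    vgg19         = list(lr = 5e-6, batch = 128L, epochs = 50L),
    custom        = list(lr = 5e-4, batch = 32L, epochs = 200L))[[arch]]
  structure(list(
    arch = arch,
    learning_rate = if (is.null(learning_rate)) defaults$lr else learning_rate,
    batch_size = as.integer(if (is.null(batch_size)) defaults$batch else batch_size),
    epochs = as.integer(if (is.null(epochs)) defaults$epochs else epochs),
    beta1 = beta1, beta2 = beta2, dropout_rate = dropout_rate,
    augment = isTRUE(augment), seed = as.integer(seed)),
    class = "training_hyperparams")
}
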