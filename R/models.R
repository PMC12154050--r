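# The two classifier architectures. The compact 2-D CNN uses unpadded
# 3x3 convolutions and 2x2 max pools (so a 171x149 input proceeds
# 169x147 -> 84x73 -> 82x71 -> 41x35 -> 39x33 -> 19x16, flattening to
# 38912 features). The shallow 1-D ResNet reads the image with the pair
# axis as the sequence and the window axis as input features: a strided
# "same" conv halves 171 to 86, then three basic residual blocks at
# 64/128/256 filters with strided downsampling and projection shortcuts,
# global average pooling and a softmax head.

#' Classifier specification
#'
#' @param architecture `"custom_cnn"` (2-D convolutional stack) or
#'   `"shallow_resnet"` (1-D residual network over the pair axis).
#' @param input_shape Image shape: `(height, width)` or `(height, width, 1)`
#'   for the CNN; `(length, channels)` for the ResNet. For connectogram
#'   images height/length is the pair count and width/channels the window
#'   count.
#' @param n_classes Number of classes (>= 2).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("custom_cnn", "shallow_resnet"),
                       input_shape, n_classes) {
  architecture <- match.arg(architecture)
  if (!is_count(n_classes) || n_classes < 2)
    cc_config_error("`n_classes` must be an integer >= 2")
  input_shape <- as.integer(input_shape)
  if (architecture == "custom_cnn") {
    if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
    if (length(input_shape) != 3L || input_shape[3] != 1L)
      cc_config_error("custom_cnn input_shape must be (height, width) or (height, width, 1)")
  } else {
    if (length(input_shape) != 2L)
      cc_config_error("shallow_resnet input_shape must be (length, channels)")
  }
  if (any(input_shape < 1L))
    cc_config_error("input_shape dimensions must be positive")
  structure(list(architecture = architecture, input_shape = input_shape,
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

shape_str <- function(s) paste0("(", paste(s, collapse = ", "), ")")

#' Layer-by-layer output shapes of an architecture
#'
#' Pure shape arithmetic (no weights): used both to size the dense layers at
#' build time and to audit the architecture against its reference layer
#' listing. Raises a configuration error naming the first layer whose output
#' would collapse below one element.
#'
#' @param spec A [model_spec()].
#' @return `data.frame` with columns `layer`, `output` (shape string,
#'   batch dimension omitted).
#' @export
model_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  rows <- list()
  add <- function(name, shape) rows[[length(rows) + 1L]] <<- list(
    layer = name, output = shape_str(shape), shape = list(shape))
  chk <- function(name, shape) {
    if (any(shape < 1))
      cc_config_error(sprintf(
        "input too small for the layer chain: layer '%s' would output %s",
        name, shape_str(shape)))
    shape
  }
  if (spec$architecture == "custom_cnn") {
    h <- spec$input_shape[1]; w <- spec$input_shape[2]
    add("input", c(h, w, 1L))
    filt <- c(32L, 64L, 128L)
    for (b in 1:3) {
      h <- h - 2L; w <- w - 2L
      add(sprintf("conv2d_%d", b), chk(sprintf("conv2d_%d", b), c(h, w, filt[b])))
      h <- h %/% 2L; w <- w %/% 2L
      add(sprintf("maxpool2d_%d", b), chk(sprintf("maxpool2d_%d", b), c(h, w, filt[b])))
    }
    add("flatten", c(h * w * 128L))
    add("dense_1", 128L)
    add("dense_out", spec$n_classes)
  } else {
    L <- spec$input_shape[1]; C <- spec$input_shape[2]
    add("input", c(L, C))
    L <- as.integer(ceiling(L / 2))
    add("conv1d", chk("conv1d", c(L, 64L)))
    add("batchnorm", c(L, 64L))
    add("relu", c(L, 64L))
    L <- L %/% 2L
    add("maxpool1d", chk("maxpool1d", c(L, 64L)))
    add("resblock_1", chk("resblock_1", c(L, 64L)))
    L <- as.integer(ceiling(L / 2))
    add("resblock_2", chk("resblock_2", c(L, 128L)))
    L <- as.integer(ceiling(L / 2))
    add("resblock_3", chk("resblock_3", c(L, 256L)))
    add("global_avg_pool", 256L)
    add("dense_out", spec$n_classes)
  }
  data.frame(layer = vapply(rows, `[[`, "", "layer"),
             output = vapply(rows, `[[`, "", "output"),
             stringsAsFactors = FALSE)
}

#' Build a trainable classifier
#'
#' Instantiates the layer stack of a [model_spec()] with seeded random
#' initialization (He for ReLU convolutions, Glorot for the output layer).
#' The output layer is linear; softmax is applied by the cross-entropy loss
#' and by [nn_predict()].
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `nn_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  model_shapes(spec)   # validates the chain, errors name the failing layer
  layers <- with_seed(seed, {
    if (spec$architecture == "custom_cnn") {
      h <- spec$input_shape[1]; w <- spec$input_shape[2]
      for (i in 1:3) { h <- (h - 2L) %/% 2L; w <- (w - 2L) %/% 2L }
      list(layer_conv2d(1L, 32L), layer_relu(), layer_maxpool2d(2L),
           layer_conv2d(32L, 64L), layer_relu(), layer_maxpool2d(2L),
           layer_conv2d(64L, 128L), layer_relu(), layer_maxpool2d(2L),
           layer_flatten(),
           layer_dense(h * w * 128L, 128L, "he"), layer_relu(),
           layer_dense(128L, spec$n_classes, "glorot"))
    } else {
      C <- spec$input_shape[2]
      list(layer_conv1d(C, 64L, 3L, 2L, "same"),
           layer_bn1d(64L), layer_relu(), layer_maxpool1d(2L),
           layer_resblock1d(64L, 64L, 1L),
           layer_resblock1d(64L, 128L, 2L),
           layer_resblock1d(128L, 256L, 2L),
           layer_gap1d(),
           layer_dense(256L, spec$n_classes, "glorot"))
    }
  })
  structure(list(spec = spec, layers = layers, classes = NULL,
                 history = NULL, init_seed = as.integer(seed)),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s  input %s  %d classes%s\n",
              x$spec$architecture, shape_str(x$spec$input_shape),
              x$spec$n_classes,
              if (is.null(x$classes)) " (untrained)" else " (trained)"))
  print(model_shapes(x$spec))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model An `nn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  count <- function(layers) {
    s <- 0
    for (l in layers) {
      if (l$type == "resblock1d") {
        s <- s + count(l$main)
        if (!is.null(l$short)) s <- s + count(l$short)
      } else s <- s + sum(vapply(l$params, length, 0L))
    }
    s
  }
  count(model$layers)
}
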