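# Training: mini-batch Adam on softmax cross-entropy, with per-epoch
# train/validation history. Everything is seeded; on a single-threaded BLAS
# the run is bit-reproducible.

#' Training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 8; small-to-moderate batches
#'   work best for connectogram images).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed controlling shuffling (and, through
#'   [subject_wise_cv()], weight initialization and validation holdout).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, learning_rate = 1e-3,
                         seed = 1L, optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  if (!is_count(epochs) || epochs < 1) cc_config_error("`epochs` must be >= 1")
  if (!is_count(batch_size) || batch_size < 1)
    cc_config_error("`batch_size` must be >= 1")
  if (!is_scalar_num(learning_rate) || learning_rate <= 0)
    cc_config_error("`learning_rate` must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 optimizer = optimizer),
            class = "train_config")
}

# subset the leading (batch) dimension of a 2-/3-/4-D array
x_rows <- function(x, idx) {
  d <- dim(x)
  switch(as.character(length(d)),
         "2" = x[idx, , drop = FALSE],
         "3" = x[idx, , , drop = FALSE],
         "4" = x[idx, , , , drop = FALSE],
         cc_input_error("unsupported input array rank"))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Stack connectogram images into a model input tensor
#'
#' @param images List of `connectogram` objects with identical dimensions.
#' @param architecture Target architecture (decides 3-D vs 4-D layout).
#' @return For `"shallow_resnet"` an `(n, pairs, windows)` array; for
#'   `"custom_cnn"` an `(n, pairs, windows, 1)` array.
#' @export
connectogram_tensor <- function(images,
                                architecture = c("shallow_resnet", "custom_cnn")) {
  architecture <- match.arg(architecture)
  stopifnot(length(images) >= 1, all(vapply(images, inherits, TRUE, "connectogram")))
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    cc_input_error("images have non-uniform dimensions")
  n <- length(images)
  x <- array(0, c(n, dims[1, 1], dims[2, 1]))
  for (i in seq_len(n)) x[i, , ] <- images[[i]]$pixels
  if (architecture == "custom_cnn") dim(x) <- c(dim(x), 1L)
  x
}

#' Labels of a connectogram list
#'
#' @param images List of `connectogram` objects.
#' @return Character vector of class labels.
#' @export
connectogram_labels <- function(images)
  vapply(images, function(im) if (is.null(im$label)) NA_character_ else im$label, "")

#' Subjects of a connectogram list
#'
#' @param images List of `connectogram` objects.
#' @return Character vector of subject ids.
#' @export
connectogram_subjects <- function(images)
  vapply(images, function(im) im$subject_id, "")

#' Train a classifier
#'
#' Mini-batch training with softmax cross-entropy. `history` records the
#' running training loss/accuracy of each epoch and, when a validation set
#' is supplied, end-of-epoch validation loss/accuracy in inference mode.
#'
#' @param model An `nn_model` from [build_model()].
#' @param x Input tensor (see [connectogram_tensor()]).
#' @param y Class labels (character or factor), one per input row.
#' @param cfg A [train_config()].
#' @param validation Optional `list(x = ..., y = ...)` held-out set.
#' @param verbose Print per-epoch progress.
#' @return The fitted `nn_model`, with `$classes` and `$history` set.
#' @export
nn_train <- function(model, x, y, cfg = train_config(), validation = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(model, "nn_model"), inherits(cfg, "train_config"))
  n <- dim(x)[1]
  y <- as.character(y)
  if (length(y) != n) cc_input_error("length(y) must match nrow(x)")
  classes <- sort(unique(y))
  if (length(classes) < 2)
    cc_config_error("training set contains a single class; need >= 2")
  if (length(classes) > model$spec$n_classes)
    cc_config_error(sprintf("%d classes present but model has %d outputs",
                            length(classes), model$spec$n_classes))
  if (length(classes) < model$spec$n_classes)
    classes <- c(classes,
                 sprintf(".unused_%d", seq_len(model$spec$n_classes - length(classes))))
  yi <- match(y, classes)
  k <- model$spec$n_classes
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), yi)] <- 1

  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), val_loss = numeric(0),
                     val_accuracy = numeric(0))
  layers <- model$layers
  t_step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        xb <- x_rows(x, idx)
        yb <- onehot[idx, , drop = FALSE]
        fw <- chain_forward(layers, xb, training = TRUE)
        layers <- fw$layers
        p <- softmax_rows(fw$out)
        m <- length(idx)
        ep_loss <- ep_loss - sum(log(pmax(p[yb == 1], 1e-12)))
        ep_correct <- ep_correct + sum(max.col(p) == yi[idx])
        dlogits <- (p - yb) / m
        bw <- chain_backward(layers, fw$caches, dlogits)
        t_step <- t_step + 1L
        for (i in seq_along(layers)) {
          layers[[i]] <- if (cfg$optimizer == "adam")
            adam_step_layer(layers[[i]], bw$grads[[i]], cfg$learning_rate, t_step)
          else sgd_step_layer(layers[[i]], bw$grads[[i]], cfg$learning_rate)
        }
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(validation)) {
        vm <- model; vm$layers <- layers; vm$classes <- classes
        vp <- nn_predict(vm, validation$x)
        vyi <- match(as.character(validation$y), classes)
        val_loss <- -mean(log(pmax(vp[cbind(seq_along(vyi), vyi)], 1e-12)))
        val_acc <- mean(max.col(vp) == vyi)
      }
      hist[ep, ] <- list(ep, ep_loss / n, ep_correct / n, val_loss, val_acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s", ep,
                        ep_loss / n, ep_correct / n,
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  })
  model$layers <- layers
  model$classes <- classes
  model$history <- hist
  model
}

#' Predict class probabilities
#'
#' @param model A fitted `nn_model`.
#' @param x Input tensor.
#' @return `n x n_classes` matrix of softmax probabilities, columns named by
#'   class.
#' @export
nn_predict <- function(model, x) {
  stopifnot(inherits(model, "nn_model"))
  fw <- chain_forward(model$layers, x, training = FALSE)
  p <- softmax_rows(fw$out)
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}
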