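# Correctness of the conv-net engine: reference layer shapes, gradient
# agreement with central finite differences, determinism, and learning on a
# separable toy problem.

ns <- asNamespace("connectocoh")

nn_loss <- function(layers, x, yoh) {
  fw <- ns$chain_forward(layers, x, training = TRUE)
  p <- ns$softmax_rows(fw$out)
  -sum(yoh * log(pmax(p, 1e-12))) / nrow(yoh)
}

# walk a (possibly composite) layer stack, perturb single weights, compare
# analytic gradients with central finite differences
grad_check <- function(layers, x, yoh, n_per_param = 3, h = 1e-5) {
  fw <- ns$chain_forward(layers, x, training = TRUE)
  layers <- fw$layers
  p <- ns$softmax_rows(fw$out)
  bw <- ns$chain_backward(layers, fw$caches, (p - yoh) / nrow(yoh))
  worst <- 0
  visit <- function(path, grad_node) {
    sub <- layers
    for (pp in path) sub <- sub[[pp]]
    if (sub$type == "resblock1d") {
      for (i in seq_along(sub$main))
        visit(c(path, list("main", i)), grad_node$main[[i]])
      if (!is.null(sub$short))
        for (i in seq_along(sub$short))
          visit(c(path, list("short", i)), grad_node$short[[i]])
      return()
    }
    for (nm in names(sub$params)) {
      pv <- sub$params[[nm]]
      for (t in seq_len(min(n_per_param, length(pv)))) {
        j <- sample(length(pv), 1)
        lp <- set_param_at(layers, path, nm, replace_at(pv, j, h))
        lm <- set_param_at(layers, path, nm, replace_at(pv, j, -h))
        num <- (nn_loss(lp, x, yoh) - nn_loss(lm, x, yoh)) / (2 * h)
        gv <- grad_node[[nm]][j]
        # absolute floor: biases feeding BN have true gradient exactly 0
        worst <<- max(worst, abs(num - gv) / max(abs(num) + abs(gv), 1e-3))
      }
    }
  }
  for (i in seq_along(layers)) visit(list(i), bw$grads[[i]])
  for (t in 1:5) {
    j <- sample(length(x), 1)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    num <- (nn_loss(layers, xp, yoh) - nn_loss(layers, xm, yoh)) / (2 * h)
    worst <- max(worst, abs(num - bw$dx[j]) / max(abs(num) + abs(bw$dx[j]), 1e-3))
  }
  worst
}

replace_at <- function(v, j, delta) { v[j] <- v[j] + delta; v }

# functional nested assignment: path elements are indices or "main"/"short"
set_param_at <- function(layers, path, nm, val) {
  if (length(path) == 1L) {
    layers[[path[[1]]]]$params[[nm]] <- val
    return(layers)
  }
  layers[[path[[1]]]] <- set_param_at(layers[[path[[1]]]], path[-1], nm, val)
  layers
}

test_that("backpropagation matches finite differences for the 1-D residual stack", {
  set.seed(30)
  n <- 4; L <- 20; C <- 5
  x <- array(rnorm(n * L * C), c(n, L, C))
  yoh <- diag(3)[sample(1:3, n, TRUE), , drop = FALSE]
  layers <- list(ns$layer_conv1d(C, 6L, 3L, 2L, "same"), ns$layer_bn1d(6L),
                 ns$layer_relu(), ns$layer_maxpool1d(2L),
                 ns$layer_resblock1d(6L, 6L, 1L),
                 ns$layer_resblock1d(6L, 8L, 2L),
                 ns$layer_gap1d(), ns$layer_dense(8L, 3L))
  expect_lt(grad_check(layers, x, yoh), 1e-4)
})

test_that("backpropagation matches finite differences for the 2-D conv stack", {
  set.seed(31)
  n <- 3; H <- 13; W <- 11
  x <- array(rnorm(n * H * W), c(n, H, W, 1))
  yoh <- diag(3)[sample(1:3, n, TRUE), , drop = FALSE]
  layers <- list(ns$layer_conv2d(1L, 4L), ns$layer_relu(), ns$layer_maxpool2d(2L),
                 ns$layer_conv2d(4L, 6L), ns$layer_relu(), ns$layer_maxpool2d(2L),
                 ns$layer_flatten(), ns$layer_dense(6L, 3L))
  expect_lt(grad_check(layers, x, yoh), 1e-5)
})

test_that("custom CNN reproduces its reference layer shapes on 171x149 input", {
  spec <- model_spec("custom_cnn", c(171, 149, 1), 3)
  sh <- model_shapes(spec)
  expected <- c(input = "(171, 149, 1)",
                conv2d_1 = "(169, 147, 32)", maxpool2d_1 = "(84, 73, 32)",
                conv2d_2 = "(82, 71, 64)", maxpool2d_2 = "(41, 35, 64)",
                conv2d_3 = "(39, 33, 128)", maxpool2d_3 = "(19, 16, 128)",
                flatten = "(38912)", dense_1 = "(128)", dense_out = "(3)")
  expect_equal(setNames(sh$output, sh$layer), expected)
  # a real forward pass realises the flatten width
  model <- build_model(spec, seed = 1)
  x <- array(runif(1 * 171 * 149), c(1, 171, 149, 1))
  fw <- ns$chain_forward(model$layers, x, training = FALSE)
  expect_equal(dim(fw$out), c(1, 3))
  flat_idx <- which(vapply(model$layers, function(l) l$type, "") == "flatten")
  expect_equal(dim(model$layers[[flat_idx + 1]]$params$W), c(38912, 128))
})

test_that("shallow ResNet reproduces its reference layer shapes on (171, 149) input", {
  spec <- model_spec("shallow_resnet", c(171, 149), 3)
  sh <- model_shapes(spec)
  expected <- c(input = "(171, 149)", conv1d = "(86, 64)",
                batchnorm = "(86, 64)", relu = "(86, 64)",
                maxpool1d = "(43, 64)", resblock_1 = "(43, 64)",
                resblock_2 = "(22, 128)", resblock_3 = "(11, 256)",
                global_avg_pool = "(256)", dense_out = "(3)")
  expect_equal(setNames(sh$output, sh$layer), expected)
  model <- build_model(spec, seed = 1)
  x <- array(runif(2 * 171 * 149), c(2, 171, 149))
  fw <- ns$chain_forward(model$layers, x, training = FALSE)
  expect_equal(dim(fw$out), c(2, 3))
  # first conv halves the pair axis: 171 -> 86
  r1 <- ns$lay_forward(model$layers[[1]], x, training = FALSE)
  expect_equal(dim(r1$out), c(2, 86, 64))
})

test_that("an input too small for the pooling chain names the failing layer", {
  expect_error(model_spec("custom_cnn", c(8, 8, 1), 2) |> model_shapes(),
               "conv2d|maxpool2d")
  expect_error(build_model(model_spec("custom_cnn", c(10, 149, 1), 2)),
               "layer")
})

test_that("training is deterministic given the seeds and records history", {
  set.seed(32)
  n <- 12; L <- 12; C <- 4
  x <- array(rnorm(n * L * C), c(n, L, C))
  x[1:6, 1:4, ] <- x[1:6, 1:4, ] + 1
  y <- rep(c("p", "q"), each = 6)
  spec <- model_spec("shallow_resnet", c(L, C), 2)
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 9)
  f1 <- nn_train(build_model(spec, seed = 5), x, y, cfg)
  f2 <- nn_train(build_model(spec, seed = 5), x, y, cfg)
  expect_identical(f1$layers, f2$layers)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(c("epoch", "loss", "accuracy", "val_loss", "val_accuracy")
                  %in% names(f1$history)))
  # one epoch -> one history row
  f3 <- nn_train(build_model(spec, seed = 5), x, y,
                 train_config(epochs = 1, batch_size = 4, seed = 9))
  expect_equal(nrow(f3$history), 1)
  # a different init seed changes the weights
  f4 <- nn_train(build_model(spec, seed = 6), x, y, cfg)
  expect_false(identical(f1$layers, f4$layers))
})

test_that("single-class training sets are rejected", {
  x <- array(rnorm(4 * 12 * 4), c(4, 12, 4))
  spec <- model_spec("shallow_resnet", c(12, 4), 2)
  expect_error(nn_train(build_model(spec), x, rep("only", 4), train_config(epochs = 1)),
               "single class")
})

test_that("both architectures fit a linearly separable image set within 20 epochs", {
  set.seed(33)
  n <- 24
  mk_imgs <- function() {
    x <- array(runif(n * 26 * 22, 0.3, 0.5), c(n, 26, 22))
    x[1:12, 5:12, 5:12] <- x[1:12, 5:12, 5:12] + 0.3   # class-mean shift
    x
  }
  y <- rep(c("a", "b"), each = 12)
  x1 <- mk_imgs()
  rn <- nn_train(build_model(model_spec("shallow_resnet", c(26, 22), 2), seed = 2),
                 x1, y, train_config(epochs = 20, batch_size = 8, seed = 3))
  expect_gte(rn$history$accuracy[nrow(rn$history)], 0.95)
  x2 <- x1; dim(x2) <- c(n, 26, 22, 1)
  cn <- nn_train(build_model(model_spec("custom_cnn", c(26, 22), 2), seed = 2),
                 x2, y, train_config(epochs = 20, batch_size = 8, seed = 3))
  expect_gte(cn$history$accuracy[nrow(cn$history)], 0.95)
  # predictions carry class names and are proper probabilities
  p <- nn_predict(rn, x1)
  expect_equal(colnames(p), c("a", "b"))
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-9)
})
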