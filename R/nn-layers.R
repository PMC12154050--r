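# Minimal feed-forward convolutional network engine (pure R, im2col + BLAS
# matrix products). Layouts: 1-D activations are (batch, length, channels)
# arrays, 2-D activations are (batch, height, width, channels) arrays, dense
# activations are (batch, features) matrices. Each layer implements a
# forward pass returning an output plus a cache, and a backward pass mapping
# the output gradient to an input gradient and parameter gradients.
# Backward passes are verified against finite differences in the test suite.

# ---- initializers ----------------------------------------------------------

he_normal <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- layer constructors ----------------------------------------------------

layer_conv1d <- function(in_ch, out_ch, k = 3L, stride = 1L,
                         padding = c("same", "valid")) {
  padding <- match.arg(padding)
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, padding = padding,
       params = list(W = he_normal(k * in_ch, out_ch, k * in_ch),
                     b = numeric(out_ch)))
}

layer_conv2d <- function(in_ch, out_ch, k = 3L) {
  # valid padding, stride 1 (the only variant the 2-D stack needs)
  list(type = "conv2d", in_ch = in_ch, out_ch = out_ch, k = k,
       params = list(W = he_normal(k * k * in_ch, out_ch, k * k * in_ch),
                     b = numeric(out_ch)))
}

layer_bn1d <- function(ch, momentum = 0.9, eps = 1e-5) {
  list(type = "bn1d", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

layer_relu <- function() list(type = "relu", params = list())

layer_maxpool1d <- function(pool = 2L)
  list(type = "maxpool1d", pool = pool, params = list())

layer_maxpool2d <- function(pool = 2L)
  list(type = "maxpool2d", pool = pool, params = list())

layer_gap1d <- function() list(type = "gap1d", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(d_in, d_out, init = c("he", "glorot")) {
  init <- match.arg(init)
  W <- if (init == "he") he_normal(d_in, d_out, d_in) else glorot_uniform(d_in, d_out)
  list(type = "dense", d_in = d_in, d_out = d_out,
       params = list(W = W, b = numeric(d_out)))
}

# Basic residual block: conv-BN-ReLU-conv-BN on the main path, identity or
# projection (1x1 strided conv + BN) shortcut, ReLU after the addition.
layer_resblock1d <- function(in_ch, out_ch, stride = 1L) {
  main <- list(layer_conv1d(in_ch, out_ch, 3L, stride, "same"),
               layer_bn1d(out_ch),
               layer_relu(),
               layer_conv1d(out_ch, out_ch, 3L, 1L, "same"),
               layer_bn1d(out_ch))
  short <- if (stride != 1L || in_ch != out_ch)
    list(layer_conv1d(in_ch, out_ch, 1L, stride, "same"), layer_bn1d(out_ch))
  else NULL
  list(type = "resblock1d", in_ch = in_ch, out_ch = out_ch, stride = stride,
       main = main, short = short, params = list())
}

# ---- padding arithmetic (TensorFlow "same" convention) ---------------------

pad1d_same <- function(L, k, s) {
  lout <- ceiling(L / s)
  total <- max((lout - 1) * s + k - L, 0)
  c(total %/% 2, total - total %/% 2)
}

conv1d_out_len <- function(L, k, s, padding) {
  if (padding == "same") ceiling(L / s) else (L - k) %/% s + 1L
}

# ---- forward / backward per type -------------------------------------------

fwd_conv1d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  k <- layer$k; s <- layer$stride
  pd <- if (layer$padding == "same") pad1d_same(L, k, s) else c(0L, 0L)
  Lp <- L + pd[1] + pd[2]
  if (Lp < k) cc_config_error(sprintf(
    "conv1d: input length %d smaller than kernel %d", L, k))
  if (pd[1] || pd[2]) {
    xp <- array(0, c(n, Lp, C))
    xp[, (pd[1] + 1):(pd[1] + L), ] <- x
  } else xp <- x
  Lout <- (Lp - k) %/% s + 1L
  starts <- seq(1L, by = s, length.out = Lout)
  cols <- array(0, c(n, Lout, k * C))
  for (j in seq_len(k))
    cols[, , ((j - 1) * C + 1):(j * C)] <- xp[, starts + j - 1L, , drop = FALSE]
  dim(cols) <- c(n * Lout, k * C)
  out <- cols %*% layer$params$W
  out <- out + rep(layer$params$b, each = nrow(out))
  dim(out) <- c(n, Lout, layer$out_ch)
  list(out = out,
       cache = list(cols = cols, n = n, L = L, C = C, Lp = Lp, Lout = Lout,
                    starts = starts, pd = pd),
       layer = layer)
}

bwd_conv1d <- function(layer, cache, dout) {
  k <- layer$k; C <- cache$C
  dm <- dout; dim(dm) <- c(cache$n * cache$Lout, layer$out_ch)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(layer$params$W)
  dim(dcols) <- c(cache$n, cache$Lout, k * C)
  dxp <- array(0, c(cache$n, cache$Lp, C))
  for (j in seq_len(k)) {
    idx <- cache$starts + j - 1L
    dxp[, idx, ] <- dxp[, idx, ] + dcols[, , ((j - 1) * C + 1):(j * C)]
  }
  dx <- dxp[, (cache$pd[1] + 1):(cache$pd[1] + cache$L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_conv2d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  k <- layer$k
  if (H < k || W < k) cc_config_error(sprintf(
    "conv2d: input %dx%d smaller than %dx%d kernel", H, W, k, k))
  oh <- H - k + 1L; ow <- W - k + 1L
  cols <- array(0, c(n, oh, ow, k * k * C))
  p <- 0L
  for (dw in seq_len(k)) for (dh in seq_len(k)) {
    cols[, , , (p * C + 1):((p + 1) * C)] <-
      x[, dh:(dh + oh - 1L), dw:(dw + ow - 1L), , drop = FALSE]
    p <- p + 1L
  }
  dim(cols) <- c(n * oh * ow, k * k * C)
  out <- cols %*% layer$params$W
  out <- out + rep(layer$params$b, each = nrow(out))
  dim(out) <- c(n, oh, ow, layer$out_ch)
  list(out = out,
       cache = list(cols = cols, n = n, H = H, W = W, C = C, oh = oh, ow = ow),
       layer = layer)
}

bwd_conv2d <- function(layer, cache, dout) {
  k <- layer$k; C <- cache$C
  dm <- dout; dim(dm) <- c(cache$n * cache$oh * cache$ow, layer$out_ch)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(layer$params$W)
  dim(dcols) <- c(cache$n, cache$oh, cache$ow, k * k * C)
  dx <- array(0, c(cache$n, cache$H, cache$W, C))
  p <- 0L
  for (dw in seq_len(k)) for (dh in seq_len(k)) {
    hs <- dh:(dh + cache$oh - 1L); ws <- dw:(dw + cache$ow - 1L)
    dx[, hs, ws, ] <- dx[, hs, ws, ] + dcols[, , , (p * C + 1):((p + 1) * C)]
    p <- p + 1L
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_bn1d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  xm <- x; dim(xm) <- c(n * L, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n * L)
    varb <- colMeans(xc^2)
    layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
    layer$running_var  <- layer$momentum * layer$running_var  + (1 - layer$momentum) * varb
  } else {
    mu <- layer$running_mean
    varb <- layer$running_var
    xc <- xm - rep(mu, each = n * L)
  }
  invstd <- 1 / sqrt(varb + layer$eps)
  xhat <- xc * rep(invstd, each = n * L)
  out <- xhat * rep(layer$params$gamma, each = n * L) +
    rep(layer$params$beta, each = n * L)
  dim(out) <- d
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, d = d, training = training),
       layer = layer)
}

bwd_bn1d <- function(layer, cache, dout) {
  d <- cache$d; N <- d[1] * d[2]; C <- d[3]
  dm <- dout; dim(dm) <- c(N, C)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(layer$params$gamma, each = N)
  if (cache$training) {
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - rep(t1 / N, each = N) -
           cache$xhat * rep(t2 / N, each = N)) * rep(cache$invstd, each = N)
  } else {
    dx <- dxhat * rep(cache$invstd, each = N)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fwd_relu <- function(layer, x, training) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = list(mask = mask), layer = layer)
}

bwd_relu <- function(layer, cache, dout) {
  dout[!cache$mask] <- 0
  list(dx = dout, grads = list())
}

fwd_maxpool1d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]; p <- layer$pool
  Lout <- L %/% p
  if (Lout < 1) cc_config_error(sprintf(
    "maxpool1d: input length %d smaller than pool %d", L, p))
  xr <- x[, seq_len(Lout * p), , drop = FALSE]
  dim(xr) <- c(n, p, Lout, C)
  out <- array(xr[, 1L, , ], c(n, Lout, C))
  amax <- array(1L, c(n, Lout, C))
  for (q in seq_len(p)[-1]) {
    sq <- array(xr[, q, , ], c(n, Lout, C))
    upd <- sq > out
    out[upd] <- sq[upd]
    amax[upd] <- q
  }
  list(out = out, cache = list(amax = amax, L = L, p = p, Lout = Lout,
                               n = n, C = C), layer = layer)
}

bwd_maxpool1d <- function(layer, cache, dout) {
  n <- cache$n; C <- cache$C; p <- cache$p; Lout <- cache$Lout
  dxr <- array(0, c(n, p, Lout, C))
  for (q in seq_len(p)) {
    tmp <- array(0, c(n, Lout, C))
    sel <- cache$amax == q
    tmp[sel] <- dout[sel]
    dxr[, q, , ] <- tmp
  }
  dim(dxr) <- c(n, p * Lout, C)
  dx <- array(0, c(n, cache$L, C))
  dx[, seq_len(p * Lout), ] <- dxr
  list(dx = dx, grads = list())
}

fwd_maxpool2d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]; p <- layer$pool
  oh <- H %/% p; ow <- W %/% p
  if (oh < 1 || ow < 1) cc_config_error(sprintf(
    "maxpool2d: input %dx%d smaller than pool %d", H, W, p))
  xr <- x[, seq_len(oh * p), seq_len(ow * p), , drop = FALSE]
  dim(xr) <- c(n, p, oh, p, ow, C)
  out <- NULL; amax <- NULL
  q <- 0L
  for (q2 in seq_len(p)) for (q1 in seq_len(p)) {
    q <- q + 1L
    sq <- array(xr[, q1, , q2, , ], c(n, oh, ow, C))
    if (is.null(out)) {
      out <- sq; amax <- array(1L, c(n, oh, ow, C))
    } else {
      upd <- sq > out
      out[upd] <- sq[upd]
      amax[upd] <- q
    }
  }
  list(out = out, cache = list(amax = amax, H = H, W = W, p = p, oh = oh,
                               ow = ow, n = n, C = C), layer = layer)
}

bwd_maxpool2d <- function(layer, cache, dout) {
  n <- cache$n; C <- cache$C; p <- cache$p; oh <- cache$oh; ow <- cache$ow
  dxr <- array(0, c(n, p, oh, p, ow, C))
  q <- 0L
  for (q2 in seq_len(p)) for (q1 in seq_len(p)) {
    q <- q + 1L
    tmp <- array(0, c(n, oh, ow, C))
    sel <- cache$amax == q
    tmp[sel] <- dout[sel]
    dxr[, q1, , q2, , ] <- tmp
  }
  dim(dxr) <- c(n, p * oh, p * ow, C)
  dx <- array(0, c(n, cache$H, cache$W, C))
  dx[, seq_len(p * oh), seq_len(p * ow), ] <- dxr
  list(dx = dx, grads = list())
}

fwd_gap1d <- function(layer, x, training) {
  d <- dim(x)
  out <- colMeans(aperm(x, c(2L, 1L, 3L)))        # (n, C)
  list(out = out, cache = list(d = d), layer = layer)
}

bwd_gap1d <- function(layer, cache, dout) {
  d <- cache$d
  dx <- aperm(array(dout / d[2], c(d[1], d[3], d[2])), c(1L, 3L, 2L))
  list(dx = dx, grads = list())
}

fwd_flatten <- function(layer, x, training) {
  d <- dim(x)
  out <- x; dim(out) <- c(d[1], prod(d[-1]))
  list(out = out, cache = list(d = d), layer = layer)
}

bwd_flatten <- function(layer, cache, dout) {
  dim(dout) <- cache$d
  list(dx = dout, grads = list())
}

fwd_dense <- function(layer, x, training) {
  out <- x %*% layer$params$W
  out <- out + rep(layer$params$b, each = nrow(out))
  list(out = out, cache = list(x = x), layer = layer)
}

bwd_dense <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

fwd_resblock1d <- function(layer, x, training) {
  mf <- chain_forward(layer$main, x, training)
  layer$main <- mf$layers
  if (is.null(layer$short)) {
    sh <- x; scache <- NULL
  } else {
    sf <- chain_forward(layer$short, x, training)
    layer$short <- sf$layers
    sh <- sf$out; scache <- sf$caches
  }
  s <- mf$out + sh
  mask <- s > 0
  s[!mask] <- 0
  list(out = s,
       cache = list(main = mf$caches, short = scache, mask = mask),
       layer = layer)
}

bwd_resblock1d <- function(layer, cache, dout) {
  dout[!cache$mask] <- 0
  mb <- chain_backward(layer$main, cache$main, dout)
  if (is.null(layer$short)) {
    dx <- mb$dx + dout
    grads <- list(main = mb$grads, short = NULL)
  } else {
    sb <- chain_backward(layer$short, cache$short, dout)
    dx <- mb$dx + sb$dx
    grads <- list(main = mb$grads, short = sb$grads)
  }
  list(dx = dx, grads = grads)
}

# ---- generic dispatch and chains -------------------------------------------

lay_forward <- function(layer, x, training) {
  switch(layer$type,
         conv1d = fwd_conv1d(layer, x, training),
         conv2d = fwd_conv2d(layer, x, training),
         bn1d = fwd_bn1d(layer, x, training),
         relu = fwd_relu(layer, x, training),
         maxpool1d = fwd_maxpool1d(layer, x, training),
         maxpool2d = fwd_maxpool2d(layer, x, training),
         gap1d = fwd_gap1d(layer, x, training),
         flatten = fwd_flatten(layer, x, training),
         dense = fwd_dense(layer, x, training),
         resblock1d = fwd_resblock1d(layer, x, training),
         cc_config_error(sprintf("unknown layer type '%s'", layer$type)))
}

lay_backward <- function(layer, cache, dout) {
  switch(layer$type,
         conv1d = bwd_conv1d(layer, cache, dout),
         conv2d = bwd_conv2d(layer, cache, dout),
         bn1d = bwd_bn1d(layer, cache, dout),
         relu = bwd_relu(layer, cache, dout),
         maxpool1d = bwd_maxpool1d(layer, cache, dout),
         maxpool2d = bwd_maxpool2d(layer, cache, dout),
         gap1d = bwd_gap1d(layer, cache, dout),
         flatten = bwd_flatten(layer, cache, dout),
         dense = bwd_dense(layer, cache, dout),
         resblock1d = bwd_resblock1d(layer, cache, dout),
         cc_config_error(sprintf("unknown layer type '%s'", layer$type)))
}

chain_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- lay_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

chain_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- lay_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# ---- Adam updates (recursive over composite layers) ------------------------

adam_init_like <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step_layer <- function(layer, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  if (layer$type == "resblock1d") {
    for (i in seq_along(layer$main))
      layer$main[[i]] <- adam_step_layer(layer$main[[i]], grads$main[[i]],
                                         lr, t, beta1, beta2, eps)
    if (!is.null(layer$short))
      for (i in seq_along(layer$short))
        layer$short[[i]] <- adam_step_layer(layer$short[[i]], grads$short[[i]],
                                            lr, t, beta1, beta2, eps)
    return(layer)
  }
  if (!length(layer$params)) return(layer)
  if (is.null(layer$opt)) layer$opt <- adam_init_like(layer$params)
  for (nm in names(layer$params)) {
    g <- grads[[nm]]
    st <- layer$opt[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    layer$params[[nm]] <- layer$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    layer$opt[[nm]] <- st
  }
  layer
}

sgd_step_layer <- function(layer, grads, lr) {
  if (layer$type == "resblock1d") {
    for (i in seq_along(layer$main))
      layer$main[[i]] <- sgd_step_layer(layer$main[[i]], grads$main[[i]], lr)
    if (!is.null(layer$short))
      for (i in seq_along(layer$short))
        layer$short[[i]] <- sgd_step_layer(layer$short[[i]], grads$short[[i]], lr)
    return(layer)
  }
  for (nm in names(layer$params))
    layer$params[[nm]] <- layer$params[[nm]] - lr * grads[[nm]]
  layer
}
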