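# Minimal neural-network engine for small cytometry models.
#
# Layers operate on batches stored as base-R arrays:
#   dense input: (N, D) matrix
#   1-D conv input: (N, C, L) array (C feature channels over a length-L signal)
#   2-D conv input: (N, C, H, W) array
# Every layer implements a forward pass returning (out, cache) and a backward
# pass returning (grad_input, parameter gradients). Gradients are verified
# against central finite differences in the test suite.

nn_layer <- function(type, ...) {
  l <- list(type = type, ...)
  class(l) <- c(paste0("nnl_", type), "nn_layer")
  l
}

# He-uniform initialisation, deterministic under the caller's RNG state
init_w <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

layer_conv1d <- function(in_ch, out_ch, kernel, pad = (kernel - 1L) %/% 2L) {
  nn_layer("conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
           pad = pad,
           W = init_w(c(out_ch, in_ch, kernel), in_ch * kernel),
           b = numeric(out_ch))
}

layer_bn <- function(n_ch, ndim) {
  # ndim: 1 for (N,D) features, 2 for (N,C,L), 3 for (N,C,H,W)
  nn_layer("bn", n_ch = n_ch, ndim = ndim, eps = 1e-5, momentum = 0.1,
           gamma = rep(1, n_ch), beta = numeric(n_ch),
           run_mean = numeric(n_ch), run_var = rep(1, n_ch))
}

layer_relu <- function() nn_layer("relu")
layer_maxpool1d <- function(kernel = 2L) nn_layer("maxpool1d", kernel = kernel)
layer_gap1d <- function() nn_layer("gap1d")  # adaptive average pool -> (N, C)
layer_gap2d <- function() nn_layer("gap2d")

layer_linear <- function(in_dim, out_dim) {
  nn_layer("linear", in_dim = in_dim, out_dim = out_dim,
           W = init_w(c(in_dim, out_dim), in_dim), b = numeric(out_dim))
}

layer_conv2d <- function(in_ch, out_ch, kernel, stride = 1L,
                         pad = (kernel - 1L) %/% 2L) {
  nn_layer("conv2d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
           stride = stride, pad = pad,
           W = init_w(c(out_ch, in_ch, kernel, kernel),
                      in_ch * kernel * kernel),
           b = numeric(out_ch))
}

# residual block: out = relu(body(x) + shortcut(x)); body/shortcut are layer
# lists (shortcut empty => identity)
layer_residual <- function(body, shortcut = list()) {
  nn_layer("residual", body = body, shortcut = shortcut)
}

# -- forward -----------------------------------------------------------------

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fc <- layer_forward(layers[[i]], x, training)
    x <- fc$out
    caches[[i]] <- fc$cache
    if (training && !is.null(fc$layer)) layers[[i]] <- fc$layer
  }
  list(out = x, caches = caches, layers = layers)
}

layer_forward <- function(layer, x, training) UseMethod("layer_forward")

layer_forward.nnl_relu <- function(layer, x, training) {
  list(out = pmax(x, 0), cache = list(mask = x > 0))
}

layer_forward.nnl_linear <- function(layer, x, training) {
  list(out = sweep(x %*% layer$W, 2, layer$b, `+`), cache = list(x = x))
}

pad1d <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2L * p))
  xp[, , (p + 1L):(p + d[3])] <- x
  xp
}

layer_forward.nnl_conv1d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; L <- d[3]; k <- layer$kernel
  xp <- pad1d(x, layer$pad)
  Lo <- dim(xp)[3] - k + 1L
  if (Lo < 1L) stop_config("conv1d kernel larger than its input signal")
  Wmat <- matrix(aperm(layer$W, c(2, 3, 1)), ncol = layer$out_ch)
  out <- array(0, c(n, layer$out_ch, Lo))
  xwins <- vector("list", Lo)
  for (l in seq_len(Lo)) {
    xl <- matrix(xp[, , l:(l + k - 1L), drop = FALSE], nrow = n)
    xwins[[l]] <- xl
    out[, , l] <- sweep(xl %*% Wmat, 2, layer$b, `+`)
  }
  list(out = out, cache = list(xwins = xwins, in_dim = d))
}

layer_forward.nnl_maxpool1d <- function(layer, x, training) {
  d <- dim(x); k <- layer$kernel
  Lo <- d[3] %/% k
  if (Lo < 1L) stop_config("maxpool window larger than its input signal")
  out <- x[, , seq(1L, by = k, length.out = Lo), drop = FALSE]
  amax <- array(1L, c(d[1], d[2], Lo))
  for (j in seq_len(k)[-1]) {
    sl <- x[, , seq(j, by = k, length.out = Lo), drop = FALSE]
    better <- sl > out
    out[better] <- sl[better]
    amax[better] <- j
  }
  list(out = out, cache = list(amax = amax, in_dim = d))
}

layer_forward.nnl_gap1d <- function(layer, x, training) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  out <- rowMeans(xm); dim(out) <- d[1:2]
  list(out = out, cache = list(in_dim = d))
}

layer_forward.nnl_gap2d <- function(layer, x, training) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- rowMeans(xm); dim(out) <- d[1:2]
  list(out = out, cache = list(in_dim = d))
}

bn_axes <- function(x, ndim) {
  # returns x reshaped to (n_obs, n_ch) view indices
  switch(as.character(ndim),
         "1" = x,
         "2" = matrix(aperm(x, c(1, 3, 2)), ncol = dim(x)[2]),
         "3" = matrix(aperm(x, c(1, 3, 4, 2)), ncol = dim(x)[2]))
}

bn_unaxes <- function(m, ndim, d) {
  switch(as.character(ndim),
         "1" = m,
         "2" = aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2)),
         "3" = aperm(array(m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3)))
}

layer_forward.nnl_bn <- function(layer, x, training) {
  d <- dim(x); if (is.null(d)) d <- c(nrow(x), ncol(x))
  xm <- bn_axes(x, layer$ndim)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  inv_sd <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, `*`)
  ym <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  list(out = bn_unaxes(ym, layer$ndim, d),
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d,
                    training = training),
       layer = layer)
}

pad2d <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  xp[, , (p + 1L):(p + d[3]), (p + 1L):(p + d[4])] <- x
  xp
}

conv2d_cols <- function(xp, k, s, Ho, Wo) {
  d <- dim(xp); n <- d[1]; C <- d[2]
  col <- array(0, c(n, Ho, Wo, C, k * k))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      q <- ki + k * (kj - 1L)
      sub <- xp[, , seq(ki, by = s, length.out = Ho),
                seq(kj, by = s, length.out = Wo), drop = FALSE]
      col[, , , , q] <- aperm(sub, c(1, 3, 4, 2))
    }
  }
  dim(col) <- c(n * Ho * Wo, C * k * k)
  col
}

layer_forward.nnl_conv2d <- function(layer, x, training) {
  d <- dim(x); n <- d[1]; k <- layer$kernel; s <- layer$stride
  xp <- pad2d(x, layer$pad)
  dp <- dim(xp)
  Ho <- (dp[3] - k) %/% s + 1L
  Wo <- (dp[4] - k) %/% s + 1L
  if (Ho < 1L || Wo < 1L) stop_config("conv2d kernel larger than its input")
  X <- conv2d_cols(xp, k, s, Ho, Wo)
  Wmat <- matrix(aperm(layer$W, c(2, 3, 4, 1)), ncol = layer$out_ch)
  out <- sweep(X %*% Wmat, 2, layer$b, `+`)
  out <- aperm(array(out, c(n, Ho, Wo, layer$out_ch)), c(1, 4, 2, 3))
  list(out = out, cache = list(X = X, in_dim = d, Ho = Ho, Wo = Wo))
}

layer_forward.nnl_residual <- function(layer, x, training) {
  fb <- nn_forward(layer$body, x, training)
  if (length(layer$shortcut)) {
    fs <- nn_forward(layer$shortcut, x, training)
    sc <- fs$out
  } else {
    fs <- NULL
    sc <- x
  }
  pre <- fb$out + sc
  out <- pmax(pre, 0)
  if (training) {
    layer$body <- fb$layers
    if (!is.null(fs)) layer$shortcut <- fs$layers
  }
  list(out = out,
       cache = list(bcache = fb$caches, scache = if (is.null(fs)) NULL else fs$caches,
                    mask = pre > 0),
       layer = layer)
}

# -- backward ----------------------------------------------------------------

nn_backward <- function(layers, caches, grad_out) {
  grads <- vector("list", length(layers))
  g <- grad_out
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], caches[[i]], g)
    g <- bk$gx
    grads[i] <- list(bk$gp)  # keep NULL placeholders for parameter-free layers
  }
  list(gx = g, grads = grads)
}

layer_backward <- function(layer, cache, g) UseMethod("layer_backward")

layer_backward.nnl_relu <- function(layer, cache, g) {
  list(gx = g * cache$mask, gp = NULL)
}

layer_backward.nnl_linear <- function(layer, cache, g) {
  list(gx = g %*% t(layer$W),
       gp = list(W = t(cache$x) %*% g, b = colSums(g)))
}

layer_backward.nnl_conv1d <- function(layer, cache, g) {
  d <- cache$in_dim; n <- d[1]; k <- layer$kernel; p <- layer$pad
  Lo <- dim(g)[3]
  Wmat <- matrix(aperm(layer$W, c(2, 3, 1)), ncol = layer$out_ch)
  dW <- matrix(0, nrow = nrow(Wmat), ncol = ncol(Wmat))
  db <- numeric(layer$out_ch)
  gxp <- array(0, c(n, d[2], d[3] + 2L * p))
  for (l in seq_len(Lo)) {
    gl <- matrix(g[, , l], nrow = n)
    dW <- dW + t(cache$xwins[[l]]) %*% gl
    db <- db + colSums(gl)
    dxl <- gl %*% t(Wmat)
    gxp[, , l:(l + k - 1L)] <- gxp[, , l:(l + k - 1L), drop = FALSE] +
      array(dxl, c(n, d[2], k))
  }
  gx <- if (p > 0L) gxp[, , (p + 1L):(p + d[3]), drop = FALSE] else gxp
  list(gx = gx,
       gp = list(W = aperm(array(dW, c(d[2], k, layer$out_ch)), c(3, 1, 2)),
                 b = db))
}

layer_backward.nnl_maxpool1d <- function(layer, cache, g) {
  d <- cache$in_dim; k <- layer$kernel
  gx <- array(0, d)
  Lo <- dim(g)[3]
  for (j in seq_len(k)) {
    sel <- cache$amax == j
    gs <- array(0, dim(g))
    gs[sel] <- g[sel]
    gx[, , seq(j, by = k, length.out = Lo)] <- gs
  }
  list(gx = gx, gp = NULL)
}

layer_backward.nnl_gap1d <- function(layer, cache, g) {
  d <- cache$in_dim
  gx <- array(rep(as.vector(g) / d[3], d[3]), d)
  list(gx = gx, gp = NULL)
}

layer_backward.nnl_gap2d <- function(layer, cache, g) {
  d <- cache$in_dim
  gx <- array(rep(as.vector(g) / (d[3] * d[4]), d[3] * d[4]), d)
  list(gx = gx, gp = NULL)
}

layer_backward.nnl_bn <- function(layer, cache, g) {
  d <- cache$d
  gm <- bn_axes(g, layer$ndim)
  xhat <- cache$xhat
  dgamma <- colSums(gm * xhat)
  dbeta <- colSums(gm)
  if (cache$training) {
    m <- nrow(gm)
    dxhat <- sweep(gm, 2, layer$gamma, `*`)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
    dxm <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
  } else {
    dxm <- sweep(sweep(gm, 2, layer$gamma, `*`), 2, cache$inv_sd, `*`)
  }
  list(gx = bn_unaxes(dxm, layer$ndim, d),
       gp = list(gamma = dgamma, beta = dbeta))
}

layer_backward.nnl_conv2d <- function(layer, cache, g) {
  d <- cache$in_dim; n <- d[1]; k <- layer$kernel; s <- layer$stride
  p <- layer$pad; Ho <- cache$Ho; Wo <- cache$Wo
  gm <- matrix(aperm(g, c(1, 3, 4, 2)), ncol = layer$out_ch)
  Wmat <- matrix(aperm(layer$W, c(2, 3, 4, 1)), ncol = layer$out_ch)
  dWmat <- t(cache$X) %*% gm
  db <- colSums(gm)
  dX <- gm %*% t(Wmat)
  dim(dX) <- c(n, Ho, Wo, d[2], k * k)
  gxp <- array(0, c(n, d[2], d[3] + 2L * p, d[4] + 2L * p))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      q <- ki + k * (kj - 1L)
      ri <- seq(ki, by = s, length.out = Ho)
      rj <- seq(kj, by = s, length.out = Wo)
      sub <- dX[, , , , q, drop = FALSE]
      dim(sub) <- dim(dX)[1:4]
      gxp[, , ri, rj] <- gxp[, , ri, rj, drop = FALSE] +
        aperm(sub, c(1, 4, 2, 3))
    }
  }
  gx <- if (p > 0L)
    gxp[, , (p + 1L):(p + d[3]), (p + 1L):(p + d[4]), drop = FALSE]
  else gxp
  dW <- aperm(array(dWmat, c(d[2], k, k, layer$out_ch)), c(4, 1, 2, 3))
  list(gx = gx, gp = list(W = dW, b = db))
}

layer_backward.nnl_residual <- function(layer, cache, g) {
  g <- g * cache$mask
  bb <- nn_backward(layer$body, cache$bcache, g)
  if (length(layer$shortcut)) {
    sb <- nn_backward(layer$shortcut, cache$scache, g)
    gx <- bb$gx + sb$gx
    gp <- list(body = bb$grads, shortcut = sb$grads)
  } else {
    gx <- bb$gx + g
    gp <- list(body = bb$grads, shortcut = NULL)
  }
  list(gx = gx, gp = gp)
}

# -- parameter plumbing ------------------------------------------------------

PARAM_NAMES <- c("W", "b", "gamma", "beta")

layer_params <- function(layer) {
  if (layer$type == "residual") {
    list(body = lapply(layer$body, layer_params),
         shortcut = lapply(layer$shortcut, layer_params))
  } else {
    layer[intersect(PARAM_NAMES, names(layer))]
  }
}

set_layer_params <- function(layer, params) {
  if (layer$type == "residual") {
    for (i in seq_along(layer$body))
      layer$body[[i]] <- set_layer_params(layer$body[[i]], params$body[[i]])
    for (i in seq_along(layer$shortcut))
      layer$shortcut[[i]] <- set_layer_params(layer$shortcut[[i]],
                                              params$shortcut[[i]])
  } else {
    for (nm in names(params)) layer[[nm]] <- params[[nm]]
  }
  layer
}

# flatten nested parameter lists into a flat named list of arrays
flatten_params <- function(plist, prefix = "") {
  out <- list()
  for (i in seq_along(plist)) {
    p <- plist[[i]]
    nm <- names(plist)[i]
    key <- if (is.null(nm) || nm == "" || grepl("^[0-9]*$", nm))
      paste0(prefix, i) else paste0(prefix, nm)
    if (is.list(p)) out <- c(out, flatten_params(p, paste0(key, ".")))
    else if (!is.null(p)) out[[key]] <- p
  }
  out
}

# counts of layer types, recursing through residual blocks
layer_census <- function(layers) {
  census <- c(conv1d = 0L, conv2d = 0L, bn = 0L, maxpool1d = 0L,
              linear = 0L, relu = 0L, gap1d = 0L, gap2d = 0L,
              residual = 0L)
  for (l in layers) {
    census[l$type] <- census[l$type] + 1L
    if (l$type == "residual") {
      inner <- layer_census(c(l$body, l$shortcut))
      census <- census + inner
    }
  }
  census
}

# -- loss --------------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class 1..K; w: per-class weights
cross_entropy <- function(logits, y, w = NULL) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  wi <- if (is.null(w)) rep(1, n) else w[y]
  idx <- cbind(seq_len(n), y)
  loss <- sum(wi * -log(pmax(p[idx], 1e-12))) / sum(wi)
  grad <- p
  grad[idx] <- grad[idx] - 1
  grad <- grad * (wi / sum(wi))
  list(loss = loss, grad = grad, prob = p)
}
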