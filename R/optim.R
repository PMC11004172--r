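# Ranger optimizer: RAdam (rectified Adam) wrapped in Lookahead slow weights.
# An Adam fallback with the same learning rate is available behind the
# config flag. State is kept per parameter tensor in a flat named list.

optim_init <- function(params, method = c("ranger", "adam"), lr = 5e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       la_k = 6L, la_alpha = 0.5) {
  method <- match.arg(method)
  list(method = method, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L,
       m = lapply(params, function(p) array(0, dim(as.array(p)))),
       v = lapply(params, function(p) array(0, dim(as.array(p)))),
       la_k = la_k, la_alpha = la_alpha,
       slow = if (method == "ranger") params else NULL)
}

optim_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2
  rho_inf <- 2 / (1 - b2) - 1
  for (k in names(params)) {
    g <- as.array(grads[[k]])
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    mhat <- state$m[[k]] / (1 - b1^t)
    if (state$method == "adam") {
      vhat <- state$v[[k]] / (1 - b2^t)
      upd <- state$lr * mhat / (sqrt(vhat) + state$eps)
    } else {
      rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
      if (rho_t > 4) {
        vhat <- sqrt(state$v[[k]] / (1 - b2^t))
        r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                      ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        upd <- state$lr * r_t * mhat / (vhat + state$eps)
      } else {
        upd <- state$lr * mhat  # unrectified warm-up step
      }
    }
    params[[k]] <- params[[k]] - upd
  }
  if (state$method == "ranger" && state$t %% state$la_k == 0L) {
    for (k in names(params)) {
      state$slow[[k]] <- state$slow[[k]] +
        state$la_alpha * (params[[k]] - state$slow[[k]])
      params[[k]] <- state$slow[[k]]
    }
  }
  list(state = state, params = params)
}

# -- generic mini-batch trainer ---------------------------------------------

# layers: nn layer list; x: batch array/matrix; y: integer classes 1..K.
# Carves a validation split from the data, early-stops on validation-loss
# plateau, and tracks the best weights seen.
train_network <- function(layers, x, y, n_classes,
                          lr = 5e-3, max_epochs = 75L, batch_size = 128L,
                          optimizer = c("ranger", "adam"),
                          class_weights = NULL, val_fraction = 0.1,
                          patience = 10L, seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  if (length(unique(y)) < 2L)
    stop_degenerate("training requires at least two classes")
  set.seed(seed)
  # stratified validation split
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    nv <- max(1L, round(length(ix) * val_fraction))
    if (length(ix) <= 1L) integer(0) else sample(ix, min(nv, length(ix) - 1L))
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_len(n), val_idx)

  take <- function(ix) {
    if (is.matrix(x)) x[ix, , drop = FALSE]
    else if (length(dim(x)) == 3L) x[ix, , , drop = FALSE]
    else x[ix, , , , drop = FALSE]
  }
  xtr <- take(tr_idx); ytr <- y[tr_idx]
  xva <- take(val_idx); yva <- y[val_idx]

  get_params <- function() flatten_params(lapply(layers, layer_params))
  put_params <- function(flat) {
    nested <- lapply(layers, layer_params)
    flat_names <- names(flatten_params(nested))
    stopifnot(identical(flat_names, names(flat)))
    pos <- 0L
    rebuild <- function(pl) {
      lapply(pl, function(p) {
        if (is.list(p)) rebuild(p)
        else { pos <<- pos + 1L; flat[[pos]] }
      })
    }
    nested2 <- rebuild(nested)
    for (i in seq_along(layers))
      layers[[i]] <<- set_layer_params(layers[[i]], nested2[[i]])
  }

  state <- optim_init(get_params(), method = optimizer, lr = lr)
  ntr <- length(tr_idx)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best <- list(val_loss = Inf, params = get_params(), epoch = 0L,
               bn = layers)
  wait <- 0L

  eval_split <- function(xs, ys) {
    if (!length(ys)) return(c(loss = NA_real_, acc = NA_real_))
    fw <- nn_forward(layers, xs, training = FALSE)
    ce <- cross_entropy(fw$out, ys, class_weights)
    pred <- max.col(fw$out, ties.method = "first")
    c(loss = ce$loss, acc = mean(pred == ys))
  }

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (s in starts) {
      ix <- ord[s:min(s + batch_size - 1L, ntr)]
      xb <- if (is.matrix(xtr)) xtr[ix, , drop = FALSE]
            else if (length(dim(xtr)) == 3L) xtr[ix, , , drop = FALSE]
            else xtr[ix, , , , drop = FALSE]
      yb <- ytr[ix]
      fw <- nn_forward(layers, xb, training = TRUE)
      layers <- fw$layers  # batch-norm running stats
      ce <- cross_entropy(fw$out, yb, class_weights)
      bk <- nn_backward(layers, fw$caches, ce$grad)
      gflat <- flatten_params(bk$grads)
      pflat <- get_params()
      st <- optim_step(state, pflat, gflat)
      state <- st$state
      put_params(st$params)
      ep_loss <- ep_loss + ce$loss * length(ix)
      ep_n <- ep_n + length(ix)
    }
    va <- eval_split(xva, yva)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n,
      val_loss = unname(va["loss"]), val_acc = unname(va["acc"])))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss / ep_n, va["loss"], va["acc"]))
    if (is.finite(va["loss"]) && va["loss"] < best$val_loss - 1e-6) {
      best <- list(val_loss = unname(va["loss"]), params = get_params(),
                   epoch = epoch, bn = layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  if (is.finite(best$val_loss)) {
    layers <- best$bn
    put_params(best$params)
  }
  list(layers = layers, history = history, best_epoch = best$epoch)
}
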