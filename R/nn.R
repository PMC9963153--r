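# Minimal 1D-CNN engine: conv1d (same padding) / batch normalization /
# dropout / dense layers with Adam, written against base matrix algebra.
# Activations flow as 3D arrays [batch, length, channels] until flattened.
# Everything is single-threaded and deterministic given the R RNG stream.

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_conv1d <- function(cin, cout, k = 7L) {
  list(type = "conv1d", cin = cin, cout = cout, k = k, pad = (k - 1L) %/% 2L,
       W = glorot_uniform(k * cin, k * cout, c(k * cin, cout)),
       b = numeric(cout), activation = "relu", trainable = TRUE)
}

layer_batchnorm <- function(c, eps = 1e-3, momentum = 0.99) {
  list(type = "batchnorm", gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c),
       eps = eps, momentum = momentum, trainable = TRUE)
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate, trainable = FALSE)

layer_flatten <- function() list(type = "flatten", trainable = FALSE)

layer_dense <- function(fin, fout, activation = "linear", l2 = 0) {
  list(type = "dense", W = glorot_uniform(fin, fout, c(fin, fout)),
       b = numeric(fout), activation = activation, l2 = l2, trainable = TRUE)
}

# im2col patches: x [N, L, C] -> [(N*L), (k*C)] with zero padding.
conv_patches <- function(x, k, pad) {
  d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
  xp <- array(0, c(N, L + 2L * pad, C))
  xp[, (pad + 1L):(pad + L), ] <- x
  P <- array(0, c(N, L, k * C))
  for (o in seq_len(k)) {
    P[, , ((o - 1L) * C + 1L):(o * C)] <- xp[, o:(o + L - 1L), , drop = FALSE]
  }
  dim(P) <- c(N * L, k * C)
  P
}

layer_forward <- function(layer, x, training) {
  cache <- NULL
  out <- switch(layer$type,
    conv1d = {
      d <- dim(x)
      P <- conv_patches(x, layer$k, layer$pad)
      Z <- sweep(P %*% layer$W, 2, layer$b, `+`)
      mask <- Z > 0
      Z[!mask] <- 0
      cache <- list(P = P, mask = mask, in_dim = d)
      dim(Z) <- c(d[1], d[2], layer$cout)
      Z
    },
    batchnorm = {
      d <- dim(x)
      C <- d[3]
      xm <- x; dim(xm) <- c(d[1] * d[2], C)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
      Z <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
      cache <- list(xhat = xhat, inv = inv, mu = mu, var = v, dims = d,
                    batch_mu = if (training) mu, batch_var = if (training) v)
      dim(Z) <- d
      Z
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (runif(length(x)) < keep) / keep
        cache <- list(mask = mask)
        x * array(mask, dim = dim(x) %||% length(x))
      } else x
    },
    flatten = {
      d <- dim(x)
      cache <- list(dims = d)
      dim(x) <- c(d[1], prod(d[-1]))
      x
    },
    dense = {
      Z <- sweep(x %*% layer$W, 2, layer$b, `+`)
      mask <- NULL
      if (layer$activation == "relu") {
        mask <- Z > 0
        Z[!mask] <- 0
      }
      cache <- list(x = x, mask = mask)
      Z
    }
  )
  list(out = out, cache = cache)
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv1d = {
      d <- cache$in_dim
      N <- d[1]; L <- d[2]; C <- d[3]
      dZ <- dout
      dim(dZ) <- c(N * L, layer$cout)
      dZ <- dZ * cache$mask
      dW <- crossprod(cache$P, dZ)
      db <- colSums(dZ)
      dP <- dZ %*% t(layer$W)
      dim(dP) <- c(N, L, layer$k * C)
      dxp <- array(0, c(N, L + 2L * layer$pad, C))
      for (o in seq_len(layer$k)) {
        blk <- dP[, , ((o - 1L) * C + 1L):(o * C), drop = FALSE]
        dim(blk) <- c(N, L, C)
        dxp[, o:(o + L - 1L), ] <- dxp[, o:(o + L - 1L), , drop = FALSE] + blk
      }
      dx <- dxp[, (layer$pad + 1L):(layer$pad + L), , drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = db))
    },
    batchnorm = {
      d <- cache$dims
      M <- d[1] * d[2]
      dZ <- dout; dim(dZ) <- c(M, length(layer$gamma))
      dgamma <- colSums(dZ * cache$xhat)
      dbeta <- colSums(dZ)
      dxhat <- sweep(dZ, 2, layer$gamma, `*`)
      # Compact batchnorm backward: dx = inv/M * (M*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dx <- sweep(M * dxhat, 2, s1) - sweep(cache$xhat, 2, s2, `*`)
      dx <- sweep(dx, 2, cache$inv / M, `*`)
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * array(cache$mask, dim = dim(dout) %||% length(dout)),
                grads = NULL)
    },
    flatten = {
      dim(dout) <- cache$dims
      list(dx = dout, grads = NULL)
    },
    dense = {
      dZ <- dout
      if (!is.null(cache$mask)) dZ <- dZ * cache$mask
      dW <- crossprod(cache$x, dZ) + 2 * layer$l2 * layer$W
      db <- colSums(dZ)
      list(dx = dZ %*% t(layer$W), grads = list(W = dW, b = db))
    }
  )
}

nn_forward <- function(layers, X, training = FALSE) {
  x <- array(X, dim = c(nrow(X), ncol(X), 1L))
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], x, training)
    x <- st$out
    caches[[i]] <- st$cache
  }
  list(out = as.numeric(x), caches = caches)
}

# Backpropagate d(loss)/d(output); returns per-layer gradient lists.
nn_backward <- function(layers, caches, dout_vec) {
  n <- length(layers)
  grads <- vector("list", n)
  dout <- matrix(dout_vec, ncol = 1L)
  for (i in rev(seq_len(n))) {
    st <- layer_backward(layers[[i]], dout, caches[[i]])
    grads[i] <- list(st$grads)  # plain [[<- would drop NULL entries
    dout <- st$dx
  }
  grads
}

# Re-estimate batchnorm population statistics from a full pass over the
# training set (dropout disabled). Done at each epoch end so inference-mode
# evaluation reflects the current weights instead of a lagging running
# average.
estimate_bn_stats <- function(layers, X) {
  tmp <- layers
  for (i in seq_along(tmp)) if (tmp[[i]]$type == "dropout") tmp[[i]]$rate <- 0
  fwd <- nn_forward(tmp, X, training = TRUE)
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "batchnorm") {
      layers[[i]]$running_mean <- fwd$caches[[i]]$batch_mu
      layers[[i]]$running_var <- fwd$caches[[i]]$batch_var
    }
  }
  layers
}

# Update batchnorm running statistics after a training-mode forward pass.
nn_update_running <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "batchnorm") {
      m <- layers[[i]]$momentum
      layers[[i]]$running_mean <- m * layers[[i]]$running_mean +
        (1 - m) * caches[[i]]$batch_mu
      layers[[i]]$running_var <- m * layers[[i]]$running_var +
        (1 - m) * caches[[i]]$batch_var
    }
  }
  layers
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!l$trainable) return(NULL)
    nms <- intersect(c("W", "b", "gamma", "beta"), names(l))
    stats::setNames(lapply(nms, function(nm) {
      list(m = array(0, dim = dim(l[[nm]]) %||% length(l[[nm]])),
           v = array(0, dim = dim(l[[nm]]) %||% length(l[[nm]])))
    }), nms)
  })
}

adam_step <- function(layers, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  lr_t <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(layers)) {
    if (!layers[[i]]$trainable || is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr_t * as.numeric(st$m) /
        (sqrt(as.numeric(st$v)) + eps)
      dim(layers[[i]][[nm]]) <- dim(g)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# One generic training loop shared by the regressor and the binary model.
# loss = "mse" (linear output) or "bce" (sigmoid applied to the output).
nn_train <- function(layers, X, y, X_val, y_val, loss, batch_size, epochs,
                     patience, lr) {
  state <- adam_init(layers)
  t <- 0L
  history <- list()
  n <- nrow(X)
  rises <- 0L
  prev_val <- Inf
  eval_loss <- function(lyr, Xe, ye) {
    pred <- nn_forward(lyr, Xe, training = FALSE)$out
    if (loss == "bce") {
      p <- pmin(pmax(sigmoid(pred), 1e-12), 1 - 1e-12)
      -mean(ye * log(p) + (1 - ye) * log(1 - p))
    } else mean((pred - ye)^2)
  }
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- nn_forward(layers, Xb, training = TRUE)
      layers <- nn_update_running(layers, fwd$caches)
      if (loss == "bce") {
        p <- pmin(pmax(sigmoid(fwd$out), 1e-12), 1 - 1e-12)
        lb <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        dout <- (p - yb) / length(yb)
      } else {
        lb <- mean((fwd$out - yb)^2)
        dout <- 2 * (fwd$out - yb) / length(yb)
      }
      grads <- nn_backward(layers, fwd$caches, dout)
      t <- t + 1L
      upd <- adam_step(layers, grads, state, t, lr)
      layers <- upd$layers
      state <- upd$state
      tr_loss <- tr_loss + lb
      nb <- nb + 1L
    }
    layers <- estimate_bn_stats(layers, X)
    val_loss <- if (length(y_val)) eval_loss(layers, X_val, y_val) else NA_real_
    history[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / nb,
                          val_loss = val_loss)
    if (is.finite(val_loss)) {
      rises <- if (val_loss > prev_val) rises + 1L else 0L
      prev_val <- val_loss
      if (!is.null(patience) && rises > patience) break
    }
  }
  list(layers = layers,
       history = tibble::as_tibble(do.call(rbind, history)))
}
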