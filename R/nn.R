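# Minimal 1D convolutional network engine. Activations are (channels,
# length, batch) arrays; convolutions are lowered to BLAS matrix products
# via im2col. Everything is deterministic given the caller's RNG state.
# Conventions: kernel size 3, stride 1, zero padding 1 (length-preserving);
# max-pooling kernel/stride 2.

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# ---- layer constructors ---------------------------------------------------

nn_conv <- function(c_in, c_out, init_sd = 0.02) {
  list(type = "conv", c_in = c_in, c_out = c_out,
       W = init_mat(c_out, 3L * c_in, init_sd), b = numeric(c_out))
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

nn_act <- function(kind = c("leaky_relu", "relu"), lambda = 0.01) {
  kind <- match.arg(kind)
  list(type = "act", lambda = if (kind == "relu") 0 else lambda)
}

nn_maxpool <- function() list(type = "maxpool")

nn_apool <- function(out = 2L) list(type = "apool", out = as.integer(out))

nn_flatten <- function() list(type = "flatten")

nn_fc <- function(d_in, d_out, init_sd = 0.02) {
  list(type = "fc", d_in = d_in, d_out = d_out,
       W = init_mat(d_out, d_in, init_sd), b = numeric(d_out))
}

# ---- forward / backward ---------------------------------------------------

layer_forward <- function(layer, X, training) {
  switch(layer$type,
    conv = {
      Y <- cpp_conv_forward(X, layer$W, layer$b)
      list(out = Y, cache = list(X = X), layer = layer)
    },
    bn = {
      d <- dim(X)
      Xm <- X; dim(Xm) <- c(d[1], d[2] * d[3])
      if (training) {
        mu <- rowMeans(Xm)
        v <- rowMeans(Xm * Xm) - mu * mu
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- (Xm - mu) * inv
      Y <- layer$gamma * xhat + layer$beta
      dim(Y) <- d
      list(out = Y, cache = list(xhat = xhat, inv = inv, d = d), layer = layer)
    },
    act = {
      mask <- X > 0
      Y <- X * (mask + layer$lambda * !mask)
      list(out = Y, cache = list(mask = mask), layer = layer)
    },
    maxpool = {
      d <- dim(X); L <- d[2]
      i1 <- seq(1L, L, by = 2L)
      A <- X[, i1, , drop = FALSE]
      B <- X[, i1 + 1L, , drop = FALSE]
      mask <- A >= B
      list(out = pmax(A, B), cache = list(mask = mask, d = d), layer = layer)
    },
    apool = {
      d <- dim(X); L <- d[2]; p <- L %/% layer$out
      Y <- array(0, c(d[1], layer$out, d[3]))
      for (k in seq_len(layer$out)) {
        acc <- matrix(0, d[1], d[3])
        for (j in seq_len(p)) acc <- acc + X[, (k - 1L) * p + j, ]
        Y[, k, ] <- acc / p
      }
      list(out = Y, cache = list(d = d, p = p), layer = layer)
    },
    flatten = {
      d <- dim(X)
      Y <- X; dim(Y) <- c(d[1] * d[2], d[3])
      list(out = Y, cache = list(d = d), layer = layer)
    },
    fc = {
      list(out = layer$W %*% X + layer$b, cache = list(X = X), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dY, cache) {
  switch(layer$type,
    conv = {
      bw <- cpp_conv_backward(cache$X, layer$W, dY)
      list(dX = bw$dX, grads = list(W = bw$dW, b = as.numeric(bw$db)))
    },
    bn = {
      d <- cache$d
      dYm <- dY; dim(dYm) <- c(d[1], d[2] * d[3])
      dgamma <- rowSums(dYm * cache$xhat)
      dbeta <- rowSums(dYm)
      dxhat <- dYm * layer$gamma
      dX <- cache$inv * (dxhat - rowMeans(dxhat) -
                           cache$xhat * rowMeans(dxhat * cache$xhat))
      dim(dX) <- d
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      list(dX = dY * (cache$mask + layer$lambda * !cache$mask), grads = NULL)
    },
    maxpool = {
      d <- cache$d
      dX <- array(0, d)
      i1 <- seq(1L, d[2], by = 2L)
      dX[, i1, ] <- dY * cache$mask
      dX[, i1 + 1L, ] <- dY * !cache$mask
      list(dX = dX, grads = NULL)
    },
    apool = {
      d <- cache$d; p <- cache$p
      dX <- array(0, d)
      nout <- d[2] %/% p
      for (k in seq_len(nout)) {
        g <- dY[, k, ] / p
        for (j in seq_len(p)) dX[, (k - 1L) * p + j, ] <- g
      }
      list(dX = dX, grads = NULL)
    },
    flatten = {
      dX <- dY; dim(dX) <- cache$d
      list(dX = dX, grads = NULL)
    },
    fc = {
      list(dX = crossprod(layer$W, dY),
           grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
    }
  )
}

net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], X, training)
    X <- st$out
    caches[[i]] <- st$cache
    layers[[i]] <- st$layer
  }
  list(out = X, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], dOut, caches[[i]])
    dOut <- st$dX
    grads[i] <- list(st$grads)  # keep NULL entries (parameter-free layers)
  }
  list(dX = dOut, grads = grads)
}

# ---- loss -----------------------------------------------------------------

# Softmax cross-entropy; returns mean loss, posteriors and dLoss/dlogits.
softmax_ce <- function(logits, labels) {
  N <- ncol(logits)
  mx <- apply(logits, 2, max)
  E <- exp(sweep(logits, 2, mx))
  P <- sweep(E, 2, colSums(E), "/")
  picked <- P[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dL <- P
  dL[cbind(labels, seq_len(N))] <- dL[cbind(labels, seq_len(N))] - 1
  list(loss = loss, posterior = P, dlogits = dL / N)
}

softmax_probs <- function(logits) {
  mx <- apply(logits, 2, max)
  E <- exp(sweep(logits, 2, mx))
  sweep(E, 2, colSums(E), "/")
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv", "fc")) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else if (l$type == "bn") {
      list(mg = l$gamma * 0, vg = l$gamma * 0,
           mb = l$beta * 0, vb = l$beta * 0)
    } else NULL
  })
}

adam_update1 <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_step <- function(layers, grads, state, lr, t) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    s <- state[[i]]
    if (l$type %in% c("conv", "fc")) {
      u <- adam_update1(l$W, g$W, s$mW, s$vW, lr, t)
      l$W <- u$p; s$mW <- u$m; s$vW <- u$v
      u <- adam_update1(l$b, g$b, s$mb, s$vb, lr, t)
      l$b <- u$p; s$mb <- u$m; s$vb <- u$v
    } else if (l$type == "bn") {
      u <- adam_update1(l$gamma, g$gamma, s$mg, s$vg, lr, t)
      l$gamma <- u$p; s$mg <- u$m; s$vg <- u$v
      u <- adam_update1(l$beta, g$beta, s$mb, s$vb, lr, t)
      l$beta <- u$p; s$mb <- u$m; s$vb <- u$v
    }
    layers[[i]] <- l
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# Learning-rate schedule: initial rate scaled by 0.1 every 10 epochs.
lr_at_epoch <- function(lr0, epoch) lr0 * 0.1^((epoch - 1) %/% 10)
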