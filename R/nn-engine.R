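# Compact sequence-model engine: batched forward/backward passes for the
# layer kinds the five TSS architectures need (1D convolution, max pooling,
# dropout, flatten, dense, LSTM / bidirectional LSTM), trained with Adam on
# binary cross-entropy. Batches are arrays of shape (batch, time, channels);
# dense layers operate on (batch, features) matrices. Gradients are verified
# against finite differences in the test suite.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

new_layer <- function(type, ...) {
  c(list(type = type), list(...))
}

# ---- parameter initialization --------------------------------------------

glorot <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_layer_params <- function(layer, in_shape) {
  # in_shape: c(T, C) for 3D inputs, c(NA, D) for matrix inputs
  switch(layer$type,
    conv1d = {
      C <- in_shape[2L]
      layer$params <- list(
        W = glorot(layer$width * C, layer$filters, layer$width * C, layer$filters),
        b = rep(0, layer$filters))
      layer$in_channels <- C
      layer
    },
    dense = {
      D <- in_shape[2L]
      layer$params <- list(W = glorot(D, layer$units, D, layer$units),
                           b = rep(0, layer$units))
      layer
    },
    lstm = {
      C <- in_shape[2L]
      H <- layer$units
      mk <- function() {
        b <- rep(0, 4L * H)
        b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
        # recurrent weights orthogonal per gate (preserves state norm over
        # long sequences and speeds up learning markedly vs uniform init)
        Wh <- do.call(cbind, lapply(1:4, function(g) {
          qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))
        }))
        list(Wx = glorot(C, 4L * H, C, 4L * H), Wh = Wh, b = b)
      }
      layer$params <- if (isTRUE(layer$bidirectional)) {
        fw <- mk(); bw <- mk()
        list(Wx = fw$Wx, Wh = fw$Wh, b = fw$b,
             Wx_r = bw$Wx, Wh_r = bw$Wh, b_r = bw$b)
      } else mk()
      layer
    },
    layer
  )
}

layer_out_shape <- function(layer, in_shape) {
  switch(layer$type,
    conv1d = c(in_shape[1L] - layer$width + 1L, layer$filters),
    maxpool = c(in_shape[1L] %/% layer$size, in_shape[2L]),
    dropout = in_shape,
    flatten = c(NA, in_shape[1L] * in_shape[2L]),
    dense = c(NA, layer$units),
    lstm = c(NA, layer$units * (1L + isTRUE(layer$bidirectional))),
    stop("unknown layer type: ", layer$type)
  )
}

# Initialize (or re-initialize) all weights of a model from a seed.
init_model_params <- function(model, seed) {
  set.seed(seed)
  shape <- c(model$input_length, 4L)
  for (i in seq_along(model$layers)) {
    model$layers[[i]] <- init_layer_params(model$layers[[i]], shape)
    shape <- layer_out_shape(model$layers[[i]], shape)
  }
  model$initialized <- TRUE
  model
}

# ---- per-layer forward/backward ------------------------------------------

conv1d_forward <- function(layer, X) {
  d <- dim(X); B <- d[1L]; T_ <- d[2L]; C <- d[3L]
  wd <- layer$width
  out_t <- T_ - wd + 1L
  if (out_t < 1L) stop("input too short for conv1d width ", wd, call. = FALSE)
  Xcol <- matrix(0, B * out_t, wd * C)
  for (w in seq_len(wd)) {
    Xcol[, ((w - 1L) * C + 1L):(w * C)] <-
      matrix(X[, w:(w + out_t - 1L), , drop = FALSE], B * out_t, C)
  }
  A <- Xcol %*% layer$params$W
  A <- A + rep(layer$params$b, each = nrow(A))
  Y2 <- pmax(A, 0)
  list(Y = array(Y2, c(B, out_t, layer$filters)),
       cache = list(Xcol = Xcol, mask = A > 0, B = B, T_ = T_, C = C,
                    out_t = out_t))
}

conv1d_backward <- function(layer, cache, dY) {
  ch <- cache
  dY2 <- matrix(dY, ch$B * ch$out_t, layer$filters) * ch$mask
  grads <- list(W = crossprod(ch$Xcol, dY2), b = colSums(dY2))
  dXcol <- tcrossprod(dY2, layer$params$W)
  dX <- array(0, c(ch$B, ch$T_, ch$C))
  for (w in seq_len(layer$width)) {
    cols <- ((w - 1L) * ch$C + 1L):(w * ch$C)
    dX[, w:(w + ch$out_t - 1L), ] <- dX[, w:(w + ch$out_t - 1L), , drop = FALSE] +
      array(dXcol[, cols], c(ch$B, ch$out_t, ch$C))
  }
  list(dX = dX, grads = grads)
}

maxpool_forward <- function(layer, X) {
  d <- dim(X); B <- d[1L]; T_ <- d[2L]; C <- d[3L]
  s <- layer$size
  out_t <- T_ %/% s
  if (out_t < 1L) stop("input too short for maxpool size ", s, call. = FALSE)
  X4 <- array(X[, seq_len(s * out_t), , drop = FALSE], c(B, s, out_t, C))
  Y <- array(X4[, 1L, , ], c(B, out_t, C))
  U <- array(1L, c(B, out_t, C))
  if (s > 1L) {
    for (u in 2L:s) {
      cmp <- array(X4[, u, , ], c(B, out_t, C))
      upd <- cmp > Y
      Y[upd] <- cmp[upd]
      U[upd] <- u
    }
  }
  list(Y = Y, cache = list(U = U, B = B, T_ = T_, C = C, out_t = out_t, s = s))
}

maxpool_backward <- function(layer, cache, dY) {
  ch <- cache
  dX4 <- array(0, c(ch$B, ch$s, ch$out_t, ch$C))
  for (u in seq_len(ch$s)) {
    m <- ch$U == u
    tmp <- array(0, c(ch$B, ch$out_t, ch$C))
    tmp[m] <- dY[m]
    dX4[, u, , ] <- tmp
  }
  dX <- array(0, c(ch$B, ch$T_, ch$C))
  dX[, seq_len(ch$s * ch$out_t), ] <- array(dX4, c(ch$B, ch$s * ch$out_t, ch$C))
  list(dX = dX, grads = NULL)
}

dropout_forward <- function(layer, X, train) {
  if (!train || layer$rate <= 0) {
    return(list(Y = X, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  mask <- array(stats::rbinom(length(X), 1L, keep) / keep,
                dim = if (is.null(dim(X))) length(X) else dim(X))
  list(Y = X * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, cache, dY) {
  if (is.null(cache$mask)) return(list(dX = dY, grads = NULL))
  list(dX = dY * cache$mask, grads = NULL)
}

flatten_forward <- function(layer, X) {
  d <- dim(X)
  list(Y = matrix(X, d[1L], d[2L] * d[3L]), cache = list(d = d))
}

flatten_backward <- function(layer, cache, dY) {
  list(dX = array(dY, cache$d), grads = NULL)
}

dense_forward <- function(layer, X) {
  A <- X %*% layer$params$W
  A <- A + rep(layer$params$b, each = nrow(A))
  Y <- switch(layer$activation,
              relu = pmax(A, 0),
              sigmoid = sigmoid_(A),
              linear = A)
  list(Y = Y, cache = list(X = X, A = A, Y = Y))
}

# `preact` signals that dY is already the gradient at the pre-activation
# (used for the final sigmoid layer combined with cross-entropy loss).
dense_backward <- function(layer, cache, dY, preact = FALSE) {
  dA <- if (preact) {
    dY
  } else {
    switch(layer$activation,
           relu = dY * (cache$A > 0),
           sigmoid = dY * cache$Y * (1 - cache$Y),
           linear = dY)
  }
  list(dX = tcrossprod(dA, layer$params$W),
       grads = list(W = crossprod(cache$X, dA), b = colSums(dA)))
}

# Single-direction LSTM over (B, T, C); returns the final hidden state.
lstm_dir_forward <- function(X, Wx, Wh, b) {
  d <- dim(X); B <- d[1L]; T_ <- d[2L]; C <- d[3L]
  H <- ncol(Wh) / 4L
  Xm <- matrix(X, B * T_, C)
  XW <- Xm %*% Wx
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  I <- array(0, c(B, H, T_)); Fg <- I; G <- I; O <- I; Cs <- I; Hs <- I
  i1 <- 1L:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H); i4 <- (3L * H + 1L):(4L * H)
  for (t in seq_len(T_)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    A <- XW[rows, , drop = FALSE] + h %*% Wh
    A <- A + rep(b, each = B)
    i_g <- sigmoid_(A[, i1, drop = FALSE])
    f_g <- sigmoid_(A[, i2, drop = FALSE])
    g_g <- tanh(A[, i3, drop = FALSE])
    o_g <- sigmoid_(A[, i4, drop = FALSE])
    cc <- f_g * cc + i_g * g_g
    h <- o_g * tanh(cc)
    I[, , t] <- i_g; Fg[, , t] <- f_g; G[, , t] <- g_g; O[, , t] <- o_g
    Cs[, , t] <- cc; Hs[, , t] <- h
  }
  list(h = h, cache = list(Xm = Xm, I = I, Fg = Fg, G = G, O = O, Cs = Cs,
                           Hs = Hs, B = B, T_ = T_, C = C, H = H))
}

lstm_dir_backward <- function(cache, Wx, Wh, dh) {
  ch <- cache
  B <- ch$B; T_ <- ch$T_; H <- ch$H
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, H, 4L * H)
  db <- rep(0, 4L * H)
  dXm <- matrix(0, B * T_, ch$C)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    i_g <- matrix(ch$I[, , t], B, H); f_g <- matrix(ch$Fg[, , t], B, H)
    g_g <- matrix(ch$G[, , t], B, H); o_g <- matrix(ch$O[, , t], B, H)
    c_t <- matrix(ch$Cs[, , t], B, H)
    c_prev <- if (t > 1L) matrix(ch$Cs[, , t - 1L], B, H) else matrix(0, B, H)
    h_prev <- if (t > 1L) matrix(ch$Hs[, , t - 1L], B, H) else matrix(0, B, H)
    tc <- tanh(c_t)
    do_ <- dh * tc
    dc <- dc + dh * o_g * (1 - tc^2)
    di <- dc * g_g
    dg <- dc * i_g
    df <- dc * c_prev
    dA <- cbind(di * i_g * (1 - i_g),
                df * f_g * (1 - f_g),
                dg * (1 - g_g^2),
                do_ * o_g * (1 - o_g))
    rows <- ((t - 1L) * B + 1L):(t * B)
    dWh <- dWh + crossprod(h_prev, dA)
    dWx <- dWx + crossprod(ch$Xm[rows, , drop = FALSE], dA)
    db <- db + colSums(dA)
    dXm[rows, ] <- tcrossprod(dA, Wx)
    dh <- tcrossprod(dA, Wh)
    dc <- dc * f_g
  }
  list(dWx = dWx, dWh = dWh, db = db,
       dX = array(dXm, c(B, T_, ch$C)))
}

lstm_forward <- function(layer, X) {
  fw <- lstm_dir_forward(X, layer$params$Wx, layer$params$Wh, layer$params$b)
  if (!isTRUE(layer$bidirectional)) {
    return(list(Y = fw$h, cache = list(fw = fw$cache)))
  }
  Xr <- X[, rev(seq_len(dim(X)[2L])), , drop = FALSE]
  bw <- lstm_dir_forward(Xr, layer$params$Wx_r, layer$params$Wh_r, layer$params$b_r)
  list(Y = cbind(fw$h, bw$h), cache = list(fw = fw$cache, bw = bw$cache))
}

lstm_backward <- function(layer, cache, dY) {
  H <- layer$units
  if (!isTRUE(layer$bidirectional)) {
    r <- lstm_dir_backward(cache$fw, layer$params$Wx, layer$params$Wh, dY)
    return(list(dX = r$dX, grads = list(Wx = r$dWx, Wh = r$dWh, b = r$db)))
  }
  rf <- lstm_dir_backward(cache$fw, layer$params$Wx, layer$params$Wh,
                          dY[, seq_len(H), drop = FALSE])
  rb <- lstm_dir_backward(cache$bw, layer$params$Wx_r, layer$params$Wh_r,
                          dY[, (H + 1L):(2L * H), drop = FALSE])
  dX <- rf$dX + rb$dX[, rev(seq_len(dim(rb$dX)[2L])), , drop = FALSE]
  list(dX = dX,
       grads = list(Wx = rf$dWx, Wh = rf$dWh, b = rf$db,
                    Wx_r = rb$dWx, Wh_r = rb$dWh, b_r = rb$db))
}

# ---- whole-model forward/backward ----------------------------------------

nn_forward <- function(model, X, train = FALSE) {
  caches <- vector("list", length(model$layers))
  cur <- X
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    res <- switch(ly$type,
      conv1d = conv1d_forward(ly, cur),
      maxpool = maxpool_forward(ly, cur),
      dropout = dropout_forward(ly, cur, train),
      flatten = flatten_forward(ly, cur),
      dense = dense_forward(ly, cur),
      lstm = lstm_forward(ly, cur))
    cur <- res$Y
    caches[[i]] <- res$cache
  }
  list(p = as.numeric(cur), caches = caches)
}

# dZ_out: gradient at the final dense layer's pre-activation, (B, 1).
nn_backward <- function(model, caches, dZ_out) {
  n <- length(model$layers)
  grads <- vector("list", n)
  d <- dZ_out
  for (i in rev(seq_len(n))) {
    ly <- model$layers[[i]]
    res <- switch(ly$type,
      conv1d = conv1d_backward(ly, caches[[i]], d),
      maxpool = maxpool_backward(ly, caches[[i]], d),
      dropout = dropout_backward(ly, caches[[i]], d),
      flatten = flatten_backward(ly, caches[[i]], d),
      dense = dense_backward(ly, caches[[i]], d, preact = (i == n)),
      lstm = lstm_backward(ly, caches[[i]], d))
    d <- res$dX
    grads[i] <- list(res$grads)  # [[<- would drop the element when NULL
  }
  grads
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (is.null(ly$params)) return(NULL)
    list(m = lapply(ly$params, function(p) p * 0),
         v = lapply(ly$params, function(p) p * 0))
  })
}

adam_step <- function(model, state, grads, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state[[i]]$m[[nm]] <- beta1 * state[[i]]$m[[nm]] + (1 - beta1) * g[[nm]]
      state[[i]]$v[[nm]] <- beta2 * state[[i]]$v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- state[[i]]$m[[nm]] / (1 - beta1^step)
      vhat <- state[[i]]$v[[nm]] / (1 - beta2^step)
      model$layers[[i]]$params[[nm]] <-
        model$layers[[i]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, state = state)
}

# Forward in evaluation mode over mini-batches (bounds peak memory for the
# recurrent layers, whose caches grow with batch x time).
nn_predict <- function(model, X, batch_size = 128L) {
  n <- dim(X)[1L]
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    out[s:e] <- nn_forward(model, X[s:e, , , drop = FALSE], train = FALSE)$p
  }
  out
}
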