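# Recurrent layers (plain tanh RNN and LSTM) with pad-mask handling and
# full backpropagation through time. At padded timesteps the hidden (and
# cell) state is frozen, so after the last timestep each sequence's state
# equals its state at its final real keyframe.

sigmoid <- function(x) 1 / (1 + exp(-x))

init_rnn_params <- function(input_dim, layers, n_classes) {
  params <- list()
  din <- input_dim
  for (l in seq_along(layers)) {
    h <- layers[l]
    params[[sprintf("l%d.Wx", l)]] <- glorot(din, h)
    params[[sprintf("l%d.Wh", l)]] <- glorot(h, h)
    params[[sprintf("l%d.b", l)]] <- numeric(h)
    din <- h
  }
  params[["out.W"]] <- glorot(din, n_classes)
  params[["out.b"]] <- numeric(n_classes)
  params
}

init_lstm_params <- function(input_dim, layers, n_classes) {
  params <- list()
  din <- input_dim
  for (l in seq_along(layers)) {
    h <- layers[l]
    params[[sprintf("l%d.Wx", l)]] <- glorot(din, 4 * h)
    params[[sprintf("l%d.Wh", l)]] <- glorot(h, 4 * h)
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1   # forget-gate bias starts open
    params[[sprintf("l%d.b", l)]] <- b
    din <- h
  }
  params[["out.W"]] <- glorot(din, n_classes)
  params[["out.b"]] <- numeric(n_classes)
  params
}

rnn_forward <- function(params, x, mask, layers) {
  b <- dim(x)[1]; tt <- dim(x)[2]
  inp <- x
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    hdim <- layers[l]
    Wx <- params[[sprintf("l%d.Wx", l)]]
    Wh <- params[[sprintf("l%d.Wh", l)]]
    bb <- params[[sprintf("l%d.b", l)]]
    H <- array(0, c(b, tt, hdim))
    Hc <- array(0, c(b, tt, hdim))
    h <- matrix(0, b, hdim)
    for (t in seq_len(tt)) {
      xt <- matrix(inp[, t, ], b)
      hc <- tanh(sweep(xt %*% Wx + h %*% Wh, 2, bb, `+`))
      m <- mask[, t]
      h <- hc * m + h * (1 - m)
      Hc[, t, ] <- hc
      H[, t, ] <- h
    }
    caches[[l]] <- list(H = H, Hc = Hc, inp = inp)
    inp <- H
  }
  list(h_final = matrix(inp[, tt, ], b), caches = caches)
}

rnn_backward <- function(params, fwd, dh_final, mask, layers) {
  b <- nrow(dh_final); tt <- dim(mask)[2]
  grads <- zeros_like(params)
  # external per-timestep gradient flowing into the top layer: only the
  # last timestep receives the loss gradient
  dH_ext <- array(0, c(b, tt, layers[length(layers)]))
  dH_ext[, tt, ] <- dh_final
  for (l in rev(seq_along(layers))) {
    cache <- fwd$caches[[l]]
    Wx <- params[[sprintf("l%d.Wx", l)]]
    Wh <- params[[sprintf("l%d.Wh", l)]]
    din <- ncol(Wx)
    dX <- array(0, dim(cache$inp))
    dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh))
    db <- numeric(length(params[[sprintf("l%d.b", l)]]))
    dh_run <- matrix(0, b, layers[l])
    for (t in rev(seq_len(tt))) {
      m <- mask[, t]
      dh_total <- matrix(dH_ext[, t, ], b) + dh_run
      hc <- matrix(cache$Hc[, t, ], b)
      da <- (dh_total * m) * (1 - hc^2)
      xt <- matrix(cache$inp[, t, ], b)
      h_prev <- if (t > 1) matrix(cache$H[, t - 1, ], b)
                else matrix(0, b, layers[l])
      dWx <- dWx + crossprod(xt, da)
      dWh <- dWh + crossprod(h_prev, da)
      db <- db + colSums(da)
      dX[, t, ] <- da %*% t(Wx)
      dh_run <- dh_total * (1 - m) + da %*% t(Wh)
    }
    grads[[sprintf("l%d.Wx", l)]] <- dWx
    grads[[sprintf("l%d.Wh", l)]] <- dWh
    grads[[sprintf("l%d.b", l)]] <- db
    dH_ext <- dX
  }
  grads
}

lstm_forward <- function(params, x, mask, layers) {
  b <- dim(x)[1]; tt <- dim(x)[2]
  inp <- x
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    hdim <- layers[l]
    Wx <- params[[sprintf("l%d.Wx", l)]]
    Wh <- params[[sprintf("l%d.Wh", l)]]
    bb <- params[[sprintf("l%d.b", l)]]
    ii <- seq_len(hdim); ff <- hdim + ii; gg <- 2 * hdim + ii
    oo <- 3 * hdim + ii
    H <- array(0, c(b, tt, hdim)); C <- array(0, c(b, tt, hdim))
    I <- array(0, c(b, tt, hdim)); Fg <- array(0, c(b, tt, hdim))
    G <- array(0, c(b, tt, hdim)); O <- array(0, c(b, tt, hdim))
    Cc <- array(0, c(b, tt, hdim))
    h <- matrix(0, b, hdim); cs <- matrix(0, b, hdim)
    for (t in seq_len(tt)) {
      xt <- matrix(inp[, t, ], b)
      z <- sweep(xt %*% Wx + h %*% Wh, 2, bb, `+`)
      ig <- sigmoid(z[, ii, drop = FALSE])
      fg <- sigmoid(z[, ff, drop = FALSE])
      gg_ <- tanh(z[, gg, drop = FALSE])
      og <- sigmoid(z[, oo, drop = FALSE])
      c_cand <- fg * cs + ig * gg_
      h_cand <- og * tanh(c_cand)
      m <- mask[, t]
      cs <- c_cand * m + cs * (1 - m)
      h <- h_cand * m + h * (1 - m)
      I[, t, ] <- ig; Fg[, t, ] <- fg; G[, t, ] <- gg_; O[, t, ] <- og
      Cc[, t, ] <- c_cand; C[, t, ] <- cs; H[, t, ] <- h
    }
    caches[[l]] <- list(H = H, C = C, I = I, Fg = Fg, G = G, O = O,
                        Cc = Cc, inp = inp)
    inp <- H
  }
  list(h_final = matrix(inp[, tt, ], b), caches = caches)
}

lstm_backward <- function(params, fwd, dh_final, mask, layers) {
  b <- nrow(dh_final); tt <- dim(mask)[2]
  grads <- zeros_like(params)
  dH_ext <- array(0, c(b, tt, layers[length(layers)]))
  dH_ext[, tt, ] <- dh_final
  for (l in rev(seq_along(layers))) {
    cache <- fwd$caches[[l]]
    hdim <- layers[l]
    Wx <- params[[sprintf("l%d.Wx", l)]]
    Wh <- params[[sprintf("l%d.Wh", l)]]
    dX <- array(0, dim(cache$inp))
    dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh))
    db <- numeric(4 * hdim)
    dh_run <- matrix(0, b, hdim)
    dc_run <- matrix(0, b, hdim)
    for (t in rev(seq_len(tt))) {
      m <- mask[, t]
      dh_total <- matrix(dH_ext[, t, ], b) + dh_run
      dh_cand <- dh_total * m
      ig <- matrix(cache$I[, t, ], b); fg <- matrix(cache$Fg[, t, ], b)
      gg_ <- matrix(cache$G[, t, ], b); og <- matrix(cache$O[, t, ], b)
      c_cand <- matrix(cache$Cc[, t, ], b)
      c_prev <- if (t > 1) matrix(cache$C[, t - 1, ], b)
                else matrix(0, b, hdim)
      tc <- tanh(c_cand)
      do_ <- dh_cand * tc
      dc_cand <- dh_cand * og * (1 - tc^2) + dc_run * m
      di <- dc_cand * gg_
      df <- dc_cand * c_prev
      dg <- dc_cand * ig
      dz <- cbind(
        di * ig * (1 - ig),
        df * fg * (1 - fg),
        dg * (1 - gg_^2),
        do_ * og * (1 - og)
      )
      xt <- matrix(cache$inp[, t, ], b)
      h_prev <- if (t > 1) matrix(cache$H[, t - 1, ], b)
                else matrix(0, b, hdim)
      dWx <- dWx + crossprod(xt, dz)
      dWh <- dWh + crossprod(h_prev, dz)
      db <- db + colSums(dz)
      dX[, t, ] <- dz %*% t(Wx)
      dh_run <- dh_total * (1 - m) + dz %*% t(Wh)
      dc_run <- dc_cand * fg + dc_run * (1 - m)
    }
    grads[[sprintf("l%d.Wx", l)]] <- dWx
    grads[[sprintf("l%d.Wh", l)]] <- dWh
    grads[[sprintf("l%d.b", l)]] <- db
    dH_ext <- dX
  }
  grads
}
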