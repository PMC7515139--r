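# 2D convolutional network on the (keyframes x features) matrix, treated
# as a single-channel image: 3x3 same-padding convolutions, ReLU, 2x2 max
# pooling (ceil mode) after each convolution, then dense layers. Padded
# keyframe rows enter as zeros.

init_cnn_params <- function(input_shape, conv_channels, dense_units,
                            n_classes) {
  params <- list()
  cin <- 1L
  h <- input_shape[1]; w <- input_shape[2]
  for (l in seq_along(conv_channels)) {
    cout <- conv_channels[l]
    params[[sprintf("c%d.W", l)]] <-
      array(stats::runif(9 * cin * cout,
                         -sqrt(6 / (9 * cin + 9 * cout)),
                         sqrt(6 / (9 * cin + 9 * cout))),
            c(3, 3, cin, cout))
    params[[sprintf("c%d.b", l)]] <- numeric(cout)
    cin <- cout
    h <- ceiling(h / 2); w <- ceiling(w / 2)
  }
  flat <- h * w * cin
  params[["d1.W"]] <- glorot(flat, dense_units)
  params[["d1.b"]] <- numeric(dense_units)
  params[["out.W"]] <- glorot(dense_units, n_classes)
  params[["out.b"]] <- numeric(n_classes)
  params
}

# x: [b, h, w, cin]; W: [3, 3, cin, cout] -> [b, h, w, cout] (same padding)
conv2d_forward <- function(x, W, b) {
  d <- dim(x); bn <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  cout <- dim(W)[4]
  xp <- array(0, c(bn, h + 2, w + 2, cin))
  xp[, 2:(h + 1), 2:(w + 1), ] <- x
  out <- array(rep(b, each = bn * h * w), c(bn, h, w, cout))
  for (ki in 1:3) {
    for (kj in 1:3) {
      slab <- xp[, ki:(ki + h - 1), kj:(kj + w - 1), , drop = FALSE]
      out <- out + array(
        matrix(slab, ncol = cin) %*% matrix(W[ki, kj, , ], cin, cout),
        c(bn, h, w, cout))
    }
  }
  out
}

conv2d_backward <- function(x, W, dout) {
  d <- dim(x); bn <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  cout <- dim(W)[4]
  xp <- array(0, c(bn, h + 2, w + 2, cin))
  xp[, 2:(h + 1), 2:(w + 1), ] <- x
  dxp <- array(0, c(bn, h + 2, w + 2, cin))
  dW <- array(0, dim(W))
  dout_mat <- matrix(dout, ncol = cout)
  for (ki in 1:3) {
    for (kj in 1:3) {
      slab <- matrix(xp[, ki:(ki + h - 1), kj:(kj + w - 1), , drop = FALSE],
                     ncol = cin)
      dW[ki, kj, , ] <- crossprod(slab, dout_mat)
      dslab <- dout_mat %*% t(matrix(W[ki, kj, , ], cin, cout))
      dxp[, ki:(ki + h - 1), kj:(kj + w - 1), ] <-
        dxp[, ki:(ki + h - 1), kj:(kj + w - 1), , drop = FALSE] +
        array(dslab, c(bn, h, w, cin))
    }
  }
  db <- colSums(dout_mat)
  list(dx = dxp[, 2:(h + 1), 2:(w + 1), , drop = FALSE], dW = dW, db = db)
}

# 2x2 max pooling, ceil mode: odd trailing rows/cols padded with -Inf
maxpool_forward <- function(x) {
  d <- dim(x); bn <- d[1]; h <- d[2]; w <- d[3]; ch <- d[4]
  hp <- 2 * ceiling(h / 2); wp <- 2 * ceiling(w / 2)
  xp <- array(-Inf, c(bn, hp, wp, ch))
  xp[, 1:h, 1:w, ] <- x
  ho <- hp / 2; wo <- wp / 2
  cand <- list(
    xp[, seq(1, hp, 2), seq(1, wp, 2), , drop = FALSE],
    xp[, seq(2, hp, 2), seq(1, wp, 2), , drop = FALSE],
    xp[, seq(1, hp, 2), seq(2, wp, 2), , drop = FALSE],
    xp[, seq(2, hp, 2), seq(2, wp, 2), , drop = FALSE]
  )
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  # winner mask per candidate (first winner takes the gradient on ties)
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4)
  for (q in 1:4) {
    m <- (cand[[q]] == out) & !taken
    taken <- taken | m
    masks[[q]] <- m
  }
  list(out = out, masks = masks, in_dim = d, pad_dim = c(bn, hp, wp, ch))
}

maxpool_backward <- function(cache, dout) {
  d <- cache$in_dim
  dxp <- array(0, cache$pad_dim)
  hp <- cache$pad_dim[2]; wp <- cache$pad_dim[3]
  offs <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (q in 1:4) {
    g <- dout * cache$masks[[q]]
    dxp[, seq(offs[[q]][1], hp, 2), seq(offs[[q]][2], wp, 2), ] <-
      dxp[, seq(offs[[q]][1], hp, 2), seq(offs[[q]][2], wp, 2),
          , drop = FALSE] + g
  }
  dxp[, 1:d[2], 1:d[3], , drop = FALSE]
}

cnn_forward <- function(params, x, conv_channels) {
  bn <- dim(x)[1]
  a <- array(x, c(dim(x), 1L))
  cache <- list(conv = vector("list", length(conv_channels)))
  for (l in seq_along(conv_channels)) {
    W <- params[[sprintf("c%d.W", l)]]
    z <- conv2d_forward(a, W, params[[sprintf("c%d.b", l)]])
    r <- pmax(z, 0)
    pool <- maxpool_forward(r)
    cache$conv[[l]] <- list(a_in = a, z = z, pool = pool)
    a <- pool$out
  }
  flat <- matrix(a, bn)
  z1 <- sweep(flat %*% params[["d1.W"]], 2, params[["d1.b"]], `+`)
  r1 <- pmax(z1, 0)
  cache$flat <- flat; cache$z1 <- z1; cache$r1 <- r1
  cache$conv_out_dim <- dim(a)
  list(h_final = r1, cache = cache)
}

cnn_backward <- function(params, fwd, dr1, x, conv_channels) {
  cache <- fwd$cache
  grads <- zeros_like(params)
  dz1 <- dr1 * (cache$z1 > 0)
  grads[["d1.W"]] <- crossprod(cache$flat, dz1)
  grads[["d1.b"]] <- colSums(dz1)
  da <- array(dz1 %*% t(params[["d1.W"]]), cache$conv_out_dim)
  for (l in rev(seq_along(conv_channels))) {
    cc <- cache$conv[[l]]
    dr <- maxpool_backward(cc$pool, da)
    dz <- dr * (cc$z > 0)
    cb <- conv2d_backward(cc$a_in, params[[sprintf("c%d.W", l)]], dz)
    grads[[sprintf("c%d.W", l)]] <- cb$dW
    grads[[sprintf("c%d.b", l)]] <- cb$db
    da <- cb$dx
  }
  grads
}
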