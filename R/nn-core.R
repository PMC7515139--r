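# Shared neural-network machinery: initialisation, softmax cross-entropy,
# ADAM updates, gradient clipping. Parameters and gradients travel as flat
# named lists of numeric arrays.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and the softmax-input gradient for integer labels
softmax_xent <- function(logits, y_int) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y_int)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# rescale all gradients jointly so their global L2 norm is <= max_norm
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

zeros_like <- function(params) {
  lapply(params, function(p) array(0, dim(p) %||% length(p)))
}
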