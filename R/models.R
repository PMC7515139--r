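# Model specification, construction, training (ADAM + early stopping),
# and prediction for the three sequence classifiers.

#' Specify a sequence classifier
#'
#' Defaults follow the best-performing architectures found for this task:
#' CNN with three 3x3 convolution layers of 250, 250 and 100 channels
#' (each followed by 2x2 max pooling) and a dense layer of 100 units;
#' plain RNN with recurrent layers of 300, 150, 100 tanh units; LSTM with
#' layers of 250, 300, 300 units. All end in a dense softmax output layer
#' of `n_classes` units.
#'
#' @param kind `"cnn"`, `"rnn"` or `"lstm"`.
#' @param layers integer vector of layer widths (conv channels for the
#'   CNN, recurrent units otherwise); NULL uses the defaults above.
#' @param n_classes 7, 6 or 4.
#' @param input_shape `c(max_keyframes, features)`.
#' @param dense_units width of the CNN dense layer (ignored for
#'   recurrent kinds).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("cnn", "rnn", "lstm"), layers = NULL,
                       n_classes = 7, input_shape, dense_units = 100) {
  kind <- match.arg(kind)
  if (is.null(layers)) {
    layers <- switch(kind,
      cnn = c(250, 250, 100),
      rnn = c(300, 150, 100),
      lstm = c(250, 300, 300)
    )
  }
  if (!n_classes %in% c(7, 6, 4)) {
    stop("`n_classes` must be 7, 6 or 4", call. = FALSE)
  }
  if (missing(input_shape) || length(input_shape) != 2 ||
      any(input_shape < 1)) {
    stop("`input_shape` must be c(max_keyframes, features)", call. = FALSE)
  }
  structure(
    list(kind = kind, layers = as.integer(layers),
         n_classes = as.integer(n_classes),
         input_shape = as.integer(input_shape),
         dense_units = as.integer(dense_units)),
    class = "model_spec"
  )
}

#' Build a trainable classifier from a specification
#'
#' Initialises weights (Glorot-uniform) and returns an untrained model.
#' Pass `seed` for reproducible initialisation.
#'
#' @param spec a `model_spec`.
#' @param seed optional integer seed for the weight initialisation.
#' @return object of class `affmotion_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  init <- function() {
    switch(spec$kind,
      rnn = init_rnn_params(spec$input_shape[2], spec$layers,
                            spec$n_classes),
      lstm = init_lstm_params(spec$input_shape[2], spec$layers,
                              spec$n_classes),
      cnn = init_cnn_params(spec$input_shape, spec$layers,
                            spec$dense_units, spec$n_classes)
    )
  }
  params <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(list(spec = spec, params = params, history = numeric(0),
                 trained = FALSE),
            class = "affmotion_model")
}

#' @export
print.affmotion_model <- function(x, ...) {
  cat(sprintf("<affmotion_model %s [%s] -> %d classes, %strained>\n",
              x$spec$kind, paste(x$spec$layers, collapse = ", "),
              x$spec$n_classes, if (x$trained) "" else "un"))
  invisible(x)
}

model_forward <- function(model, x, mask) {
  spec <- model$spec
  if (!identical(dim(x)[2:3], as.integer(spec$input_shape))) {
    stop("input shape ", paste(dim(x)[2:3], collapse = "x"),
         " does not match the model's expected ",
         paste(spec$input_shape, collapse = "x"), call. = FALSE)
  }
  mask_num <- if (is.logical(mask)) mask + 0 else mask
  fwd <- switch(spec$kind,
    rnn = rnn_forward(model$params, x, mask_num, spec$layers),
    lstm = lstm_forward(model$params, x, mask_num, spec$layers),
    cnn = cnn_forward(model$params, x, spec$layers)
  )
  fwd$logits <- sweep(fwd$h_final %*% model$params[["out.W"]], 2,
                      model$params[["out.b"]], `+`)
  fwd
}

model_backward <- function(model, fwd, dlogits, x, mask) {
  spec <- model$spec
  mask_num <- if (is.logical(mask)) mask + 0 else mask
  dh <- dlogits %*% t(model$params[["out.W"]])
  grads <- switch(spec$kind,
    rnn = rnn_backward(model$params, fwd, dh, mask_num, spec$layers),
    lstm = lstm_backward(model$params, fwd, dh, mask_num, spec$layers),
    cnn = cnn_backward(model$params, fwd, dh, x, spec$layers)
  )
  grads[["out.W"]] <- crossprod(fwd$h_final, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  grads
}

#' Class probabilities for a batch of padded feature matrices
#'
#' @param model an `affmotion_model`.
#' @param x array `[n, max_keyframes, features]`.
#' @param mask logical `[n, max_keyframes]` pad mask (all-true if NULL).
#' @return matrix `[n, n_classes]` of probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, x, mask = NULL) {
  if (length(dim(x)) == 2) x <- array(x, c(1L, dim(x)))
  if (is.null(mask)) mask <- matrix(TRUE, dim(x)[1], dim(x)[2])
  if (is.null(dim(mask))) mask <- matrix(mask, nrow = dim(x)[1])
  softmax_rows(model_forward(model, x, mask)$logits)
}

#' Training configuration
#'
#' ADAM with cross-entropy loss; training runs for at most `max_epochs`
#' epochs and stops early once the (training) loss has not improved by at
#' least `min_delta` for more than `patience` consecutive epochs.
#'
#' @param max_epochs epoch cap (default 500).
#' @param patience early-stop patience in epochs (default 30; must be
#'   smaller than `max_epochs`).
#' @param lr ADAM learning rate.
#' @param batch_size minibatch size.
#' @param seed integer RNG seed; training is deterministic given it.
#' @param min_delta minimum loss improvement counted as progress.
#' @param clip_norm global gradient-norm clip (recurrent stability).
#' @return list of class `train_config`.
#' @export
train_config <- function(max_epochs = 500, patience = 30, lr = 1e-3,
                         batch_size = 32, seed = 1, min_delta = 1e-4,
                         clip_norm = 5) {
  if (patience >= max_epochs) {
    stop("`patience` must be smaller than `max_epochs`", call. = FALSE)
  }
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), min_delta = min_delta,
                 clip_norm = clip_norm),
            class = "train_config")
}

#' Train a classifier
#'
#' Minibatch ADAM on softmax cross-entropy. Deterministic given
#' `config$seed` (weight re-initialisation is not performed here; seed
#' [build_model()] for fully reproducible runs).
#'
#' @param model an `affmotion_model`.
#' @param x array `[n, max_keyframes, features]` of padded, z-scored
#'   feature matrices.
#' @param y labels: factor or character (converted against
#'   [emotion_levels()] of the model's class count) or integer class ids.
#' @param mask logical pad mask `[n, max_keyframes]`.
#' @param config a [train_config()].
#' @return the trained model; `$history` holds the per-epoch mean loss.
#' @export
train <- function(model, x, y, mask = NULL, config = train_config()) {
  stopifnot(inherits(model, "affmotion_model"))
  n <- dim(x)[1]
  if (is.null(n) || n == 0) stop("empty training set", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, n, dim(x)[2])
  y_int <- encode_labels(y, model$spec$n_classes)
  if (length(y_int) != n) stop("length(y) != nrow(x)", call. = FALSE)
  state <- adam_init(model$params)
  history <- numeric(0)
  best <- Inf
  stall <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- x[idx, , , drop = FALSE]
        mb <- mask[idx, , drop = FALSE]
        fwd <- model_forward(model, xb, mb)
        sx <- softmax_xent(fwd$logits, y_int[idx])
        grads <- model_backward(model, fwd, sx$dlogits, xb, mb)
        grads <- clip_gradients(grads, config$clip_norm)
        upd <- adam_step(model$params, grads, state, lr = config$lr)
        model$params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + sx$loss * length(idx)
      }
      epoch_loss <- epoch_loss / n
      history <- c(history, epoch_loss)
      if (epoch_loss < best - config$min_delta) {
        best <- epoch_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > config$patience) break
      }
    }
  })
  model$history <- history
  model$trained <- TRUE
  model
}

# map labels to 1..n_classes against the canonical emotion order
encode_labels <- function(y, n_classes) {
  lv <- emotion_levels(n_classes)
  if (is.numeric(y)) {
    y_int <- as.integer(y)
    if (any(y_int < 1 | y_int > n_classes)) {
      stop("integer labels out of range 1..", n_classes, call. = FALSE)
    }
    return(y_int)
  }
  y_int <- match(as.character(y), lv)
  if (anyNA(y_int)) {
    stop("labels outside emotion_levels(", n_classes, "): ",
         paste(unique(as.character(y)[is.na(y_int)]), collapse = ", "),
         call. = FALSE)
  }
  y_int
}
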