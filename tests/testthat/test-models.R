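# tiny dataset helpers for classifier tests ------------------------------

toy_batch <- function(n = 6, tt = 5, d = 4, n_classes = 4, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(n * tt * d), c(n, tt, d))
  mask <- matrix(TRUE, n, tt)
  lens <- sample(2:tt, n, replace = TRUE)
  for (i in seq_len(n)) mask[i, ] <- seq_len(tt) <= lens[i]
  x[array(rep(!mask, d), c(n, tt, d))] <- 0
  y <- sample(n_classes, n, replace = TRUE)
  list(x = x, mask = mask, y = y)
}

# two well-separated classes whose signal is the sequence mean
separable_set <- function(n = 40, tt = 6, d = 2, seed = 3) {
  set.seed(seed)
  y <- rep(1:2, length.out = n)
  x <- array(rnorm(n * tt * d, sd = 0.2), c(n, tt, d))
  x[, , 1] <- x[, , 1] + ifelse(y == 1, 1.5, -1.5)
  list(x = x, mask = matrix(TRUE, n, tt), y = y)
}

test_that("analytic gradients match numeric gradients (RNN, LSTM, CNN)", {
  b <- toy_batch(n = 4, tt = 5, d = 3, n_classes = 4, seed = 11)
  mask_num <- b$mask + 0
  for (kind in c("rnn", "lstm", "cnn")) {
    spec <- model_spec(kind, layers = c(3, 2), n_classes = 4,
                       input_shape = c(5, 3), dense_units = 3)
    model <- build_model(spec, seed = 21)
    # move every parameter off exact zero so ReLU/pooling kinks do not
    # sit precisely at the evaluation point of the finite difference
    set.seed(22)
    model$params <- lapply(model$params, function(p) {
      p + rnorm(length(p), sd = 0.05)
    })
    loss_of <- function(params) {
      m2 <- model; m2$params <- params
      fwd <- affmotion:::model_forward(m2, b$x, b$mask)
      affmotion:::softmax_xent(fwd$logits, b$y)$loss
    }
    fwd <- affmotion:::model_forward(model, b$x, b$mask)
    sx <- affmotion:::softmax_xent(fwd$logits, b$y)
    grads <- affmotion:::model_backward(model, fwd, sx$dlogits, b$x, b$mask)
    num <- numeric_grad(loss_of, model$params)
    for (nm in names(grads)) {
      expect_lt(max(abs(grads[[nm]] - num[[nm]])), 1e-6,
                label = paste(kind, nm, "gradient error"))
    }
  }
})

test_that("probability outputs are normalised and shaped per spec", {
  b <- toy_batch(seed = 5)
  for (kind in c("rnn", "lstm", "cnn")) {
    for (nc in c(7, 4)) {
      spec <- model_spec(kind, layers = c(4, 3), n_classes = nc,
                         input_shape = c(5, 4), dense_units = 4)
      model <- build_model(spec, seed = 1)
      p <- predict_proba(model, b$x, b$mask)
      expect_equal(dim(p), c(6, nc))
      expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
      expect_true(all(p >= 0))
    }
  }
  # single-sample forward pass runs without shape errors
  spec <- model_spec("cnn", layers = c(3, 3), n_classes = 7,
                     input_shape = c(5, 4), dense_units = 4)
  model <- build_model(spec, seed = 2)
  p1 <- predict_proba(model, b$x[1, , ])
  expect_equal(dim(p1), c(1, 7))
  # mismatched input shape is an error
  expect_error(predict_proba(model, array(0, c(2, 4, 4))), "shape")
})

test_that("untrained models score at chance on balanced data", {
  set.seed(8)
  n <- 280; tt <- 4; d <- 3
  x <- array(rnorm(n * tt * d), c(n, tt, d))
  y <- rep(1:7, each = 40)
  spec <- model_spec("lstm", layers = 8, n_classes = 7,
                     input_shape = c(tt, d))
  accs <- vapply(1:5, function(s) {
    model <- build_model(spec, seed = s)
    mean(max.col(predict_proba(model, x)) == y)
  }, numeric(1))
  expect_gt(mean(accs), 1 / 7 - 0.08)
  expect_lt(mean(accs), 1 / 7 + 0.08)
})

test_that("training drives loss down and solves separable data", {
  b <- separable_set()
  spec <- model_spec("lstm", layers = 6, n_classes = 4,
                     input_shape = dim(b$x)[2:3])
  model <- build_model(spec, seed = 4)
  cfg <- train_config(max_epochs = 60, patience = 59, seed = 4,
                      batch_size = 8)
  fit <- train(model, b$x, b$y, b$mask, cfg)
  expect_gt(length(fit$history), 5)
  # early epochs trend downward and the toy problem is solved
  expect_lt(mean(tail(fit$history, 3)), mean(head(fit$history, 3)))
  expect_equal(mean(max.col(predict_proba(fit, b$x, b$mask)) == b$y), 1)
})

test_that("early stopping triggers on stalled loss", {
  b <- separable_set(n = 12)
  # zero learning rate: loss can never improve, so training stops after
  # patience + 1 epochs
  spec <- model_spec("rnn", layers = 4, n_classes = 4,
                     input_shape = dim(b$x)[2:3])
  model <- build_model(spec, seed = 1)
  cfg <- train_config(max_epochs = 400, patience = 5, lr = 0, seed = 1)
  fit <- train(model, b$x, b$y, b$mask, cfg)
  expect_lte(length(fit$history), 10)
})

test_that("training is deterministic given a seed", {
  b <- separable_set(n = 16)
  spec <- model_spec("lstm", layers = 5, n_classes = 4,
                     input_shape = dim(b$x)[2:3])
  cfg <- train_config(max_epochs = 8, patience = 7, seed = 9)
  f1 <- train(build_model(spec, seed = 9), b$x, b$y, b$mask, cfg)
  f2 <- train(build_model(spec, seed = 9), b$x, b$y, b$mask, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_error(train(build_model(spec, seed = 1),
                     array(0, c(0, 6, 2)), integer(0)), "empty")
})

test_that("padded steps do not influence recurrent predictions", {
  # two inputs identical on real steps but wildly different on padded
  # steps must give identical probabilities
  set.seed(31)
  x1 <- array(rnorm(1 * 6 * 3), c(1, 6, 3))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 1, 6)
  x2 <- x1
  x2[1, 4:6, ] <- 99
  for (kind in c("rnn", "lstm")) {
    spec <- model_spec(kind, layers = c(4, 3), n_classes = 7,
                       input_shape = c(6, 3))
    model <- build_model(spec, seed = 3)
    expect_equal(predict_proba(model, x1, mask),
                 predict_proba(model, x2, mask), tolerance = 1e-12)
  }
})

test_that("subject folds partition subjects with balanced sizes", {
  subjects <- sprintf("S%02d", 1:16)
  folds <- affmotion:::with_seed(1,
    affmotion:::make_subject_folds(rep(subjects, each = 5), 10))
  expect_length(folds, 10)
  expect_setequal(unlist(folds), subjects)
  expect_equal(sum(lengths(folds) == 2), 6)
  expect_equal(sum(lengths(folds) == 1), 4)
  expect_equal(anyDuplicated(unlist(folds)), 0)

  loso <- affmotion:::with_seed(1,
    affmotion:::make_subject_folds(rep(subjects, 2), "loso"))
  expect_length(loso, 16)
  expect_true(all(lengths(loso) == 1))
  expect_error(affmotion:::with_seed(1,
    affmotion:::make_subject_folds(subjects[1:4], 10)), "loso")
})

test_that("cross-validation never leaks subjects and counts add up", {
  corpus <- tiny_corpus()
  ds <- prepare_dataset(corpus, "PU", 0.05)
  spec <- model_spec("rnn", layers = 6, n_classes = 7,
                     input_shape = dim(ds$x)[2:3])
  cfg <- train_config(max_epochs = 4, patience = 3, seed = 2)
  res <- subject_grouped_cv(ds, spec, cfg, folds = 2, iterations = 2)
  expect_s3_class(res, "cv_result")
  expect_equal(res$n, 2 * length(corpus))  # every sample tested per iteration
  expect_equal(sum(res$confusion), res$n)
  expect_equal(dim(res$fold_accuracy), c(2, 2))
  # fold test sets are disjoint and cover the corpus: per iteration each
  # recording is predicted exactly once, so totals match exactly
  expect_equal(rowSums(res$confusion),
               setNames(2 * as.vector(table(
                 factor(ds$labels, emotion_levels(7)))), emotion_levels(7)))
})

test_that("class subsets drop the right emotions and reuse preprocessing", {
  corpus <- tiny_corpus()
  ds <- prepare_dataset(corpus, "PU", 0.05)
  spec4 <- model_spec("lstm", layers = 6, n_classes = 4,
                      input_shape = dim(ds$x)[2:3])
  cfg <- train_config(max_epochs = 4, patience = 3, seed = 2)
  res4 <- subject_grouped_cv(ds, spec4, cfg, folds = 2, iterations = 1)
  expect_identical(res4$levels, c("sadness", "fear", "anger", "happiness"))
  expect_equal(res4$n, sum(ds$labels %in% res4$levels))
  expect_equal(dim(confusion(res4)), c(4, 4))
  rn <- confusion(res4, normalize = TRUE)
  expect_true(all(abs(rowSums(rn) - 1) < 1e-12))
})

test_that("the experiment grid covers the requested combinations", {
  corpus <- tiny_corpus()
  datasets <- list(PU = prepare_dataset(corpus, "PU", 0.05),
                   OU = prepare_dataset(corpus, "OU", 0.05))
  cfg <- train_config(max_epochs = 3, patience = 2, seed = 1)
  grid <- run_experiment_grid(datasets, kinds = c("rnn", "lstm"),
                              class_subsets = c(7, 4),
                              layers = list(rnn = 5, lstm = 5),
                              config = cfg, folds = 2, iterations = 1)
  expect_equal(nrow(grid), 2 * 2 * 2)
  expect_true(all(table(grid$set, grid$classes) == 2))
  # one best model flagged per set x classes column
  agg <- aggregate(best ~ set + classes, grid, sum)
  expect_true(all(agg$best >= 1))
  # determinism: the same configuration reproduces the same table
  grid2 <- run_experiment_grid(datasets, kinds = c("rnn", "lstm"),
                               class_subsets = c(7, 4),
                               layers = list(rnn = 5, lstm = 5),
                               config = cfg, folds = 2, iterations = 1)
  expect_identical(grid, grid2)
})

test_that("perfect and constant classifiers give the expected confusions", {
  lv <- emotion_levels(4)
  res <- structure(list(
    confusion = matrix(0L, 4, 4, dimnames = list(lv, lv)),
    levels = lv), class = "cv_result")
  diag(res$confusion) <- 5L
  expect_true(all(confusion(res)[upper.tri(diag(4))] == 0))
  const <- res
  const$confusion[] <- 0L
  const$confusion[, 2] <- 3L
  expect_equal(sum(confusion(const) != 0), 4)
  expect_equal(sum(confusion(const)), 12)
})
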