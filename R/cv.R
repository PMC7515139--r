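# Subject-grouped cross-validation, confusion matrices, and the
# experiment grid over feature sets / architectures / class subsets.

# partition unique subjects into `folds` groups of near-equal size
# (round-robin over a shuffled order; uses the current RNG state)
make_subject_folds <- function(subjects, folds) {
  u <- unique(subjects)
  if (identical(folds, "loso")) folds <- length(u)
  folds <- as.integer(folds)
  if (folds > length(u)) {
    stop("fewer subjects (", length(u), ") than folds (", folds,
         "); use folds = \"loso\" for strict leave-one-subject-out",
         call. = FALSE)
  }
  u <- sample(u)
  split(u, rep_len(seq_len(folds), length(u)))
}

#' Subject-grouped cross-validation of a sequence classifier
#'
#' Folds partition *subjects*, so no individual contributes to both the
#' training and the test portion of any fold (the grouped reading of
#' leave-one-subject-out; pass `folds = "loso"` for one subject per
#' fold). Each iteration reshuffles the fold assignment. Z-score
#' statistics are fitted on the training portion of each fold and applied
#' to its test portion (set `normalize_scope = "corpus"` for whole-corpus
#' statistics). The final score is the sample-weighted mean accuracy over
#' all folds and iterations.
#'
#' @param dataset a `feature_dataset` from [pad_sequences()] /
#'   [prepare_dataset()] (not yet z-scored).
#' @param spec a `model_spec`; its `input_shape` must match the dataset.
#' @param config a [train_config()].
#' @param folds number of subject folds (default 10) or `"loso"`.
#' @param iterations number of reshuffled repetitions (default 10).
#' @param normalize_scope `"train"` (default) or `"corpus"`.
#' @param verbose print per-fold accuracies.
#' @return object of class `cv_result`: `accuracy` (percent,
#'   sample-weighted), `fold_accuracy` (iterations x folds matrix),
#'   `confusion` (true x predicted counts over all test predictions),
#'   `levels`, `n`.
#' @export
subject_grouped_cv <- function(dataset, spec, config = train_config(),
                               folds = 10, iterations = 10,
                               normalize_scope = c("train", "corpus"),
                               verbose = FALSE) {
  normalize_scope <- match.arg(normalize_scope)
  lv <- emotion_levels(spec$n_classes)
  keep <- dataset$labels %in% lv
  if (!all(keep)) dataset <- subset_dataset(dataset, keep)
  n <- dim(dataset$x)[1]
  y_int <- encode_labels(dataset$labels, spec$n_classes)
  n_folds <- if (identical(folds, "loso")) length(unique(dataset$subjects))
             else as.integer(folds)
  conf <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  fold_acc <- matrix(NA_real_, iterations, n_folds)
  correct <- 0L; total <- 0L
  corpus_stats <- if (normalize_scope == "corpus") fit_zscore(dataset)
                  else NULL
  for (it in seq_len(iterations)) {
    fold_sets <- with_seed(config$seed + it,
                           make_subject_folds(dataset$subjects, folds))
    for (f in seq_along(fold_sets)) {
      test <- dataset$subjects %in% fold_sets[[f]]
      tr <- subset_dataset(dataset, !test)
      te <- subset_dataset(dataset, test)
      stats <- corpus_stats %||% suppressWarnings(fit_zscore(tr))
      tr <- suppressWarnings(zscore_normalize(tr, stats))
      te <- suppressWarnings(zscore_normalize(te, stats))
      seed_f <- (as.numeric(config$seed) * 1000 + it * 100 + f) %%
        .Machine$integer.max
      model <- build_model(spec, seed = seed_f)
      cfg <- config
      cfg$seed <- seed_f
      model <- train(model, tr$x, tr$labels, tr$mask, cfg)
      probs <- predict_proba(model, te$x, te$mask)
      pred <- max.col(probs, ties.method = "first")
      truth <- encode_labels(te$labels, spec$n_classes)
      fold_acc[it, f] <- mean(pred == truth)
      correct <- correct + sum(pred == truth)
      total <- total + length(truth)
      for (k in seq_along(truth)) {
        conf[truth[k], pred[k]] <- conf[truth[k], pred[k]] + 1L
      }
      if (verbose) {
        message(sprintf("iteration %d fold %d: accuracy %.1f%% (n=%d)",
                        it, f, 100 * fold_acc[it, f], length(truth)))
      }
    }
  }
  structure(
    list(accuracy = 100 * correct / total, fold_accuracy = fold_acc,
         confusion = conf, levels = lv, n = total),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %.1f%% mean accuracy over %d test predictions>\n",
              x$accuracy, x$n))
  invisible(x)
}

subset_dataset <- function(dataset, keep) {
  dataset$x <- dataset$x[keep, , , drop = FALSE]
  dataset$mask <- dataset$mask[keep, , drop = FALSE]
  dataset$labels <- dataset$labels[keep]
  dataset$subjects <- dataset$subjects[keep]
  dataset$repetitions <- dataset$repetitions[keep]
  dataset
}

#' Confusion matrix of a cross-validation result
#'
#' @param result a `cv_result`.
#' @param normalize divide each row by its total (row-normalised rates).
#' @return true x predicted matrix in canonical label order.
#' @export
confusion <- function(result, normalize = FALSE) {
  m <- result$confusion
  if (normalize) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  m
}

#' Run the experiment grid
#'
#' One subject-grouped CV run per combination of feature set, model
#' specification and class subset, reproducing the layout of the
#' feature-set comparison tables. Class subsets reuse identical
#' preprocessing: the 6-class subset drops neutral, the 4-class subset
#' keeps sadness/fear/anger/happiness.
#'
#' @param datasets named list of `feature_dataset` objects (names are the
#'   feature-set ids, e.g. from [prepare_dataset()] per set).
#' @param kinds model kinds to evaluate (subset of cnn/rnn/lstm).
#' @param class_subsets integer vector over {7, 6, 4}.
#' @param layers optional named list kind -> layer widths (defaults per
#'   [model_spec()]).
#' @param config a [train_config()].
#' @param folds,iterations see [subject_grouped_cv()].
#' @return data.frame with columns `network`, `set`, `classes`,
#'   `accuracy` (percent) and `best` (TRUE for the best network within
#'   each set x classes column).
#' @export
run_experiment_grid <- function(datasets, kinds = c("cnn", "rnn", "lstm"),
                                class_subsets = 7, layers = NULL,
                                config = train_config(), folds = 10,
                                iterations = 10) {
  rows <- list()
  for (set_id in names(datasets)) {
    ds <- datasets[[set_id]]
    for (nc in class_subsets) {
      for (kind in kinds) {
        spec <- model_spec(kind, layers = layers[[kind]], n_classes = nc,
                           input_shape = dim(ds$x)[2:3])
        res <- subject_grouped_cv(ds, spec, config, folds, iterations)
        rows[[length(rows) + 1L]] <- data.frame(
          network = kind, set = set_id, classes = nc,
          accuracy = res$accuracy, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (set_id in unique(out$set)) {
    for (nc in unique(out$classes)) {
      sel <- out$set == set_id & out$classes == nc
      out$best[sel] <- out$accuracy[sel] == max(out$accuracy[sel])
    }
  }
  out
}
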