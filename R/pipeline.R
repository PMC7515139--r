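# End-to-end pipeline glue: corpus -> body frame -> keyframes -> scale
# normalisation -> feature composition -> padded dataset; plus the
# top-level entry points used by the command-line wrapper.

#' Prepare a padded feature dataset from a sensor-space corpus
#'
#' Runs the full preprocessing chain: projection into the body-local
#' frame, per-subject scale estimation from the neutral recordings,
#' keyframe extraction (on body-local trajectories), scale normalisation,
#' feature composition for `set_id`, and zero padding. Z-scoring is left
#' to the consumer (cross-validation fits it on training folds).
#'
#' @param corpus list of sensor-space `motion_sequence`.
#' @param set_id feature-set id (see [feature_set_info()]).
#' @param error_rate keyframe chord tolerance in meters; NULL skips
#'   keyframing and keeps every frame.
#' @param joints joints considered by the keyframe extractor.
#' @param missing_root passed to [to_body_frame()].
#' @return a `feature_dataset`.
#' @export
prepare_dataset <- function(corpus, set_id = "P", error_rate = 0.03,
                            joints = nonhand_joints(),
                            missing_root = "error") {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  body <- lapply(corpus, to_body_frame, missing_root = missing_root)
  subjects <- vapply(body, function(s) s$subject, character(1))
  emotions <- vapply(body, function(s) s$emotion, character(1))
  scales <- lapply(unique(subjects), function(su) {
    compute_subject_scale(body[subjects == su & emotions == "neutral"])
  })
  names(scales) <- unique(subjects)
  mats <- lapply(seq_along(body), function(i) {
    kf <- if (is.null(error_rate)) NULL else {
      suppressWarnings(extract_keyframes(body[[i]], error_rate, joints))
    }
    norm <- scale_normalize(body[[i]], scales[[subjects[i]]])
    compose_features(norm, set_id, keyframes = kf)
  })
  pad_sequences(mats)
}

#' Run the full recognition pipeline
#'
#' Generates (or reads) a corpus, prepares the requested feature set,
#' evaluates the requested model under subject-grouped cross-validation,
#' and writes a results table, a confusion matrix, and a reproducibility
#' manifest to `out_dir`.
#'
#' @param corpus_path path to a CSV/JSON-lines corpus; NULL generates a
#'   synthetic corpus instead.
#' @param out_dir output directory (created if needed).
#' @param set_id feature-set id.
#' @param error_rate keyframe tolerance (m).
#' @param model_kind `"cnn"`, `"rnn"` or `"lstm"`.
#' @param layers layer widths (NULL = defaults of [model_spec()]).
#' @param n_classes 7, 6 or 4.
#' @param folds,iterations see [subject_grouped_cv()].
#' @param seed master seed (corpus generation and training).
#' @param generator a [generator_config()] used when `corpus_path` is
#'   NULL (its seed is overridden by `seed`).
#' @param train_cfg a [train_config()] (its seed is overridden by
#'   `seed`).
#' @return invisibly, the `cv_result`.
#' @export
run_pipeline <- function(corpus_path = NULL, out_dir = ".", set_id = "P",
                         error_rate = 0.03, model_kind = "lstm",
                         layers = NULL, n_classes = 7, folds = 10,
                         iterations = 1, seed = 1,
                         generator = generator_config(),
                         train_cfg = train_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- if (is.null(corpus_path)) {
    generator$seed <- seed
    generate_corpus(generator)
  } else {
    read_sequences(corpus_path)
  }
  dataset <- prepare_dataset(corpus, set_id, error_rate)
  spec <- model_spec(model_kind, layers = layers, n_classes = n_classes,
                     input_shape = dim(dataset$x)[2:3])
  train_cfg$seed <- as.integer(seed)
  res <- subject_grouped_cv(dataset, spec, train_cfg, folds, iterations)
  utils::write.csv(
    data.frame(network = model_kind, set = set_id,
               error_rate = error_rate %||% NA, classes = n_classes,
               accuracy = res$accuracy),
    file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(confusion(res),
                   file.path(out_dir, "confusion.csv"))
  jsonlite::write_json(
    list(seed = seed, set = set_id, error_rate = error_rate,
         model = model_kind, layers = spec$layers, n_classes = n_classes,
         folds = folds, iterations = iterations,
         n_recordings = length(corpus),
         input_shape = spec$input_shape,
         package_version = as.character(utils::packageVersion("affmotion"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Quantity-of-motion report
#'
#' Computes the joints-by-emotions quantity-of-motion table for a corpus
#' and writes both the all-joints and the hands-excluded variants as CSV.
#'
#' @param corpus list of `motion_sequence` (or path to a corpus file).
#' @param out_dir output directory.
#' @return invisibly, the full `qom_table`.
#' @export
run_qom <- function(corpus, out_dir = ".") {
  if (is.character(corpus)) corpus <- read_sequences(corpus)
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qom <- quantity_of_motion(corpus)
  utils::write.csv(qom_heatmap(qom, exclude_hands = FALSE),
                   file.path(out_dir, "qom_all_joints.csv"))
  utils::write.csv(qom_heatmap(qom, exclude_hands = TRUE),
                   file.path(out_dir, "qom_no_hands.csv"))
  invisible(qom)
}
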