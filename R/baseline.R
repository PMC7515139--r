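# Handcrafted whole-recording baseline features and classic-classifier
# plumbing, for comparison against the sequence models.

#' Extract handcrafted baseline features from a recording
#'
#' Classic whole-recording summaries used throughout affective movement
#' analysis, computed on the full (un-keyframed) scale-normalised
#' sequence over the 19 non-hand joints. Exact definitions (dt = frame
#' interval; p_j(f) = position of joint j at frame f; normalised units):
#'
#' * `vel_mean`, `vel_max`: mean / max over joints and frames of
#'   `||p_j(f+1) - p_j(f)|| / dt`.
#' * `acc_mean`, `acc_max`: mean / max of `|v_j(f+1) - v_j(f)| / dt` on
#'   the speed series.
#' * `kinetic`: mean over frames of `sum_j v_j^2` (unit-mass kinetic
#'   energy proxy; scales as the square of the coordinates).
#' * `bbox_volume_mean`, `bbox_volume_max`: per-frame axis-aligned
#'   bounding-box volume of the skeleton.
#' * `contraction_index`: mean over frames of the mean wrist-to-SpineMid
#'   distance (how far the hands reach from the torso).
#' * `density`: mean over frames of the mean joint distance to the
#'   skeleton centroid.
#' * `smoothness`: mean third-difference (jerk) magnitude of joint
#'   positions divided by dt^3; 0 for sequences shorter than 4 frames.
#' * `leaning`: mean trunk pitch in degrees,
#'   `atan2(w, v)` of the SpineBase-to-SpineShoulder vector (forward
#'   lean positive).
#' * `dist_wrists`, `dist_ankles`, `dist_elbows`, `dist_wrist_head`:
#'   mean inter-joint distances of symmetric pairs (wrist--head averaged
#'   over sides).
#'
#' @param seq `motion_sequence`, `space == "scale_normalized"`, >= 3
#'   frames (acceleration is undefined below that).
#' @return named numeric vector (class `baseline_features`), all finite.
#' @export
extract_baseline_features <- function(seq) {
  if (seq$space != "scale_normalized") {
    stop("extract_baseline_features() expects a scale-normalized sequence",
         call. = FALSE)
  }
  nf <- n_frames(seq)
  if (nf < 3) {
    stop("baseline features need at least 3 frames (acceleration is ",
         "undefined for shorter sequences)", call. = FALSE)
  }
  jidx <- joint_index(nonhand_joints())
  P <- seq$positions
  P[, 1, ] <- 0  # geometric root position in the body frame
  P <- P[, jidx, , drop = FALSE]
  nj <- length(jidx)
  dt <- diff(seq$timestamps)
  disp <- sqrt(
    (P[-1, , 1] - P[-nf, , 1])^2 +
    (P[-1, , 2] - P[-nf, , 2])^2 +
    (P[-1, , 3] - P[-nf, , 3])^2
  )
  disp <- matrix(disp, ncol = nj)
  v <- disp / dt                       # (nf-1) x joints speeds
  a <- abs(diff(v)) / dt[-1]           # (nf-2) x joints accelerations
  kinetic <- mean(rowSums(v^2))
  ext <- t(apply(P, 1, function(fr) {
    m <- matrix(fr, ncol = 3)
    apply(m, 2, function(col) diff(range(col)))
  }))
  bbox <- ext[, 1] * ext[, 2] * ext[, 3]
  centroid <- apply(P, c(1, 3), mean)
  dens <- mean(vapply(seq_len(nf), function(f) {
    mean(row_norms(sweep(matrix(P[f, , ], ncol = 3), 2, centroid[f, ])))
  }, numeric(1)))
  jerk <- if (nf >= 4) {
    d3 <- apply(P, c(2, 3), function(tr) diff(tr, differences = 3))
    d3 <- array(d3, c(nf - 3, nj, 3))
    mean(sqrt(d3[, , 1]^2 + d3[, , 2]^2 + d3[, , 3]^2) /
           mean(dt)^3)
  } else 0
  wl <- seq$positions[, joint_index("WristLeft"), ]
  wr <- seq$positions[, joint_index("WristRight"), ]
  sm <- seq$positions[, joint_index("SpineMid"), ]
  ss <- seq$positions[, joint_index("SpineShoulder"), ]
  hd <- seq$positions[, joint_index("Head"), ]
  al <- seq$positions[, joint_index("AnkleLeft"), ]
  ar <- seq$positions[, joint_index("AnkleRight"), ]
  el <- seq$positions[, joint_index("ElbowLeft"), ]
  er <- seq$positions[, joint_index("ElbowRight"), ]
  contraction <- mean((row_norms(wl - sm) + row_norms(wr - sm)) / 2)
  leaning <- mean(rad2deg(atan2(ss[, 3], ss[, 2])))
  out <- c(
    vel_mean = mean(v), vel_max = max(v),
    acc_mean = mean(a), acc_max = max(a),
    kinetic = kinetic,
    bbox_volume_mean = mean(bbox), bbox_volume_max = max(bbox),
    contraction_index = contraction,
    density = dens,
    smoothness = jerk,
    leaning = leaning,
    dist_wrists = mean(row_norms(wl - wr)),
    dist_ankles = mean(row_norms(al - ar)),
    dist_elbows = mean(row_norms(el - er)),
    dist_wrist_head = mean((row_norms(wl - hd) + row_norms(wr - hd)) / 2)
  )
  if (!all(is.finite(out))) {
    stop("non-finite baseline feature; check timestamps and positions",
         call. = FALSE)
  }
  class(out) <- c("baseline_features", class(out))
  out
}

#' Baseline-feature table for a corpus
#'
#' @param corpus list of scale-normalized `motion_sequence`.
#' @return data.frame: one row per recording with baseline features plus
#'   `emotion` and `subject` columns.
#' @export
baseline_feature_table <- function(corpus) {
  feats <- t(vapply(corpus, function(s) {
    unclass(extract_baseline_features(s))
  }, numeric(15)))
  out <- as.data.frame(feats)
  out$emotion <- vapply(corpus, function(s) s$emotion, character(1))
  out$subject <- vapply(corpus, function(s) s$subject, character(1))
  out
}

#' Classic classifiers on baseline features
#'
#' Subject-grouped cross-validation of standard classifiers (random
#' forest via \pkg{randomForest}, SVM via \pkg{e1071}) on the handcrafted
#' baseline features, as a point of comparison for the sequence models.
#'
#' @param features data.frame from [baseline_feature_table()].
#' @param method `"rf"` or `"svm"`.
#' @param folds number of subject-grouped folds.
#' @param seed RNG seed for fold assignment and the classifier.
#' @return list with `accuracy` (percent) and `confusion` matrix.
#' @export
classify_baseline <- function(features, method = c("rf", "svm"),
                              folds = 10, seed = 1) {
  method <- match.arg(method)
  pkg <- switch(method, rf = "randomForest", svm = "e1071")
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for method '", method, "'",
         call. = FALSE)
  }
  y <- factor(features$emotion, levels = emotion_levels(7))
  y <- droplevels(y)
  xcols <- setdiff(names(features), c("emotion", "subject"))
  fold_sets <- with_seed(seed,
    make_subject_folds(features$subject, folds))
  lv <- levels(y)
  conf <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  for (fold in fold_sets) {
    test <- features$subject %in% fold
    fit <- with_seed(seed, switch(method,
      rf = randomForest::randomForest(
        x = features[!test, xcols], y = y[!test]),
      svm = e1071::svm(x = as.matrix(features[!test, xcols]), y = y[!test])
    ))
    pred <- predict(fit, as.matrix(features[test, xcols]))
    for (i in which(test)) {
      conf[as.character(y[i]),
           as.character(pred[match(i, which(test))])] <-
        conf[as.character(y[i]),
             as.character(pred[match(i, which(test))])] + 1L
    }
  }
  list(accuracy = 100 * sum(diag(conf)) / sum(conf), confusion = conf)
}
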