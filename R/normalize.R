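# Subject-scale normalisation, zero padding, and sequence-wise z-scoring.

#' Compute a subject's skeletal scale
#'
#' The scale is the median, over every frame of all of the subject's
#' neutral recordings, of the SpineBase--SpineShoulder distance. These two
#' joints carry the lowest sensor noise, and the neutral recordings pin the
#' scale to the resting skeleton so that whole-body events in emotional
#' recordings (hops, squats) survive normalisation.
#'
#' @param neutral_seqs list of body-local `motion_sequence` objects with
#'   `emotion == "neutral"`, all from one subject.
#' @return object of class `subject_scale` with fields `subject`,
#'   `spine_length` (meters).
#' @export
compute_subject_scale <- function(neutral_seqs) {
  if (!length(neutral_seqs)) {
    stop("no neutral recordings supplied; compute the scale from another ",
         "resting recording or supply one explicitly", call. = FALSE)
  }
  subjects <- unique(vapply(neutral_seqs, function(s) s$subject, character(1)))
  if (length(subjects) != 1) {
    stop("neutral recordings span multiple subjects: ",
         paste(subjects, collapse = ", "), call. = FALSE)
  }
  d <- unlist(lapply(neutral_seqs, function(s) {
    if (s$emotion != "neutral") {
      stop("non-neutral recording passed to compute_subject_scale()",
           call. = FALSE)
    }
    if (s$space != "body_local") {
      stop("compute_subject_scale() expects body-local sequences",
           call. = FALSE)
    }
    # in the body-local frame the root sits at the origin, so the spine
    # length is the norm of the SpineShoulder position
    row_norms(s$positions[, joint_index("SpineShoulder"), , drop = TRUE])
  }))
  sl <- stats::median(d)
  if (!is.finite(sl) || sl <= 0) {
    stop("degenerate spine length: ", sl, call. = FALSE)
  }
  structure(list(subject = subjects, spine_length = sl),
            class = "subject_scale")
}

#' Scale-normalise a body-local sequence
#'
#' Divides every (root-relative) joint position and the root displacement
#' channel componentwise by the subject's spine length, removing
#' between-subject height differences. Orientations are angles and need no
#' rescaling.
#'
#' @param seq `motion_sequence` with `space == "body_local"`.
#' @param scale a `subject_scale` (or a single positive number).
#' @return `motion_sequence` with `space == "scale_normalized"`.
#' @export
scale_normalize <- function(seq, scale) {
  if (seq$space != "body_local") {
    stop("scale_normalize() expects a body-local sequence (got '",
         seq$space, "')", call. = FALSE)
  }
  sl <- if (inherits(scale, "subject_scale")) scale$spine_length else scale
  if (!is.numeric(sl) || length(sl) != 1 || !is.finite(sl) || sl <= 0) {
    stop("invalid spine length", call. = FALSE)
  }
  out <- seq
  out$positions <- seq$positions / sl
  if (!is.null(seq$root_delta)) {
    out$root_delta$displacement <- seq$root_delta$displacement / sl
  }
  out$space <- "scale_normalized"
  out
}

#' Pad feature matrices to a common keyframe count
#'
#' Appends zero rows to each recording's feature matrix up to the corpus
#' maximum, recording which rows are real in a pad mask (real rows always
#' form a prefix). Real values are preserved bit-exactly.
#'
#' @param mats list of `feature_matrix` objects (see [compose_features()]).
#' @return object of class `feature_dataset`: list with `x` (array
#'   `[n, max_keyframes, features]`), `mask` (logical `[n, max_keyframes]`),
#'   `labels`, `subjects`, `repetitions`, `set_id`.
#' @export
pad_sequences <- function(mats) {
  if (!length(mats)) stop("`mats` must be nonempty", call. = FALSE)
  set_ids <- unique(vapply(mats, function(m) attr(m, "set_id"), character(1)))
  if (length(set_ids) != 1) {
    stop("all feature matrices must share one feature-set id", call. = FALSE)
  }
  d <- ncol(mats[[1]])
  lens <- vapply(mats, nrow, integer(1))
  tmax <- max(lens)
  n <- length(mats)
  x <- array(0, c(n, tmax, d),
             dimnames = list(NULL, NULL, colnames(mats[[1]])))
  mask <- matrix(FALSE, n, tmax)
  for (i in seq_len(n)) {
    x[i, seq_len(lens[i]), ] <- mats[[i]]
    mask[i, seq_len(lens[i])] <- TRUE
  }
  structure(
    list(
      x = x, mask = mask,
      labels = vapply(mats, function(m) attr(m, "emotion"), character(1)),
      subjects = vapply(mats, function(m) attr(m, "subject"), character(1)),
      repetitions = vapply(mats, function(m) {
        as.integer(attr(m, "repetition") %||% NA_integer_)
      }, integer(1)),
      set_id = set_ids
    ),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf(
    "<feature_dataset: %d recordings x %d keyframes x %d features (set %s)>\n",
    dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$set_id))
  invisible(x)
}

#' Fit sequence-wise z-score statistics
#'
#' Per-feature mean and standard deviation pooled over the real
#' (non-padded) rows of every sequence in `dataset`. Zero-variance
#' features (e.g. constant-filled orientation channels) get unit scale so
#' they standardise to zero, with a warning.
#'
#' @param dataset a `feature_dataset`.
#' @param per_feature if FALSE, a single global mean/sd over all features
#'   is used instead of per-feature moments.
#' @return list with `center`, `scale` vectors (length = features).
#' @export
fit_zscore <- function(dataset, per_feature = TRUE) {
  real <- real_rows(dataset)
  if (per_feature) {
    center <- colMeans(real)
    scale <- apply(real, 2, stats::sd)
  } else {
    center <- rep(mean(real), ncol(real))
    scale <- rep(stats::sd(as.vector(real)), ncol(real))
  }
  degenerate <- !is.finite(scale) | scale < 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s) standardised to 0",
            call. = FALSE)
    scale[degenerate] <- 1
  }
  list(center = center, scale = scale)
}

#' Apply z-score statistics to a padded dataset
#'
#' Standardises real rows with the supplied (or freshly fitted) moments;
#' padded rows remain exactly zero.
#'
#' @param dataset a `feature_dataset`.
#' @param stats result of [fit_zscore()]; fitted on `dataset` when NULL.
#' @param per_feature see [fit_zscore()].
#' @return the standardised `feature_dataset` (with the statistics used
#'   attached as attribute `zscore`).
#' @export
zscore_normalize <- function(dataset, stats = NULL, per_feature = TRUE) {
  if (is.null(stats)) stats <- fit_zscore(dataset, per_feature)
  x <- dataset$x
  n <- dim(x)[1]; tmax <- dim(x)[2]; d <- dim(x)[3]
  ctr <- array(rep(stats$center, each = n * tmax), c(n, tmax, d))
  scl <- array(rep(stats$scale, each = n * tmax), c(n, tmax, d))
  x <- (x - ctr) / scl
  x[!dataset$mask] <- 0   # mask recycles over the feature dimension
  dataset$x <- x
  attr(dataset, "zscore") <- stats
  dataset
}

# real (unpadded) rows of all sequences, stacked into one matrix
real_rows <- function(dataset) {
  n <- dim(dataset$x)[1]; d <- dim(dataset$x)[3]
  out <- lapply(seq_len(n), function(i) {
    dataset$x[i, dataset$mask[i, ], , drop = FALSE]
  })
  m <- do.call(rbind, lapply(out, function(a) {
    matrix(a, ncol = d)
  }))
  colnames(m) <- dimnames(dataset$x)[[3]]
  m
}
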