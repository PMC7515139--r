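# Feature-set composition and the quantity-of-motion statistic.

#' Feature-set definitions
#'
#' Six feature sets combine channel scope (P = positions, O = orientations,
#' PO = both) with joint scope (full body = the 19 non-hand joints, U =
#' the 11 upper-body joints). Every set carries one shared temporal channel
#' (the keyframe timestamp normalised to [0, 1]), giving per-keyframe
#' widths P = 58, O = 58, PO = 115, PU = 34, OU = 34, POU = 67.
#'
#' @param set_id one of `"P"`, `"O"`, `"PO"`, `"PU"`, `"OU"`, `"POU"`.
#' @return list with `set_id`, `joints`, `channels` (`"P"`, `"O"` or
#'   `"PO"`), `expected_count`.
#' @export
feature_set_info <- function(set_id) {
  set_id <- match.arg(set_id, c("P", "O", "PO", "PU", "OU", "POU"))
  upper <- grepl("U$", set_id)
  channels <- sub("U$", "", set_id)
  joints <- if (upper) upper_body_joints() else nonhand_joints()
  nch <- if (channels == "PO") 6L else 3L
  list(
    set_id = set_id,
    joints = joints,
    channels = channels,
    expected_count = nch * length(joints) + 1L
  )
}

#' Compose a per-recording feature matrix
#'
#' Builds the keyframes-by-features matrix for one recording: per selected
#' joint, 3 position channels (P family; the root contributes its
#' displacement channel) and/or 3 orientation channels (O family; joints
#' without sensor orientation are zero-filled), plus one shared temporal
#' channel, the keyframe timestamp rescaled to [0, 1] over the recording.
#' Hand joints are never included. Column counts match
#' [feature_set_info()].
#'
#' @param seq `motion_sequence` with `space == "scale_normalized"`.
#' @param set_id feature-set id (see [feature_set_info()]).
#' @param keyframes a `keyframe_sequence` from [extract_keyframes()], or
#'   NULL to use every frame.
#' @param temporal_channel include the normalised-time channel (default
#'   TRUE; disabling it deviates from the standard set widths and warns).
#' @return numeric matrix (class `feature_matrix`) of keyframes x
#'   features with metadata attributes `set_id`, `emotion`, `subject`,
#'   `repetition`.
#' @export
compose_features <- function(seq, set_id, keyframes = NULL,
                             temporal_channel = TRUE) {
  info <- feature_set_info(set_id)
  if (seq$space != "scale_normalized") {
    stop("compose_features() expects a scale-normalized sequence (got '",
         seq$space, "')", call. = FALSE)
  }
  idx <- if (is.null(keyframes)) seq_len(n_frames(seq)) else keyframes$indices
  jidx <- joint_index(info$joints)
  blocks <- list()
  if (info$channels %in% c("P", "PO")) {
    P <- seq$positions[idx, jidx, , drop = FALSE]
    m <- matrix(P, nrow = length(idx))
    colnames(m) <- paste0(rep(info$joints, 3), ".p",
                          rep(c("x", "y", "z"), each = length(jidx)))
    blocks$P <- m
  }
  if (info$channels %in% c("O", "PO")) {
    O <- seq$orientations[idx, jidx, , drop = FALSE]
    O[is.na(O)] <- 0   # joints without sensor orientation
    m <- matrix(O, nrow = length(idx))
    colnames(m) <- paste0(rep(info$joints, 3), ".o",
                          rep(c("x", "y", "z"), each = length(jidx)))
    blocks$O <- m
  }
  if (temporal_channel) {
    ts <- seq$timestamps[idx]
    span <- diff(range(seq$timestamps))
    tn <- if (span > 0) (ts - seq$timestamps[1]) / span else rep(0, length(ts))
    blocks$t <- matrix(tn, ncol = 1, dimnames = list(NULL, "t_norm"))
  } else {
    warning("temporal channel disabled; column count deviates from the ",
            "standard set widths", call. = FALSE)
  }
  out <- do.call(cbind, blocks)
  structure(out,
            class = c("feature_matrix", class(out)),
            set_id = info$set_id,
            emotion = seq$emotion,
            subject = seq$subject,
            repetition = seq$repetition)
}

#' Quantity of motion per joint and emotion
#'
#' For each joint j and emotion e, averages over all recordings of that
#' emotion the mean per-transition displacement of the joint in
#' hierarchical (parent-relative) local coordinates:
#' entry(j, e) = (1/N_e) * sum_n [ sum_f ||p_j(f) - p_j(f-1)|| / T_n ],
#' where T_n is the number of frame transitions of recording n (set
#' `normalize_by = "frames"` to divide by the frame count instead).
#' Stationary joints score 0; a joint moving a constant step scores that
#' step length. Emotions with no recordings get `NA`.
#'
#' @param corpus list of `motion_sequence`.
#' @param normalize_by `"transitions"` (default) or `"frames"`.
#' @param euler_order intrinsic Euler order for the parent frames.
#' @return 25 x 7 matrix (joints x emotions) of class `qom_table`,
#'   meters per frame transition; all entries >= 0 (or NA).
#' @export
quantity_of_motion <- function(corpus,
                               normalize_by = c("transitions", "frames"),
                               euler_order = "yxz") {
  normalize_by <- match.arg(normalize_by)
  if (!length(corpus)) stop("`corpus` must be nonempty", call. = FALSE)
  emo <- vapply(corpus, function(s) s$emotion, character(1))
  per_rec <- vapply(corpus, function(s) {
    H <- to_hierarchical_local(s, euler_order)
    nf <- dim(H)[1]
    steps <- sqrt(
      (H[-1, , 1] - H[-nf, , 1])^2 +
      (H[-1, , 2] - H[-nf, , 2])^2 +
      (H[-1, , 3] - H[-nf, , 3])^2
    )
    denom <- if (normalize_by == "transitions") nf - 1L else nf
    colSums(matrix(steps, ncol = 25)) / denom
  }, numeric(25))
  lv <- emotion_levels(7)
  out <- vapply(lv, function(e) {
    if (!any(emo == e)) return(rep(NA_real_, 25))
    rowMeans(per_rec[, emo == e, drop = FALSE])
  }, numeric(25))
  rownames(out) <- .joint_names
  colnames(out) <- lv
  class(out) <- c("qom_table", class(out))
  out
}

#' Render a quantity-of-motion heat-map
#'
#' Returns (and optionally plots) the joints-by-emotions matrix, either
#' for all 25 joints or with the six hand-related joints dropped (whose
#' apparent motion is dominated by sensor error). Row order is the
#' standard joint order and is stable across calls.
#'
#' @param table a `qom_table` from [quantity_of_motion()].
#' @param exclude_hands drop the 6 hand-related rows.
#' @param plot draw a base-graphics heat-map.
#' @return the (possibly row-subset) matrix, invisibly when plotting.
#' @export
qom_heatmap <- function(table, exclude_hands = FALSE, plot = FALSE) {
  m <- unclass(table)
  if (exclude_hands) m <- m[setdiff(rownames(m), hand_joints()), , drop = FALSE]
  colnames(m) <- unname(emotion_abbreviations()[colnames(m)])
  if (plot) {
    op <- graphics::par(mar = c(4, 8, 2, 1))
    on.exit(graphics::par(op))
    graphics::image(
      x = seq_len(ncol(m)), y = seq_len(nrow(m)),
      z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
      axes = FALSE, xlab = "", ylab = "",
      main = "Average quantity of motion (m / transition)"
    )
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 2, cex.axis = 0.7)
    return(invisible(m))
  }
  m
}
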