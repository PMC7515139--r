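# Keyframe extraction by recursive trajectory-curve simplification
# (Lowe / Douglas-Peucker).

# perpendicular distance of points (rows of P) to the segment a--b in 3D
point_segment_distance <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  rel <- sweep(P, 2, a)
  if (L2 < .Machine$double.eps) return(row_norms(rel))
  t <- pmin(1, pmax(0, (rel %*% ab)[, 1] / L2))
  row_norms(rel - outer(t, ab))
}

#' Simplify a 3D trajectory to its keypoints
#'
#' Recursive curve simplification: starting from the chord joining the
#' first and last points, if the maximum perpendicular distance of any
#' interior point to the chord exceeds `error_rate`, the trajectory is
#' split at the farthest point (ties broken by the lowest index, which
#' makes the split tree independent of `error_rate`) and both halves are
#' simplified recursively; otherwise only the endpoints are kept.
#'
#' @param points numeric matrix (n x 3), n >= 2, finite.
#' @param error_rate chord-deviation tolerance, meters, > 0.
#' @return sorted integer vector of retained 1-based indices; always
#'   includes the first and last point.
#' @export
simplify_trajectory <- function(points, error_rate) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(n) || n < 2) {
    stop("a trajectory needs at least 2 points", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("trajectory contains non-finite coordinates", call. = FALSE)
  }
  if (!is.numeric(error_rate) || length(error_rate) != 1 || error_rate <= 0) {
    stop("`error_rate` must be a single positive number", call. = FALSE)
  }
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (j - i < 2L) next
    interior <- (i + 1L):(j - 1L)
    d <- point_segment_distance(points[interior, , drop = FALSE],
                                points[i, ], points[j, ])
    m <- which.max(d)   # first maximum = lowest-index tie-break
    if (d[m] > error_rate) {
      split <- interior[m]
      keep[split] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, split)
      stack[[length(stack) + 1L]] <- c(split, j)
    }
  }
  which(keep)
}

#' Extract keyframes from a motion sequence
#'
#' Runs [simplify_trajectory()] on the position trajectory of each
#' selected joint and merges the per-joint index sets. A frame is key if
#' it is salient for any joint (`merge = "union"`, the default); the root
#' joint's trajectory is its displacement channel, so whole-body events
#' also produce keyframes. Error rates below 0.03 m tend to keep nearly
#' every frame (sensor-noise scale) and rates above 0.05 m reduce most
#' recordings to their endpoints; values outside [0.03, 0.05] are
#' accepted with a warning.
#'
#' @param seq `motion_sequence` (body-local or scale-normalized space).
#' @param error_rate chord-deviation tolerance in meters (default 0.03).
#' @param joints character vector of joint names to consider (default: the
#'   19 non-hand joints).
#' @param merge `"union"` (default) or `"per_joint"` to return the
#'   per-joint index sets unmerged.
#' @return for `"union"`, an object of class `keyframe_sequence` with
#'   fields `indices`, `error_rate`, `joints`; for `"per_joint"`, a named
#'   list of index vectors.
#' @export
extract_keyframes <- function(seq, error_rate = 0.03,
                              joints = nonhand_joints(),
                              merge = c("union", "per_joint")) {
  merge <- match.arg(merge)
  if (!length(joints)) stop("`joints` must be nonempty", call. = FALSE)
  bad <- setdiff(joints, .joint_names)
  if (length(bad)) stop("unknown joint: ", bad[1], call. = FALSE)
  if (error_rate < 0.03 - 1e-12 || error_rate > 0.05 + 1e-12) {
    warning("error_rate ", error_rate, " m is outside the recommended ",
            "[0.03, 0.05] m band", call. = FALSE)
  }
  per_joint <- lapply(joint_index(joints), function(j) {
    simplify_trajectory(seq$positions[, j, ], error_rate)
  })
  names(per_joint) <- joints
  if (merge == "per_joint") return(per_joint)
  structure(
    list(
      indices = sort(unique(unlist(per_joint))),
      error_rate = error_rate,
      joints = joints,
      sequence_id = seq$sequence_id
    ),
    class = "keyframe_sequence"
  )
}

#' @export
print.keyframe_sequence <- function(x, ...) {
  cat(sprintf("<keyframe_sequence %s: %d keyframes at error_rate %.3f m>\n",
              x$sequence_id %||% "?", length(x$indices), x$error_rate))
  invisible(x)
}

#' Mean keyframe count per emotion over a grid of error rates
#'
#' @param corpus list of `motion_sequence`.
#' @param error_rates numeric vector of tolerances (meters).
#' @param joints joints to consider (default non-hand).
#' @return data.frame with columns `emotion`, `error_rate`,
#'   `mean_keyframes`.
#' @export
keyframe_count_sweep <- function(corpus, error_rates,
                                 joints = nonhand_joints()) {
  if (!length(corpus)) stop("`corpus` must be nonempty", call. = FALSE)
  emo <- vapply(corpus, function(s) s$emotion, character(1))
  res <- lapply(error_rates, function(eps) {
    counts <- vapply(corpus, function(s) {
      length(suppressWarnings(
        extract_keyframes(s, eps, joints = joints))$indices)
    }, numeric(1))
    data.frame(
      emotion = emotion_levels(7),
      error_rate = eps,
      mean_keyframes = vapply(emotion_levels(7), function(e) {
        if (any(emo == e)) mean(counts[emo == e]) else NA_real_
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, res)
}
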