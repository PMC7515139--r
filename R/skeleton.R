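# Joint taxonomy, emotion labels, and the motion_sequence container.

.joint_names <- c(
  "SpineBase", "SpineMid", "Neck", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
  "HipRight", "KneeRight", "AnkleRight", "FootRight",
  "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight"
)

.joint_parents <- c(
  SpineBase = NA_character_, SpineMid = "SpineBase", Neck = "SpineShoulder",
  Head = "Neck",
  ShoulderLeft = "SpineShoulder", ElbowLeft = "ShoulderLeft",
  WristLeft = "ElbowLeft", HandLeft = "WristLeft",
  ShoulderRight = "SpineShoulder", ElbowRight = "ShoulderRight",
  WristRight = "ElbowRight", HandRight = "WristRight",
  HipLeft = "SpineBase", KneeLeft = "HipLeft", AnkleLeft = "KneeLeft",
  FootLeft = "AnkleLeft",
  HipRight = "SpineBase", KneeRight = "HipRight", AnkleRight = "KneeRight",
  FootRight = "AnkleRight",
  SpineShoulder = "SpineMid",
  HandTipLeft = "HandLeft", ThumbLeft = "HandLeft",
  HandTipRight = "HandRight", ThumbRight = "HandRight"
)

#' Kinect-v2 joint taxonomy
#'
#' The 25 tracked joints in standard Kinect-v2 index order (SpineBase = 0
#' ... ThumbRight = 24), with parent links forming a tree rooted at
#' SpineBase.
#'
#' @return data.frame with columns `name`, `index` (0-based), `parent`
#'   (`NA` for the root).
#' @export
kinect_joints <- function() {
  data.frame(
    name = .joint_names,
    index = 0:24,
    parent = unname(.joint_parents[.joint_names]),
    stringsAsFactors = FALSE
  )
}

#' Named joint subsets
#'
#' `hand_joints()`: the six hand-related joints excluded from feature sets
#' (their apparent motion is dominated by sensor error). `nonhand_joints()`:
#' the remaining 19 full-body joints. `upper_body_joints()`: the 11 non-hand
#' upper-body joints. `no_orientation_joints()`: joints for which the sensor
#' reports no orientation (head, hands, knees and feet).
#'
#' @return character vector of joint names.
#' @export
hand_joints <- function() {
  c("HandLeft", "HandRight", "HandTipLeft", "HandTipRight",
    "ThumbLeft", "ThumbRight")
}

#' @rdname hand_joints
#' @export
nonhand_joints <- function() setdiff(.joint_names, hand_joints())

#' @rdname hand_joints
#' @export
upper_body_joints <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head", "ShoulderLeft", "ShoulderRight",
    "ElbowLeft", "ElbowRight", "WristLeft", "WristRight", "SpineShoulder")
}

#' @rdname hand_joints
#' @export
no_orientation_joints <- function() {
  c("Head", hand_joints(), "KneeLeft", "KneeRight", "FootLeft", "FootRight")
}

joint_index <- function(names) match(names, .joint_names)

# joint indices ordered parents-before-children
topo_joint_order <- function() {
  par <- joint_index(.joint_parents[.joint_names])
  done <- is.na(par)
  ord <- which(done)
  while (length(ord) < 25) {
    ready <- which(!done & done[par])
    ord <- c(ord, ready)
    done[ready] <- TRUE
  }
  ord
}

#' Emotion labels
#'
#' The seven basic emotional states in canonical order, with standard
#' two-letter abbreviations. The 6-class subset drops neutral; the 4-class
#' subset keeps sadness, fear, anger and happiness.
#'
#' @param n_classes 7, 6 or 4.
#' @return character vector of emotion names.
#' @export
emotion_levels <- function(n_classes = 7) {
  all7 <- c("neutral", "sadness", "surprise", "fear", "anger",
            "disgust", "happiness")
  switch(as.character(n_classes),
    "7" = all7,
    "6" = setdiff(all7, "neutral"),
    "4" = c("sadness", "fear", "anger", "happiness"),
    stop("`n_classes` must be 7, 6 or 4", call. = FALSE)
  )
}

#' @rdname emotion_levels
#' @export
emotion_abbreviations <- function() {
  c(neutral = "Ne", sadness = "Sa", surprise = "Su", fear = "Fe",
    anger = "An", disgust = "Di", happiness = "Ha")
}

#' Construct a motion sequence
#'
#' A motion sequence holds an ordered run of skeletal frames: per-frame 3D
#' positions (meters) for all 25 joints, optional per-joint orientations
#' (3 per-axis Euler angles, degrees; `NA` where the sensor reports none),
#' strictly increasing timestamps, and recording metadata. The `space` tag
#' tracks which coordinate normalisations have been applied; each transform
#' updates it exactly once, so double-normalisation is rejected.
#'
#' @param positions numeric array `[frames, 25, 3]`, meters.
#' @param timestamps numeric vector, seconds, strictly increasing.
#' @param subject subject identifier.
#' @param emotion one of [emotion_levels()].
#' @param repetition integer repetition index.
#' @param orientations numeric array `[frames, 25, 3]` of degrees, or NULL;
#'   rows for joints without orientation are `NA`.
#' @param space coordinate-space tag: `"sensor"`, `"body_local"` or
#'   `"scale_normalized"`.
#' @param root_delta list with `displacement` and `rotation` matrices
#'   (`frames` x 3) describing root motion relative to the first frame;
#'   present after projection to the body-local frame.
#' @param sequence_id optional identifier; generated from metadata if NULL.
#' @param quality logical quality flag (FALSE marks simulated tracking
#'   failures).
#' @return object of class `motion_sequence`.
#' @export
motion_sequence <- function(positions, timestamps, subject, emotion,
                            repetition = 1L, orientations = NULL,
                            space = "sensor", root_delta = NULL,
                            sequence_id = NULL, quality = TRUE) {
  if (length(dim(positions)) != 3 || dim(positions)[2] != 25 ||
      dim(positions)[3] != 3) {
    stop("`positions` must be a [frames, 25, 3] array", call. = FALSE)
  }
  n <- dim(positions)[1]
  if (n < 2) stop("a motion sequence needs at least 2 frames", call. = FALSE)
  if (length(timestamps) != n) {
    stop("`timestamps` length must equal the frame count", call. = FALSE)
  }
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(positions))) {
    stop("joint positions must be finite", call. = FALSE)
  }
  emotion <- match.arg(emotion, emotion_levels(7))
  if (is.null(orientations)) {
    orientations <- array(NA_real_, dim(positions))
  }
  space <- match.arg(space, c("sensor", "body_local", "scale_normalized"))
  structure(
    list(
      positions = positions,
      orientations = orientations,
      timestamps = as.numeric(timestamps),
      subject = as.character(subject),
      emotion = emotion,
      repetition = as.integer(repetition),
      space = space,
      root_delta = root_delta,
      sequence_id = sequence_id %||%
        sprintf("%s_%s_r%02d", subject, emotion, as.integer(repetition)),
      quality = isTRUE(quality)
    ),
    class = "motion_sequence"
  )
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf(
    "<motion_sequence %s: subject %s, emotion %s, rep %d, %d frames, %.2f s, space=%s>\n",
    x$sequence_id, x$subject, x$emotion, x$repetition,
    n_frames(x), diff(range(x$timestamps)), x$space
  ))
  invisible(x)
}

#' Number of frames in a motion sequence
#' @param seq a `motion_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$positions)[1]

#' Duration of a motion sequence in seconds
#' @param seq a `motion_sequence`.
#' @return last minus first timestamp.
#' @export
duration <- function(seq) diff(range(seq$timestamps))

#' Per-emotion corpus manifest
#'
#' Counts recordings and averages durations per emotional state, in
#' canonical label order. Counts are conserved under re-ordering of the
#' corpus and sum to the total number of sequences (stored in the
#' `total` attribute).
#'
#' @param seqs list of `motion_sequence`.
#' @return data.frame with columns `emotion`, `n_samples`,
#'   `mean_duration_s`; attribute `total` holds the corpus size.
#' @export
corpus_manifest <- function(seqs) {
  lv <- emotion_levels(7)
  emo <- vapply(seqs, function(s) s$emotion, character(1))
  dur <- vapply(seqs, duration, numeric(1))
  n <- vapply(lv, function(e) sum(emo == e), integer(1))
  md <- vapply(lv, function(e) {
    if (any(emo == e)) mean(dur[emo == e]) else NA_real_
  }, numeric(1))
  out <- data.frame(
    emotion = lv, n_samples = unname(n), mean_duration_s = unname(md),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- length(seqs)
  out
}
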