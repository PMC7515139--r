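# Synthetic articulated gesture corpus.
#
# Sequences are produced by forward kinematics over the 25-joint skeleton
# tree: per-emotion archetypes drive smooth sinusoidal joint rotations
# (arms dominant, visible knee/ankle involvement), the root carries
# whole-body events (hops, backing away, sway), subjects differ in height
# and stance, and Gaussian sensor jitter is added with a larger sigma on
# hand joints. Bone lengths are exactly constant before jitter.

# parent-relative rest-pose offsets (meters, reference height 1.75 m),
# in body axes: x left, y up, z forward
.rest_offsets <- list(
  SpineMid = c(0, 0.26, 0), SpineShoulder = c(0, 0.25, 0),
  Neck = c(0, 0.09, 0), Head = c(0, 0.16, 0),
  ShoulderLeft = c(0.19, -0.03, 0), ElbowLeft = c(0.02, -0.28, 0),
  WristLeft = c(0.01, -0.25, 0), HandLeft = c(0, -0.08, 0),
  HandTipLeft = c(0, -0.07, 0), ThumbLeft = c(0.04, -0.03, 0),
  ShoulderRight = c(-0.19, -0.03, 0), ElbowRight = c(-0.02, -0.28, 0),
  WristRight = c(-0.01, -0.25, 0), HandRight = c(0, -0.08, 0),
  HandTipRight = c(0, -0.07, 0), ThumbRight = c(-0.04, -0.03, 0),
  HipLeft = c(0.09, -0.06, 0), KneeLeft = c(0.01, -0.42, 0),
  AnkleLeft = c(0, -0.40, 0), FootLeft = c(0, -0.06, 0.12),
  HipRight = c(-0.09, -0.06, 0), KneeRight = c(-0.01, -0.42, 0),
  AnkleRight = c(0, -0.40, 0), FootRight = c(0, -0.06, 0.12)
)

rot_axis_angle <- function(axis, theta) {
  a <- axis / vec_norm(axis)
  c <- cos(theta); s <- sin(theta); C <- 1 - c
  matrix(c(
    a[1] * a[1] * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2] * a[2] * C + c, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3] * a[3] * C + c
  ), 3, 3, byrow = TRUE)
}

# per-emotion movement archetypes. `joints` maps actuated joint -> rotation
# axis, involvement weight, phase offset and static bias (radians).
# `amp` is the archetype amplitude (radians), `tempo` the stroke rate (Hz).
# Fear and disgust deliberately share the "backing out, hands near head"
# motif so their confusion structure is realistic.
emotion_archetypes <- function() {
  j <- function(axis, w, phase = 0, bias = 0) {
    list(axis = axis, w = w, phase = phase, bias = bias)
  }
  X <- c(1, 0, 0); Z <- c(0, 0, 1); Y <- c(0, 1, 0)
  list(
    neutral = list(
      amp = 0.015, tempo = 0.25,
      joints = list(SpineMid = j(X, 1), ShoulderLeft = j(X, 0.4),
                    ShoulderRight = j(X, 0.4, pi), Neck = j(X, 0.4)),
      root = list(hop = 0, back = 0, sway = 0.004, yaw = 0.01)
    ),
    sadness = list(
      amp = 0.22, tempo = 0.6,
      joints = list(Neck = j(X, 0.8, 0, bias = 0.45),
                    SpineMid = j(X, 0.35, 0, bias = 0.18),
                    ShoulderLeft = j(X, 1.1, 0.4),
                    ShoulderRight = j(X, 1.1, 0.4 + pi),
                    ElbowLeft = j(X, 1.4, 0.8), ElbowRight = j(X, 1.4, 0.8),
                    KneeLeft = j(X, 0.25, 0), KneeRight = j(X, 0.25, pi)),
      root = list(hop = 0, back = 0, sway = 0.01, yaw = 0.02)
    ),
    surprise = list(
      amp = 0.45, tempo = 1.25,
      joints = list(ShoulderLeft = j(Z, 1.5, 0, bias = -0.5),
                    ShoulderRight = j(Z, 1.5, 0, bias = 0.5),
                    ElbowLeft = j(X, 1.0, 0.3, bias = 0.4),
                    ElbowRight = j(X, 1.0, 0.3, bias = 0.4),
                    Neck = j(X, 0.7, 0, bias = -0.25),
                    SpineMid = j(X, 0.35, 0, bias = -0.1),
                    KneeLeft = j(X, 0.4, 0), KneeRight = j(X, 0.4, 0)),
      root = list(hop = 0.015, back = 0.12, sway = 0.01, yaw = 0.03)
    ),
    fear = list(
      amp = 0.40, tempo = 0.9,
      joints = list(ElbowLeft = j(X, 1.6, 0, bias = 1.3),
                    ElbowRight = j(X, 1.6, 0.3, bias = 1.3),
                    ShoulderLeft = j(X, 1.0, 0, bias = 0.5),
                    ShoulderRight = j(X, 1.0, 0.3, bias = 0.5),
                    SpineMid = j(X, 0.5, 0, bias = 0.25),
                    KneeLeft = j(X, 0.6, 0, bias = 0.3),
                    KneeRight = j(X, 0.6, pi, bias = 0.3),
                    HipLeft = j(X, 0.3, 0), HipRight = j(X, 0.3, pi)),
      root = list(hop = 0, back = 0.35, sway = 0.02, yaw = 0.05)
    ),
    anger = list(
      amp = 0.55, tempo = 1.6,
      joints = list(ShoulderLeft = j(X, 1.4, 0), ShoulderRight = j(X, 1.4, pi),
                    ElbowLeft = j(X, 1.2, 0.5, bias = 0.6),
                    ElbowRight = j(X, 1.2, 0.5 + pi, bias = 0.6),
                    SpineMid = j(X, 0.6, 0, bias = 0.12),
                    KneeLeft = j(X, 0.8, 0), KneeRight = j(X, 0.8, pi),
                    HipLeft = j(X, 0.35, 0), HipRight = j(X, 0.35, pi)),
      root = list(hop = 0.01, back = 0, sway = 0.03, yaw = 0.12)
    ),
    disgust = list(
      amp = 0.38, tempo = 0.75,
      joints = list(ElbowLeft = j(X, 1.5, 0, bias = 1.1),
                    ElbowRight = j(X, 1.5, 0.4, bias = 1.1),
                    ShoulderLeft = j(X, 1.0, 0, bias = 0.4),
                    ShoulderRight = j(X, 1.0, 0.4, bias = 0.4),
                    Neck = j(Y, 0.6, 0, bias = 0.3),
                    SpineMid = j(Y, 0.3, 0, bias = 0.2),
                    KneeLeft = j(X, 0.45, 0, bias = 0.15),
                    KneeRight = j(X, 0.45, pi, bias = 0.15)),
      root = list(hop = 0, back = 0.22, sway = 0.015, yaw = 0.1)
    ),
    happiness = list(
      amp = 0.50, tempo = 1.1,
      joints = list(ShoulderLeft = j(Z, 1.3, 0, bias = -0.9),
                    ShoulderRight = j(Z, 1.3, pi, bias = 0.9),
                    ElbowLeft = j(X, 1.0, 0.4, bias = 0.5),
                    ElbowRight = j(X, 1.0, 0.4 + pi, bias = 0.5),
                    SpineMid = j(X, 0.3, 0, bias = -0.05),
                    KneeLeft = j(X, 0.7, 0), KneeRight = j(X, 0.7, 0),
                    Neck = j(X, 0.4, 0, bias = -0.1)),
      root = list(hop = 0.05, back = 0, sway = 0.02, yaw = 0.06)
    )
  )
}

#' Synthetic-corpus generator configuration
#'
#' Defaults mirror the corpus design the pipeline was built for:
#' 16 subjects x 7 emotions x 5 repetitions (560 recordings), 3.5-5 s
#' at 30 fps, subject heights spanning 1.55-1.92 m, and sensor jitter
#' that is four times larger on hand joints than on the rest of the body.
#'
#' @param n_subjects number of subjects (default 16).
#' @param n_repetitions repetitions per subject and emotion (default 5).
#' @param emotions emotions to generate (default all 7).
#' @param duration_range recording length range in seconds.
#' @param fps frame rate (default 30).
#' @param height_range subject height range in meters.
#' @param body_jitter_sd positional noise sigma for non-hand joints (m).
#' @param hand_jitter_sd positional noise sigma for hand joints (m).
#' @param orientation_noise_sd angular noise sigma (degrees) on emitted
#'   joint orientations (the estimated orientation stream of a real
#'   sensor is noisier than its positional stream).
#' @param seed integer RNG seed; generation is deterministic given it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 16, n_repetitions = 5,
                             emotions = emotion_levels(7),
                             duration_range = c(3.5, 5.0), fps = 30,
                             height_range = c(1.55, 1.92),
                             body_jitter_sd = 0.002,
                             hand_jitter_sd = 0.012,
                             orientation_noise_sd = 0.4, seed = 1) {
  stopifnot(n_subjects >= 1, n_repetitions >= 1, length(emotions) >= 1,
            all(emotions %in% emotion_levels(7)),
            length(duration_range) == 2, duration_range[1] > 0,
            diff(duration_range) >= 0, fps > 0,
            body_jitter_sd >= 0, hand_jitter_sd >= 0,
            orientation_noise_sd >= 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a labeled synthetic gesture corpus
#'
#' Builds `n_subjects x |emotions| x n_repetitions` sensor-space
#' recordings by forward kinematics (see the package vignette for the
#' motion model). Deterministic given `config$seed`. The ground-truth
#' manifest (per-recording subject, emotion, height, tempo, amplitude)
#' is attached as attribute `"manifest"`.
#'
#' @param config a [generator_config()].
#' @return list of `motion_sequence` in sensor space.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  arch <- emotion_archetypes()
  with_seed(config$seed, {
    heights <- stats::runif(config$n_subjects, config$height_range[1],
                            config$height_range[2])
    corpus <- list()
    manifest <- list()
    for (si in seq_len(config$n_subjects)) {
      subject <- sprintf("S%02d", si)
      base_x <- stats::runif(1, -0.3, 0.3)
      base_z <- stats::runif(1, 2.0, 2.8)
      base_yaw <- stats::runif(1, -25, 25)
      subj_amp <- stats::runif(1, 0.9, 1.1)
      for (emotion in config$emotions) {
        a <- arch[[emotion]]
        for (rep_i in seq_len(config$n_repetitions)) {
          dur <- stats::runif(1, config$duration_range[1],
                              config$duration_range[2])
          tempo <- a$tempo * stats::runif(1, 0.9, 1.1)
          amp <- a$amp * subj_amp * stats::runif(1, 0.85, 1.15)
          phase <- stats::runif(1, 0, 2 * pi)
          seq <- synth_sequence(
            subject, emotion, rep_i, heights[si], dur, config$fps,
            a, amp, tempo, phase, base_x, base_z, base_yaw,
            config$body_jitter_sd, config$hand_jitter_sd,
            config$orientation_noise_sd)
          corpus[[length(corpus) + 1L]] <- seq
          manifest[[length(manifest) + 1L]] <- data.frame(
            sequence_id = seq$sequence_id, subject = subject,
            emotion = emotion, repetition = rep_i,
            height = heights[si], duration = dur,
            n_frames = n_frames(seq), tempo = tempo, amplitude = amp,
            stringsAsFactors = FALSE)
        }
      }
    }
    attr(corpus, "manifest") <- do.call(rbind, manifest)
    corpus
  })
}

synth_sequence <- function(subject, emotion, rep_i, height, dur, fps,
                           arch, amp, tempo, phase, base_x, base_z,
                           base_yaw, body_sd, hand_sd, ori_sd) {
  nf <- max(2L, round(dur * fps) + 1L)
  ts <- (seq_len(nf) - 1L) / fps
  s <- height / 1.75
  offsets <- lapply(.rest_offsets, function(o) o * s)
  par_idx <- joint_index(.joint_parents[.joint_names])
  topo <- topo_joint_order()
  hand_idx <- joint_index(hand_joints())
  no_ori <- joint_index(no_orientation_joints())
  env <- sin(pi * ts / dur)^2          # ramp in and out of the rest pose
  pos <- array(NA_real_, c(nf, 25, 3))
  ori <- array(NA_real_, c(nf, 25, 3))
  base_pos <- c(base_x, 1.02 * s, base_z)
  root_axis <- c(0, 1, 0)
  for (k in seq_len(nf)) {
    t <- ts[k]
    e <- env[k]
    yaw <- deg2rad(base_yaw) +
      arch$root$yaw * amp / max(arch$amp, 1e-9) *
        sin(2 * pi * tempo * t + phase) * e
    Rroot <- rot_axis_angle(root_axis, yaw)
    hop <- arch$root$hop * max(0, sin(2 * pi * tempo * t + phase))^2 * e
    sway <- arch$root$sway * sin(2 * pi * 0.3 * t + phase) * e
    back <- arch$root$back * (t / dur) * e
    p_root <- base_pos + c(sway, hop, back)
    Rg <- vector("list", 25)
    Rg[[1]] <- Rroot
    pos[k, 1, ] <- p_root
    for (j in topo[-1]) {
      nm <- .joint_names[j]
      p <- par_idx[j]
      spec <- arch$joints[[nm]]
      Rl <- if (is.null(spec)) NULL else {
        theta <- spec$bias * e +
          amp * spec$w * sin(2 * pi * tempo * t + phase + spec$phase) * e
        rot_axis_angle(spec$axis, theta)
      }
      Rg[[j]] <- if (is.null(Rl)) Rg[[p]] else Rg[[p]] %*% Rl
      pos[k, j, ] <- pos[k, p, ] + Rg[[p]] %*% offsets[[nm]]
    }
    # a joint's emitted orientation is the rotation of the bone *into*
    # it, i.e. the cumulative rotation of the parent chain excluding the
    # joint's own actuation (Kinect-style bone orientations); the root
    # emits its own rotation
    for (j in seq_len(25)) {
      if (!(j %in% no_ori)) {
        ori[k, j, ] <- rotmat_to_euler(if (j == 1L) Rg[[1L]]
                                       else Rg[[par_idx[j]]])
      }
    }
  }
  # sensor jitter, larger on hand joints; angular noise on orientations
  noise <- array(stats::rnorm(nf * 25 * 3, sd = body_sd), c(nf, 25, 3))
  noise[, hand_idx, ] <- noise[, hand_idx, ] / max(body_sd, 1e-12) * hand_sd
  pos <- pos + noise
  if (ori_sd > 0) {
    keep_na <- is.na(ori)
    ori <- ori + array(stats::rnorm(nf * 25 * 3, sd = ori_sd),
                       c(nf, 25, 3))
    ori[keep_na] <- NA_real_
  }
  motion_sequence(pos, ts, subject, emotion, rep_i, orientations = ori,
                  space = "sensor")
}

#' Simulate tracking failures
#'
#' Flags a Bernoulli(`drop_rate`) subset of recordings as low quality and
#' corrupts them the way real skeletal tracking fails: one arm or leg
#' chain either freezes from a random frame onward or is swapped with its
#' contralateral counterpart. Deterministic given `seed`.
#'
#' @param corpus list of `motion_sequence`.
#' @param drop_rate probability in `[0, 1]` that a recording is degraded.
#' @param seed RNG seed.
#' @return corpus with `quality = FALSE` on degraded sequences.
#' @export
degrade <- function(corpus, drop_rate, seed = 1) {
  stopifnot(drop_rate >= 0, drop_rate <= 1)
  limbs <- list(
    arm_left = c("ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
                 "HandTipLeft", "ThumbLeft"),
    arm_right = c("ShoulderRight", "ElbowRight", "WristRight", "HandRight",
                  "HandTipRight", "ThumbRight"),
    leg_left = c("HipLeft", "KneeLeft", "AnkleLeft", "FootLeft"),
    leg_right = c("HipRight", "KneeRight", "AnkleRight", "FootRight")
  )
  with_seed(seed, {
    lapply(corpus, function(s) {
      if (stats::runif(1) >= drop_rate) return(s)
      nf <- n_frames(s)
      mode <- sample(c("freeze", "swap"), 1)
      if (mode == "freeze") {
        limb <- joint_index(limbs[[sample(length(limbs), 1)]])
        from <- sample(seq_len(nf - 1), 1) + 1L
        for (k in from:nf) s$positions[k, limb, ] <- s$positions[from - 1L, limb, ]
      } else {
        l <- joint_index(limbs$arm_left); r <- joint_index(limbs$arm_right)
        tmp <- s$positions[, l, ]
        s$positions[, l, ] <- s$positions[, r, ]
        s$positions[, r, ] <- tmp
      }
      s$quality <- FALSE
      s
    })
  })
}

#' Drop low-quality recordings
#'
#' Removes sequences flagged `quality = FALSE` (see [degrade()]), the
#' analogue of rejecting samples with inaccurate extremity tracking.
#'
#' @param corpus list of `motion_sequence`.
#' @return filtered corpus; warns if everything was rejected.
#' @export
reject_low_quality <- function(corpus) {
  keep <- vapply(corpus, function(s) isTRUE(s$quality), logical(1))
  out <- corpus[keep]
  if (!length(out) && length(corpus)) {
    warning("all recordings were flagged low quality", call. = FALSE)
  }
  attr(out, "manifest") <- NULL
  out
}
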