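# Projection from sensor space into the body-local [u,v,w] frame and into
# per-joint hierarchical (parent-relative) coordinates.

root_rotations <- function(seq, euler_order, missing_root) {
  nf <- n_frames(seq)
  Rs <- vector("list", nf)
  prev <- diag(3)
  for (k in seq_len(nf)) {
    ang <- seq$orientations[k, 1, ]
    if (anyNA(ang)) {
      if (missing_root == "error") {
        stop("SpineBase orientation missing in frame ", k,
             "; pass missing_root = \"identity\" to substitute the identity",
             call. = FALSE)
      }
      R <- diag(3)
    } else {
      # gimbal-adjacent root angles: keep the previous frame's rotation
      # (identity for a degenerate first frame) for continuity
      if (abs(cos(deg2rad(ang[1]))) < 1e-6) {
        R <- prev
      } else {
        R <- euler_to_rotmat(ang, euler_order)
      }
    }
    Rs[[k]] <- R
    prev <- R
  }
  Rs
}

#' Project a sequence into the body-local frame
#'
#' Re-expresses every joint relative to the SpineBase root: in each frame,
#' non-root positions become `t(R_root) %*% (p - p_root)` where `R_root` is
#' the root orientation, so the u axis points to the subject's left, v up
#' and w forward regardless of where the sensor stood. Non-root
#' orientations are re-expressed relative to the root rotation (disable
#' with `relative_orientations = FALSE` to keep sensor-frame angles). The
#' root joint's position channel is replaced by its displacement relative
#' to the first frame (and its orientation channel by the rotation change),
#' preserving whole-body events such as hops or squats.
#'
#' @param seq `motion_sequence` with `space == "sensor"`.
#' @param relative_orientations re-express non-root orientations relative
#'   to the root rotation (default) or leave them in the sensor frame.
#' @param missing_root `"error"` (default) or `"identity"` to substitute
#'   an identity rotation when the root orientation is absent.
#' @param euler_order intrinsic Euler composition order (see
#'   [euler_to_rotmat()]).
#' @return `motion_sequence` with `space == "body_local"` and a
#'   `root_delta` component (`displacement`, `rotation`; both frames x 3,
#'   zero in the first frame).
#' @export
to_body_frame <- function(seq, relative_orientations = TRUE,
                          missing_root = c("error", "identity"),
                          euler_order = "yxz") {
  missing_root <- match.arg(missing_root)
  if (seq$space != "sensor") {
    stop("to_body_frame() expects a sensor-space sequence (got space = '",
         seq$space, "')", call. = FALSE)
  }
  nf <- n_frames(seq)
  Rs <- root_rotations(seq, euler_order, missing_root)
  pos <- seq$positions
  ori <- seq$orientations
  new_pos <- pos
  new_ori <- ori
  disp <- matrix(0, nf, 3)
  rot_delta <- matrix(0, nf, 3)
  p0_1 <- pos[1, 1, ]
  R1 <- Rs[[1]]
  for (k in seq_len(nf)) {
    R <- Rs[[k]]
    p0 <- pos[k, 1, ]
    # (R^T (p - p0))^T = (p - p0)^T R
    new_pos[k, , ] <- sweep(pos[k, , ], 2, p0) %*% R
    disp[k, ] <- p0 - p0_1
    rot_delta[k, ] <- rotmat_to_euler(t(R1) %*% R, euler_order)
    if (relative_orientations) {
      for (j in 2:25) {
        a <- ori[k, j, ]
        if (!anyNA(a)) {
          new_ori[k, j, ] <- rotmat_to_euler(
            t(R) %*% euler_to_rotmat(a, euler_order), euler_order)
        }
      }
    }
  }
  new_pos[, 1, ] <- disp
  new_ori[, 1, ] <- rot_delta
  out <- seq
  out$positions <- new_pos
  out$orientations <- new_ori
  out$space <- "body_local"
  out$root_delta <- list(displacement = disp, rotation = rot_delta)
  out
}

#' Per-joint hierarchical local coordinates
#'
#' Expresses each non-root joint relative to its parent in the skeleton
#' tree (e.g. the wrist in the elbow's coordinate system): the
#' parent-relative offset is rotated into the parent's orientation frame
#' when the parent carries one, and left unrotated otherwise. The root maps
#' to its displacement relative to the first frame. This is the coordinate
#' system used by the quantity-of-motion statistic.
#'
#' @param seq a `motion_sequence` in any space.
#' @param euler_order intrinsic Euler composition order.
#' @return numeric array `[frames, 25, 3]` with joint-name dimnames.
#' @export
to_hierarchical_local <- function(seq, euler_order = "yxz") {
  nf <- n_frames(seq)
  par_idx <- joint_index(.joint_parents[.joint_names])
  out <- array(0, c(nf, 25, 3),
               dimnames = list(NULL, .joint_names, c("x", "y", "z")))
  pos <- seq$positions
  in_sensor <- seq$space == "sensor"
  # geometric positions: in the body-local frames the stored root row is a
  # displacement channel; the root itself sits at the origin
  geo <- pos
  if (!in_sensor) geo[, 1, ] <- 0
  for (k in seq_len(nf)) {
    for (j in 2:25) {
      p <- par_idx[j]
      v <- geo[k, j, ] - geo[k, p, ]
      a <- if (p == 1 && !in_sensor) rep(NA_real_, 3) else
        seq$orientations[k, p, ]
      if (!anyNA(a)) {
        v <- crossprod(euler_to_rotmat(a, euler_order), v)[, 1]
      }
      out[k, j, ] <- v
    }
  }
  if (!is.null(seq$root_delta)) {
    out[, 1, ] <- seq$root_delta$displacement
  } else {
    out[, 1, ] <- sweep(pos[, 1, , drop = FALSE], 3, pos[1, 1, ])[, 1, ]
  }
  out
}
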