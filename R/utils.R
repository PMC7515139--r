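# internal numeric helpers: rotations, seeding

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_about_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

rot_about_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s,
           0, 1, 0,
           -s, 0, c), 3, 3, byrow = TRUE)
}

rot_about_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Euler angles (degrees) to rotation matrix
#'
#' Angles are stored per axis as `c(x, y, z)` (pitch about the left/u axis,
#' yaw about the up/v axis, roll about the forward/w axis). `order` gives
#' the intrinsic composition order; the default `"yxz"` applies yaw, then
#' pitch, then roll.
#'
#' @param angles_deg numeric length-3, degrees, per-axis `c(x, y, z)`.
#' @param order three-character string over `x`, `y`, `z`.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rotmat <- function(angles_deg, order = "yxz") {
  stopifnot(length(angles_deg) == 3, is.finite(angles_deg))
  ax <- strsplit(order, "")[[1]]
  if (length(ax) != 3 || !setequal(ax, c("x", "y", "z"))) {
    stop("`order` must be a permutation of 'x', 'y', 'z'", call. = FALSE)
  }
  a <- deg2rad(angles_deg)
  R <- diag(3)
  for (axis in ax) {
    R <- R %*% switch(axis,
      x = rot_about_x(a[1L]),
      y = rot_about_y(a[2L]),
      z = rot_about_z(a[3L])
    )
  }
  R
}

#' Rotation matrix to Euler angles (degrees)
#'
#' Inverse of [euler_to_rotmat()] for the default `"yxz"` intrinsic order.
#' Returns per-axis angles `c(x, y, z)`.
#'
#' @param R 3x3 rotation matrix.
#' @param order intrinsic order; only `"yxz"` is supported for extraction.
#' @return numeric length-3, degrees.
#' @export
rotmat_to_euler <- function(R, order = "yxz") {
  if (order != "yxz") {
    stop("Euler extraction is implemented for order 'yxz' only", call. = FALSE)
  }
  # M = Ry(y) Rx(x) Rz(z):
  #   M[2,3] = -sin(x); M[1,3] = sin(y)cos(x); M[3,3] = cos(y)cos(x)
  #   M[2,1] = cos(x)sin(z); M[2,2] = cos(x)cos(z)
  sx <- -R[2, 3]
  sx <- max(-1, min(1, sx))
  x <- asin(sx)
  if (abs(cos(x)) < 1e-8) {
    # gimbal: y and z degenerate; put everything in y
    y <- atan2(-R[3, 1], R[1, 1])
    z <- 0
  } else {
    y <- atan2(R[1, 3], R[3, 3])
    z <- atan2(R[2, 1], R[2, 2])
  }
  rad2deg(c(x, y, z))
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

vec_norm <- function(v) sqrt(sum(v^2))

# row-wise Euclidean norms of a matrix
row_norms <- function(m) sqrt(rowSums(m^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
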