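# Independent brute-force oracles and fixture builders. Everything here is
# written from the definitions, independently of the package internals it
# is used to check.

# --- curve simplification oracle (plain recursion) -----------------------

oracle_seg_dist <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab * ab)
  t <- if (denom > 0) sum((p - a) * ab) / denom else 0
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

oracle_simplify <- function(points, eps) {
  n <- nrow(points)
  rec <- function(i, j) {
    if (j - i < 2) return(c(i, j))
    d <- vapply((i + 1):(j - 1), function(k) {
      oracle_seg_dist(points[k, ], points[i, ], points[j, ])
    }, numeric(1))
    m <- which.max(d)
    if (d[m] > eps) {
      s <- i + m
      c(rec(i, s), rec(s, j))
    } else {
      c(i, j)
    }
  }
  sort(unique(rec(1, n)))
}

# --- rotation oracle (independent Euler convention) ----------------------

oracle_rotmat <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry %*% Rx %*% Rz
}

# --- hierarchical-local oracle (explicit per-joint loop) ------------------

oracle_hierarchical <- function(seq) {
  tax <- kinect_joints()
  nf <- dim(seq$positions)[1]
  out <- array(0, c(nf, 25, 3))
  geo <- seq$positions
  if (seq$space != "sensor") geo[, 1, ] <- 0
  for (k in seq_len(nf)) {
    for (j in 2:25) {
      p <- match(tax$parent[j], tax$name)
      v <- geo[k, j, ] - geo[k, p, ]
      ang <- if (p == 1 && seq$space != "sensor") rep(NA_real_, 3)
             else seq$orientations[k, p, ]
      if (!anyNA(ang)) v <- t(oracle_rotmat(ang)) %*% v
      out[k, j, ] <- v
    }
  }
  if (!is.null(seq$root_delta)) {
    out[, 1, ] <- seq$root_delta$displacement
  } else {
    for (k in seq_len(nf)) out[k, 1, ] <- seq$positions[k, 1, ] -
      seq$positions[1, 1, ]
  }
  out
}

# --- quantity-of-motion oracle (double loop over recordings/frames) ------

oracle_qom <- function(corpus) {
  emo <- vapply(corpus, function(s) s$emotion, character(1))
  out <- matrix(NA_real_, 25, 7,
                dimnames = list(kinect_joints()$name, emotion_levels(7)))
  for (e in emotion_levels(7)) {
    recs <- corpus[emo == e]
    if (!length(recs)) next
    acc <- numeric(25)
    for (s in recs) {
      H <- oracle_hierarchical(s)
      nf <- dim(H)[1]
      per_joint <- numeric(25)
      for (f in 2:nf) {
        for (j in 1:25) {
          per_joint[j] <- per_joint[j] +
            sqrt(sum((H[f, j, ] - H[f - 1, j, ])^2))
        }
      }
      acc <- acc + per_joint / (nf - 1)
    }
    out[, e] <- acc / length(recs)
  }
  out
}

# --- fixture builders -----------------------------------------------------

# static skeleton: joint i at a fixed, distinct location; strictly
# monotone timestamps at 30 fps
static_positions <- function() {
  base <- cbind(
    x = seq(-0.6, 0.6, length.out = 25),
    y = seq(0.4, 1.8, length.out = 25),
    z = seq(2.4, 2.6, length.out = 25)
  )
  base[21, ] <- base[1, ] + c(0, 0.5, 0)  # SpineShoulder 0.5 m above root
  base
}

make_static_seq <- function(nf = 5, subject = "S01", emotion = "neutral",
                            repetition = 1, space = "sensor",
                            orient_root = c(0, 0, 0), spine = NULL) {
  P <- static_positions()
  if (!is.null(spine)) P[21, ] <- P[1, ] + c(0, spine, 0)
  pos <- array(rep(P, each = nf), c(nf, 25, 3))
  ori <- array(NA_real_, c(nf, 25, 3))
  for (j in setdiff(1:25, match(no_orientation_joints(),
                                kinect_joints()$name))) {
    ori[, j, ] <- 0
  }
  ori[, 1, ] <- matrix(orient_root, nf, 3, byrow = TRUE)
  if (space != "sensor") {
    # root-relative coordinates with the root row as displacement channel
    root <- pos[1, 1, ]
    pos <- sweep(pos, 3, root)
    pos[, 1, ] <- 0
  }
  motion_sequence(pos, (seq_len(nf) - 1) / 30, subject, emotion,
                  repetition, orientations = ori, space = space)
}

# apply a rigid motion (rotation R then translation tr) to a whole
# sensor-space sequence, rotating orientations consistently
apply_rigid <- function(seq, R, tr) {
  nf <- dim(seq$positions)[1]
  for (k in seq_len(nf)) {
    seq$positions[k, , ] <- t(R %*% t(seq$positions[k, , ])) +
      matrix(tr, 25, 3, byrow = TRUE)
    for (j in 1:25) {
      a <- seq$orientations[k, j, ]
      if (!anyNA(a)) {
        M <- R %*% oracle_rotmat(a)
        seq$orientations[k, j, ] <- oracle_euler_from(M)
      }
    }
  }
  seq
}

# inverse of oracle_rotmat (yxz), written from the matrix entries
oracle_euler_from <- function(M) {
  x <- asin(max(-1, min(1, -M[2, 3])))
  if (abs(cos(x)) < 1e-8) {
    y <- atan2(-M[3, 1], M[1, 1]); z <- 0
  } else {
    y <- atan2(M[1, 3], M[3, 3]); z <- atan2(M[2, 1], M[2, 2])
  }
  c(x, y, z) * 180 / pi
}

# random smooth-ish 3D trajectory for property tests
random_trajectory <- function(n = 50, scale = 0.3) {
  t <- seq(0, 1, length.out = n)
  drift <- cbind(
    cumsum(rnorm(n, sd = scale / 10)),
    sin(2 * pi * runif(1, 0.5, 2) * t) * runif(1, 0, scale),
    cumsum(rnorm(n, sd = scale / 10))
  )
  drift + matrix(rnorm(3 * n, sd = 0.01), n, 3)
}

# small shared corpora, generated once per test run
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(
        generator_config(n_subjects = 2, n_repetitions = 1,
                         duration_range = c(1.0, 1.5), seed = 42))
    }
    cache
  }
})

# numeric gradient of a scalar loss wrt each parameter entry
numeric_grad <- function(loss_fn, params, eps = 1e-5) {
  grads <- params
  for (nm in names(params)) {
    g <- params[[nm]]
    for (i in seq_along(g)) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      g[i] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
    }
    grads[[nm]] <- g
  }
  grads
}
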