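test_that("subject scale is the median spine length over neutral frames", {
  s <- make_static_seq(nf = 5, space = "body_local", spine = 0.5)
  sc <- compute_subject_scale(list(s))
  expect_equal(sc$spine_length, 0.5, tolerance = 1e-12)

  # odd-count median over per-frame distances {0.48, 0.50, 0.52}
  s3 <- make_static_seq(nf = 3, space = "body_local", spine = 0.5)
  s3$positions[1, 21, ] <- c(0, 0.48, 0)
  s3$positions[2, 21, ] <- c(0, 0.50, 0)
  s3$positions[3, 21, ] <- c(0, 0.52, 0)
  expect_equal(compute_subject_scale(list(s3))$spine_length, 0.50)

  # jittered multi-recording subject vs brute-force pooled median
  set.seed(5)
  seqs <- lapply(1:3, function(i) {
    q <- make_static_seq(nf = 7, space = "body_local", spine = 0.5)
    q$positions[, 21, ] <- q$positions[, 21, ] + rnorm(21, sd = 0.01)
    q
  })
  pooled <- unlist(lapply(seqs, function(q) {
    apply(q$positions[, 21, ], 1, function(v) sqrt(sum(v^2)))
  }))
  expect_equal(compute_subject_scale(seqs)$spine_length, median(pooled))
})

test_that("scale computation rejects unusable inputs", {
  expect_error(compute_subject_scale(list()), "no neutral recordings")
  s <- make_static_seq(space = "body_local", emotion = "anger")
  expect_error(compute_subject_scale(list(s)), "non-neutral")
  expect_error(
    compute_subject_scale(list(make_static_seq(space = "body_local"),
                               make_static_seq(space = "body_local",
                                               subject = "S02"))),
    "multiple subjects")
  expect_error(compute_subject_scale(list(make_static_seq())), "body-local")
})

test_that("unit scale is the identity; wrong space is rejected", {
  s <- make_static_seq(nf = 4, space = "body_local")
  out <- scale_normalize(s, 1)
  expect_equal(out$positions, s$positions)
  expect_identical(out$space, "scale_normalized")
  expect_error(scale_normalize(out, 1), "body-local")
  expect_error(scale_normalize(make_static_seq(), 1), "body-local")
})

test_that("uniformly scaled subjects normalise to identical sequences", {
  a <- to_body_frame(tiny_corpus()[[5]])
  # subject B: same motion, skeleton scaled x1.3 about the root
  b <- a
  b$positions <- a$positions * 1.3
  b$root_delta$displacement <- a$root_delta$displacement * 1.3
  sa <- 0.5; sb <- 0.5 * 1.3
  na_ <- scale_normalize(a, sa)
  nb <- scale_normalize(b, sb)
  expect_lt(max(abs(na_$positions - nb$positions)), 1e-9)
})

test_that("after normalisation the neutral spine length is 1", {
  corpus <- tiny_corpus()
  body <- lapply(corpus, to_body_frame)
  subj <- vapply(body, function(s) s$subject, character(1))
  emo <- vapply(body, function(s) s$emotion, character(1))
  neutral <- body[subj == "S01" & emo == "neutral"]
  sc <- compute_subject_scale(neutral)
  norm <- lapply(neutral, scale_normalize, scale = sc)
  d <- unlist(lapply(norm, function(s) {
    apply(s$positions[, 21, ], 1, function(v) sqrt(sum(v^2)))
  }))
  expect_equal(median(d), 1, tolerance = 1e-12)
})

test_that("a jump survives normalisation in the root displacement channel", {
  s <- make_static_seq(nf = 30, space = "sensor")
  t <- seq(0, 1, length.out = 30)
  hop <- 0.15 * pmax(0, sin(2 * pi * t))^2
  s$positions[, , 2] <- s$positions[, , 2] + hop  # whole body rises
  b <- to_body_frame(s)
  n <- scale_normalize(b, 0.5)
  expect_gt(max(abs(n$root_delta$displacement[, 2])), 0.2)
  # non-root joints stay still in the body frame during the hop
  expect_lt(max(abs(n$positions[, 2, 2] - n$positions[1, 2, 2])), 1e-9)
})

test_that("padding unifies lengths, masks real rows, conserves values", {
  s <- make_static_seq(nf = 6, space = "body_local")
  sn <- scale_normalize(s, 0.5)
  kf3 <- structure(list(indices = c(1L, 3L, 6L), error_rate = 0.03,
                        joints = nonhand_joints()),
                   class = "keyframe_sequence")
  kf5 <- structure(list(indices = c(1L, 2L, 3L, 5L, 6L), error_rate = 0.03,
                        joints = nonhand_joints()),
                   class = "keyframe_sequence")
  m3 <- compose_features(sn, "P", kf3)
  m5 <- compose_features(sn, "P", kf5)
  ds <- pad_sequences(list(m3, m5))
  expect_equal(dim(ds$x), c(2, 5, 58))
  expect_equal(ds$mask[1, ], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(ds$mask[2, ], rep(TRUE, 5))
  expect_identical(ds$x[1, 1:3, ], unclass(m3), ignore_attr = TRUE)
  expect_true(all(ds$x[1, 4:5, ] == 0))
  # conservation: total real rows equals pre-pad row count
  expect_equal(sum(ds$mask), nrow(m3) + nrow(m5))

  same <- pad_sequences(list(m5, m5))
  expect_true(all(same$mask))
})

test_that("z-scoring yields exact zero mean / unit sd over real rows", {
  corpus <- tiny_corpus()
  ds <- prepare_dataset(corpus, "P", 0.05)
  z <- suppressWarnings(zscore_normalize(ds))
  real <- affmotion:::real_rows(z)
  mu <- colMeans(real)
  sdv <- apply(real, 2, sd)
  expect_lt(max(abs(mu)), 1e-9)
  constant <- apply(real, 2, function(v) diff(range(v)) == 0)
  expect_lt(max(abs(sdv[!constant] - 1)), 1e-9)
  # pads remain exactly zero
  expect_true(all(z$x[!z$mask] == 0))
})

test_that("z-scoring is idempotent and zeroes constant features", {
  corpus <- tiny_corpus()
  ds <- prepare_dataset(corpus, "P", 0.05)
  z1 <- suppressWarnings(zscore_normalize(ds))
  z2 <- suppressWarnings(zscore_normalize(z1))
  expect_lt(max(abs(z2$x - z1$x)), 1e-9)

  ds$x[, , 3] <- ds$x[, , 3] * 0 + 5  # constant feature
  ds$x[!ds$mask] <- 0
  expect_warning(z3 <- zscore_normalize(ds), "zero-variance")
  expect_true(all(z3$x[, , 3][ds$mask] == 0))
})

test_that("train-fitted statistics apply unchanged to held-out data", {
  corpus <- tiny_corpus()
  ds <- prepare_dataset(corpus, "PU", 0.05)
  tr <- affmotion:::subset_dataset(ds, ds$subjects == "S01")
  te <- affmotion:::subset_dataset(ds, ds$subjects == "S02")
  st <- fit_zscore(tr)
  te_z <- zscore_normalize(te, st)
  # held-out rows transformed with the training moments, not their own
  real_te <- affmotion:::real_rows(te)
  manual <- sweep(sweep(real_te, 2, st$center), 2, st$scale, `/`)
  expect_equal(affmotion:::real_rows(te_z), manual, tolerance = 1e-12)
})
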