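test_that("feature sets reproduce the standard per-keyframe widths", {
  s <- scale_normalize(make_static_seq(nf = 4, space = "body_local"), 0.5)
  expected <- c(P = 58, O = 58, PO = 115, PU = 34, OU = 34, POU = 67)
  for (set_id in names(expected)) {
    m <- compose_features(s, set_id)
    expect_equal(ncol(m), unname(expected[set_id]))
    expect_equal(nrow(m), 4)
    expect_equal(feature_set_info(set_id)$expected_count,
                 unname(expected[set_id]))
  }
  # the identity behind the counts: 3 channels x joints + 1, with
  # PO = P + O - 1 (one shared temporal channel)
  expect_equal(expected[["PO"]], expected[["P"]] + expected[["O"]] - 1)
  expect_equal(expected[["P"]], 3 * 19 + 1)
  expect_equal(expected[["PU"]], 3 * 11 + 1)
})

test_that("feature composition fills orientations and the time channel", {
  s <- scale_normalize(make_static_seq(nf = 3, space = "body_local"), 0.5)
  m <- compose_features(s, "PO")
  expect_false(any(is.na(m)))
  # zero-filled orientation channels for joints the sensor skips
  expect_true(all(m[, "Head.ox"] == 0))
  expect_true(all(m[, "KneeLeft.oy"] == 0))
  # temporal channel normalised to [0, 1]
  expect_equal(unname(m[, "t_norm"]), c(0, 0.5, 1))
  # no hand joints anywhere
  expect_false(any(grepl("HandTip|Thumb|Hand(Left|Right)", colnames(m))))

  kf <- structure(list(indices = c(1L, 3L), error_rate = 0.03,
                       joints = nonhand_joints()),
                  class = "keyframe_sequence")
  m2 <- compose_features(s, "P", kf)
  expect_equal(nrow(m2), 2)
  expect_equal(unname(m2[, "t_norm"]), c(0, 1))

  expect_error(compose_features(s, "XYZ"))
  expect_error(compose_features(make_static_seq(), "P"), "scale-normalized")
  expect_warning(compose_features(s, "P", temporal_channel = FALSE),
                 "deviates")
})

test_that("quantity of motion: stationary and constant-step cases", {
  s <- make_static_seq(nf = 11, emotion = "anger")
  wr <- match("WristRight", kinect_joints()$name)
  # wrist advances exactly 0.01 m per transition in parent-local coords
  s$positions[, wr, 1] <- s$positions[1, wr, 1] + 0.01 * (0:10)
  qom <- quantity_of_motion(list(s))
  expect_equal(qom[wr, "anger"], 0.01, tolerance = 1e-12)
  # the wrist's child also moves by the step in wrist-relative coordinates
  hr <- match("HandRight", kinect_joints()$name)
  expect_equal(qom[hr, "anger"], 0.01, tolerance = 1e-12)
  still <- setdiff(seq_len(25), c(wr, hr))
  expect_true(all(qom[still, "anger"] == 0))
  expect_true(all(is.na(qom[, "fear"])))

  # frame-count normalisation divides by F instead of F - 1
  qom_f <- quantity_of_motion(list(s), normalize_by = "frames")
  expect_equal(qom_f[wr, "anger"], 0.01 * 10 / 11, tolerance = 1e-12)
})

test_that("quantity of motion matches the double-loop oracle", {
  set.seed(77)
  corpus <- generate_corpus(
    generator_config(n_subjects = 3, n_repetitions = 1,
                     duration_range = c(1, 1.3), seed = 99))
  qom <- quantity_of_motion(corpus)
  expect_lt(max(abs(qom - oracle_qom(corpus))), 1e-12)
  expect_true(all(qom >= 0))
})

test_that("quantity of motion is invariant to global translation", {
  corpus <- tiny_corpus()[c(3, 10)]
  shifted <- lapply(corpus, apply_rigid, R = diag(3), tr = c(4, -1, 2))
  q0 <- quantity_of_motion(corpus)
  q1 <- quantity_of_motion(shifted)
  expect_lt(max(abs(q0 - q1), na.rm = TRUE), 1e-9)
})

test_that("wrist motion dominates spine motion for non-neutral emotions", {
  corpus <- tiny_corpus()
  qom <- quantity_of_motion(corpus)
  wrists <- c("WristLeft", "WristRight")
  spine <- c("SpineMid", "SpineShoulder")
  for (e in setdiff(emotion_levels(7), "neutral")) {
    expect_gt(mean(qom[wrists, e]), mean(qom[spine, e]))
  }
})

test_that("heat-map variants subset rows stably", {
  corpus <- tiny_corpus()[1:7]
  qom <- quantity_of_motion(corpus)
  full <- qom_heatmap(qom)
  nh <- qom_heatmap(qom, exclude_hands = TRUE)
  expect_equal(dim(full), c(25, 7))
  expect_equal(dim(nh), c(19, 7))
  expect_identical(rownames(nh), setdiff(rownames(full), hand_joints()))
  expect_identical(colnames(full), unname(emotion_abbreviations()))
  # all-zero table renders uniformly
  zero <- qom * 0
  expect_true(all(qom_heatmap(zero) == 0, na.rm = TRUE))
})

test_that("baseline features: stationary and drift closed forms", {
  s <- scale_normalize(make_static_seq(nf = 10, space = "body_local"), 0.5)
  f <- extract_baseline_features(s)
  expect_equal(unname(f["vel_mean"]), 0)
  expect_equal(unname(f["acc_max"]), 0)
  expect_equal(unname(f["kinetic"]), 0)
  expect_gt(unname(f["bbox_volume_mean"]), 0)
  expect_equal(unname(f["bbox_volume_mean"]), unname(f["bbox_volume_max"]))

  # uniform drift of one joint: mean speed has a closed form,
  # acceleration stays 0
  s2 <- s
  wr <- match("WristRight", kinect_joints()$name)
  s2$positions[, wr, 1] <- s2$positions[1, wr, 1] + 0.02 * (0:9)
  f2 <- extract_baseline_features(s2)
  dt <- 1 / 30
  expect_equal(unname(f2["vel_mean"]), (0.02 / dt) / 19, tolerance = 1e-9)
  expect_equal(unname(f2["acc_max"]), 0, tolerance = 1e-9)

  # homogeneity: doubling coordinates quadruples the kinetic proxy
  s3 <- s2
  s3$positions <- s3$positions * 2
  f3 <- extract_baseline_features(s3)
  expect_equal(unname(f3["kinetic"]), 4 * unname(f2["kinetic"]),
               tolerance = 1e-9)

  short <- scale_normalize(make_static_seq(nf = 2, space = "body_local"), 0.5)
  expect_error(extract_baseline_features(short), "at least 3 frames")
})

test_that("baseline table covers the corpus with finite features", {
  corpus <- tiny_corpus()
  body <- lapply(corpus, to_body_frame)
  norm <- lapply(body, scale_normalize, scale = 0.45)
  tbl <- baseline_feature_table(norm)
  expect_equal(nrow(tbl), length(corpus))
  expect_true(all(is.finite(as.matrix(tbl[, 1:15]))))
  expect_true(all(emotion_levels(7) %in% tbl$emotion))
})
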