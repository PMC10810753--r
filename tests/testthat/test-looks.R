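test_that("a solid run of face samples yields a single face look", {
  tr <- make_trial_from_labels(rep("face", 100))
  looks <- detect_looks(tr)
  expect_equal(nrow(looks), 1)
  expect_equal(looks$label, "face")
  expect_equal(looks$n_samples, 100)
})

test_that("runs shorter than the minimum are discarded", {
  # face/bird alternating singles: no run reaches 3 samples
  tr <- make_trial_from_labels(rep(c("face", "bird"), 20))
  expect_equal(nrow(detect_looks(tr)), 0)
  # bird singleton inside face runs never becomes a look
  tr2 <- make_trial_from_labels(c(rep("face", 10), "bird", rep("face", 10)))
  looks <- detect_looks(tr2)
  expect_false("bird" %in% looks$label)
  expect_equal(nrow(looks), 2)  # the valid bird sample splits the face run
})

test_that("one invalid sample inside a run is bridged, two are not", {
  labs <- c(rep("face", 5), NA, rep("face", 5))
  val <- c(rep(1L, 5), 0L, rep(1L, 5))
  looks <- detect_looks(make_trial_from_labels(labs, valid = val))
  expect_equal(nrow(looks), 1)
  expect_equal(looks$n_samples, 11)
  val2 <- c(rep(1L, 5), 0L, 0L, rep(1L, 5))
  labs2 <- c(rep("face", 5), NA, NA, rep("face", 5))
  looks2 <- detect_looks(make_trial_from_labels(labs2, valid = val2))
  expect_equal(nrow(looks2), 2)
})

test_that("random label streams match the scalar state-machine scanner", {
  set.seed(99)
  sc <- gaze_scene(1)
  labels_pool <- c(sc$aois$label, NA)
  for (rep in 1:25) {
    n <- sample(30:200, 1)
    labs <- sample(labels_pool, n, replace = TRUE,
                   prob = c(rep(0.15, 5), 0.25))
    valid <- ifelse(runif(n) < 0.15, 0L, 1L)
    tr <- make_trial_from_labels(labs, valid = valid)
    got <- detect_looks(tr)
    want <- naive_looks(ifelse(valid == 1, labs, NA), valid)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$label, want$label)
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$n_samples, want$n_samples)
    }
  }
})

test_that("empty trials give an empty look list", {
  tr <- gaze_trial(data.frame(t_ms = numeric(0), x_px = numeric(0),
                              y_px = numeric(0), valid = integer(0)),
                   gaze_scene(1))
  expect_equal(nrow(detect_looks(tr)), 0)
})

test_that("each validity criterion triggers independently", {
  n <- 2400  # 20 s at 120 Hz
  # 30% valid, 6 s of valid face data -> valid
  labs <- c(rep("face", 720), rep(NA, n - 720))
  val <- c(rep(1L, 720), rep(0L, n - 720))
  v <- trial_validity(make_trial_from_labels(labs, valid = val))
  expect_true(v$valid)
  expect_length(v$reasons, 0)
  # 20% valid fails the proportion rule (and duration)
  val2 <- c(rep(1L, 480), rep(0L, n - 480))
  labs2 <- c(rep("face", 480), rep(NA, n - 480))
  v2 <- trial_validity(make_trial_from_labels(labs2, valid = val2))
  expect_false(v2$valid)
  expect_true(any(grepl("proportion", v2$reasons)))
  # valid everywhere but never inside an AOI
  v3 <- trial_validity(make_trial_from_labels(rep(NA_character_, n)))
  expect_false(v3$valid)
  expect_identical(v3$reasons, "no AOI look")
  # enough proportion, too little absolute duration (short trial)
  v4 <- trial_validity(make_trial_from_labels(rep("face", 120)))
  expect_false(v4$valid)
  expect_true(any(grepl("duration", v4$reasons)))
})

test_that("raising the validity threshold never rescues a trial", {
  set.seed(5)
  sc <- gaze_scene(1)
  for (rep in 1:10) {
    n <- 2400
    val <- ifelse(runif(n) < runif(1, 0.2, 0.9), 0L, 1L)
    labs <- sample(c(sc$aois$label, NA), n, TRUE)
    tr <- make_trial_from_labels(labs, valid = val)
    v_lo <- trial_validity(tr, min_valid_prop = 0.25)$valid
    v_hi <- trial_validity(tr, min_valid_prop = 0.5)$valid
    expect_true(v_lo >= v_hi)
  }
})

test_that("trial measures implement first look, face share and the 10 s window", {
  # bird (1 s), face (2 s), then car starting after 10 s
  labs <- c(rep("bird", 120), rep("face", 240), rep(NA, 960),
            rep("face", 600), rep(NA, 120), rep("car", 240),
            rep(NA, 2400 - 120 - 240 - 960 - 600 - 120 - 240))
  m <- trial_measures(make_trial_from_labels(labs))
  expect_true(m$valid)
  expect_equal(m$first_aoi, "bird")
  expect_equal(m$n_objects_10s, 2)  # car onset is past 10 s
  face_s <- 240 + 600; tot_s <- 120 + 240 + 600 + 240
  expect_equal(m$prop_face, face_s / tot_s, tolerance = 1e-10)
})

test_that("measures equal brute-force recomputation from the look list", {
  set.seed(123)
  sc <- gaze_scene(1)
  for (rep in 1:15) {
    labs <- unlist(lapply(1:sample(4:10, 1), function(i)
      rep(sample(c(sc$aois$label, NA), 1), sample(3:200, 1))))
    labs <- rep(labs, length.out = max(length(labs), 1800))
    tr <- make_trial_from_labels(labs)
    m <- trial_measures(tr)
    looks <- detect_looks(tr)
    if (!m$valid) next
    expect_equal(m$first_aoi, looks$label[which.min(looks$onset_ms)])
    expect_equal(m$prop_face,
                 sum(looks$duration_ms[looks$label == "face"]) /
                   sum(looks$duration_ms))
    expect_equal(m$n_objects_10s,
                 length(unique(looks$label[looks$onset_ms < 10000])))
    expect_lte(m$n_objects_10s, 5)
  }
})

test_that("prop_face and non-face AOI shares sum to one on valid trials", {
  set.seed(31)
  sc <- gaze_scene(1)
  labs <- unlist(lapply(1:12, function(i)
    rep(sample(sc$aois$label, 1), sample(10:100, 1))))
  tr <- make_trial_from_labels(rep(labs, length.out = 2400))
  looks <- detect_looks(tr)
  shares <- vapply(sc$aois$label, function(l)
    sum(looks$duration_ms[looks$label == l]) / sum(looks$duration_ms),
    numeric(1))
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  m <- trial_measures(tr)
  expect_equal(unname(shares["face"]), m$prop_face)
})
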