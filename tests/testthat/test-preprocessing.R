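make_candidate <- function(v, conf, seed = 1) {
  set.seed(seed)
  cbind(matrix(stats::runif(2L * v), v, 2L), conf)
}

test_that("top-k person selection matches an exhaustive argmax oracle", {
  v <- 5L
  set.seed(3)
  # 4 frames with 0..3 candidates of random confidences
  detections <- lapply(c(3L, 0L, 1L, 2L), function(nc) {
    lapply(seq_len(nc), function(i)
      make_candidate(v, stats::runif(v), seed = sample.int(1e6, 1)))
  })
  seq2 <- select_top_persons(detections, k = 2L)
  expect_identical(dim(seq2$data), c(3L, 4L, v, 2L))
  for (t in seq_along(detections)) {
    frame <- detections[[t]]
    means <- vapply(frame, function(cand) mean(cand[, 3L]), 0)
    keep <- order(-means, seq_along(means))   # exhaustive max-k rule
    for (m in 1:2) {
      if (m <= length(frame)) {
        expect_equal(seq2$data[, t, , m], t(frame[[keep[m]]]),
                     ignore_attr = TRUE)
      } else {
        expect_true(all(seq2$data[, t, , m] == 0))   # zero-padded slot
      }
    }
  }
})

test_that("person selection is invariant to candidate input order", {
  v <- 4L
  cands <- lapply(c(0.9, 0.5, 0.7), function(cf) make_candidate(v, cf))
  a <- select_top_persons(list(cands), k = 2L)
  b <- select_top_persons(list(cands[c(2L, 3L, 1L)]), k = 2L)
  expect_identical(a$data, b$data)
  # the 0.9 and 0.7 candidates are kept, in that order
  expect_equal(a$data[, 1L, , 1L], t(cands[[1L]]), ignore_attr = TRUE)
  expect_equal(a$data[, 1L, , 2L], t(cands[[3L]]), ignore_attr = TRUE)
})

test_that("confidence ties keep the lower original detection index", {
  v <- 3L
  c1 <- make_candidate(v, 0.8, seed = 1)
  c2 <- make_candidate(v, 0.8, seed = 2)
  out <- select_top_persons(list(list(c1, c2)), k = 1L)
  expect_equal(out$data[, 1L, , 1L], t(c1), ignore_attr = TRUE)
})

test_that("frame resampling hits the target length by stride or loop-padding", {
  mk <- function(t_n) {
    skeleton_sequence(array(seq_len(3L * t_n * 4L * 1L), c(3L, t_n, 4L, 1L)),
                      channels = c("x", "y", "z"))
  }
  # 50 -> 25 keeps frames 1, 3, 5, ..., 49 (0-based 0, 2, ..., 48)
  s50 <- mk(50L)
  r <- resample_frames(s50, 25L)
  expect_identical(dim(r$data)[2L], 25L)
  expect_identical(r$data, s50$data[, seq(1L, 49L, by = 2L), , , drop = FALSE])
  # identity when already at the target
  s25 <- mk(25L)
  expect_identical(resample_frames(s25, 25L), s25)
  # loop-padding repeats from the start
  s10 <- mk(10L)
  r10 <- resample_frames(s10, 25L)
  expect_identical(dim(r10$data)[2L], 25L)
  expect_identical(r10$data[, 11L, , , drop = FALSE],
                   s10$data[, 1L, , , drop = FALSE])
  expect_identical(r10$data[, 25L, , , drop = FALSE],
                   s10$data[, 5L, , , drop = FALSE])
  # long input typical of raw recordings
  expect_identical(dim(resample_frames(mk(155L), 25L)$data)[2L], 25L)
  # subsampled indices are strictly increasing (spot-check via uniqueness)
  r155 <- resample_frames(mk(155L), 25L)
  expect_identical(anyDuplicated(r155$data[1L, , 1L, 1L]), 0L)
})

test_that("rotation augmentation is an isometry that leaves confidence alone", {
  spec <- synthetic_spec(noise_sigma = 0, conf_dropout = 0)
  sq <- generate_action(1L, spec, seed = 5)
  rot <- random_rotation_augment(sq, max_degrees = 18, seed = 9)
  # confidence channel bit-exact
  expect_identical(rot$data[4L, , , ], sq$data[4L, , , ])
  # pairwise joint distances preserved within each frame/person
  for (t in c(1L, 17L, 60L)) {
    for (m in 1:2) {
      d0 <- stats::dist(t(sq$data[1:3, t, , m]))
      d1 <- stats::dist(t(rot$data[1:3, t, , m]))
      expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-9)), 1e-6)
    }
  }
  # zero bound is the identity
  same <- random_rotation_augment(sq, max_degrees = 0, seed = 1)
  expect_lt(max(abs(same$data - sq$data)), 1e-12)
  # determinism: one seed, one rotation
  expect_identical(random_rotation_augment(sq, 18, seed = 4)$data,
                   random_rotation_augment(sq, 18, seed = 4)$data)
})

test_that("2-D sequences rotate in-plane only, with angles inside the bound", {
  v <- 6L
  data <- array(stats::runif(3L * 8L * v), c(3L, 8L, v, 1L))
  sq <- skeleton_sequence(data, channels = c("x", "y", "conf"))
  for (seed in 1:40) {
    rot <- random_rotation_augment(sq, max_degrees = 18, seed = seed)
    # recover the in-plane angle from one displaced joint pair
    p0 <- sq$data[1:2, 1L, 1L, 1L] - sq$data[1:2, 1L, 2L, 1L]
    p1 <- rot$data[1:2, 1L, 1L, 1L] - rot$data[1:2, 1L, 2L, 1L]
    ang <- atan2(p1[2L], p1[1L]) - atan2(p0[2L], p0[1L])
    ang <- atan2(sin(ang), cos(ang)) * 180 / pi
    expect_lte(abs(ang), 18 + 1e-8)
  }
  expect_error(
    random_rotation_augment(
      skeleton_sequence(array(0.5, c(2L, 3L, 2L, 1L)),
                        channels = c("conf", "confb")),
      18),
    "non-spatial")
})

test_that("coordinate centering is translation-invariant and keeps zeros zero", {
  lay <- build_layout("synthetic20")
  spec <- synthetic_spec(noise_sigma = 0, conf_dropout = 0)
  sq <- generate_action(2L, spec, seed = 11)
  centered <- normalize_coordinates(sq, lay)
  expect_identical(normalize_coordinates(centered, lay), centered)
  # constant offset on all joints vanishes after centering
  shifted <- sq
  shifted$data[1:3, , , ] <- shifted$data[1:3, , , ] + 5
  expect_equal(normalize_coordinates(shifted, lay)$data, centered$data,
               tolerance = 1e-12)
  # a zero-filled person slot stays exactly zero
  gap <- sq
  gap$data[, , , 2L] <- 0
  out <- normalize_coordinates(gap, lay)
  expect_true(all(out$data[, , , 2L] == 0))
})

test_that("bone stream has the joint stream's shape and zero center joint", {
  lay <- build_layout("synthetic20")
  sq <- generate_action(1L, synthetic_spec(), seed = 2)
  bone <- to_bone_stream(sq, lay)
  expect_identical(dim(bone$data), dim(sq$data))
  expect_true(all(bone$data[1:3, , lay$center_joint, ] == 0))
  # a bone equals child minus parent: spot-check the spine (parent pelvis)
  expect_equal(bone$data[1:3, , 2L, ],
               sq$data[1:3, , 2L, ] - sq$data[1:3, , 1L, ])
})
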