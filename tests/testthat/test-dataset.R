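test_that("segmentation tiles events and rest as specified", {
  rec <- toy_recording_250(event_start = 4, dur = 10)
  es <- segment_epochs(rec)
  expect_s3_class(es, "epoch_set")
  expect_equal(sum(es$label == "liquid"), 1)
  expect_equal(sum(es$label == "rest"), 4)
  expect_equal(dim(es$values)[2:3], c(3L, 500L))
  expect_true(all(es$values >= 0 & es$values <= 1))

  # a 2-s recording with one event -> exactly one epoch
  short <- multimodal_recording(rnorm(500), rnorm(500), rnorm(500), 250,
                                annotations = data.frame(
                                  start_s = 0, end_s = 2,
                                  class_label = "cough"))
  expect_equal(length(segment_epochs(short)), 1L)
  # long events tile into consecutive epochs, trailing partial dropped
  long_ev <- multimodal_recording(rnorm(2500), rnorm(2500), rnorm(2500),
                                  250,
                                  annotations = data.frame(
                                    start_s = 0, end_s = 5,
                                    class_label = "chewing"))
  expect_equal(sum(segment_epochs(long_ev)$label == "chewing"), 2L)
  tooshort <- multimodal_recording(rnorm(475), rnorm(475), rnorm(475), 250)
  expect_error(segment_epochs(tooshort), "2-s")
})

test_that("normalize_epoch maps to [0,1] with the degenerate rule", {
  m <- rbind(seq(-3, 5, length.out = 10), rep(2, 10), rnorm(10))
  nm <- normalize_epoch(m)
  expect_equal(nm[1, 1], 0); expect_equal(nm[1, 10], 1)
  expect_true(all(nm[2, ] == 0.5))
  expect_true(all(nm >= 0 & nm <= 1))
  for (i in 1:20) {
    set.seed(i)
    x <- normalize_epoch(matrix(rnorm(30, sd = 10^runif(1, -3, 3)), 3))
    expect_true(all(x >= 0 & x <= 1))
    expect_equal(normalize_epoch(x), x, tolerance = 1e-12)  # idempotent
  }
  expect_error(normalize_epoch(matrix(c(1, NA, 3, 4), 2)), "finite")
})

test_that("one_hot uses the fixed class order", {
  expect_equal(as.numeric(one_hot("rest")), c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(one_hot("silent_aspiration")),
               c(0, 0, 0, 0, 1, 0, 0))
  m <- one_hot(sample(swallow_classes(), 20, replace = TRUE))
  expect_true(all(rowSums(m) == 1))
  expect_error(one_hot("snack"), "valid labels")
})

test_that("augmentation shifts, re-labels and tallies skips", {
  rec <- toy_recording_250(event_start = 0, dur = 10)  # event [0, 2]
  es <- segment_epochs(rec)
  same <- augment_epochs(es, rec, n_shifts = 0)
  expect_equal(length(same), length(es))
  expect_equal(attr(same, "skipped"), 0L)

  aug <- augment_epochs(es, rec, n_shifts = 3)
  expect_equal(length(aug), length(es) + 3L * length(es) -
                 attr(aug, "skipped"))
  expect_true(all(aug$shift_s %in% c(0, 0.2, 0.4, 0.6)))
  # the liquid epoch starts at 0; +0.2/+0.4 keep majority overlap,
  # +1.2 and beyond would not (checked via the overlap-label oracle)
  lab02 <- aug$label[aug$shift_s == 0.2][1]
  expect_equal(lab02, "liquid")

  # boundary flip: window shifted until event overlap < 50% becomes rest
  rec2 <- toy_recording_250(event_start = 0, dur = 6)
  es2 <- segment_epochs(rec2)
  liquid_idx <- which(es2$label == "liquid")
  aug2 <- augment_epochs(es2, rec2, n_shifts = 8)
  shifted <- which(aug2$participant_id == "TOY" & aug2$shift_s >= 1.2 &
                   seq_along(aug2$label) > length(es2))
  first_liquid_shifts <- aug2$label[aug2$shift_s == 1.2]
  expect_true("rest" %in% first_liquid_shifts)

  # shifts beyond the recording end are skipped, not truncated
  rec3 <- toy_recording_250(event_start = 0, dur = 2.2)
  es3 <- segment_epochs(rec3)
  aug3 <- augment_epochs(es3, rec3, n_shifts = 5)
  expect_gt(attr(aug3, "skipped"), 0)
})

test_that("interpatient split is disjoint, deterministic and near-target", {
  set.seed(8)
  mk_epochs <- function(counts) {
    n <- sum(counts)
    epoch_set(array(runif(n * 3 * 10), c(n, 3, 10)),
              sample(swallow_classes(), n, replace = TRUE),
              rep(sprintf("P%02d", seq_along(counts)), counts))
  }
  # 5 participants x 10 epochs: the exhaustive optimum is 3/1/1
  es <- mk_epochs(rep(10, 5))
  sp <- interpatient_split(es, seed = 1)
  expect_equal(unname(sp$achieved), c(30, 10, 10))
  expect_equal(length(sp$train), 30)

  # participant disjointness and exhaustiveness on ragged sizes
  for (s in 1:5) {
    es2 <- mk_epochs(sample(5:30, 8))
    sp2 <- interpatient_split(es2, seed = s)
    ids <- list(unique(sp2$train$participant_id),
                unique(sp2$validation$participant_id),
                unique(sp2$test$participant_id))
    expect_equal(length(Reduce(intersect, ids)), 0)
    expect_equal(length(sp2$train) + length(sp2$validation) +
                   length(sp2$test), length(es2))
    expect_true(all(lengths(ids) > 0))
    # determinism
    sp3 <- interpatient_split(es2, seed = s)
    expect_identical(sp2$assignment, sp3$assignment)
  }
  # one-hot matrices are consistent
  expect_equal(nrow(sp$onehot$train), 30)
  expect_true(all(rowSums(sp$onehot$train) == 1))
  expect_error(interpatient_split(mk_epochs(c(10, 10))), "3 distinct")
})
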