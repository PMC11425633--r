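cls <- swallow_classes()

test_that("confusion_matrix counts pairs exactly", {
  truth <- sample(cls, 50, replace = TRUE)
  cm <- confusion_matrix(truth, truth)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(sum(diag(cm)), 50L)

  cm1 <- confusion_matrix("rest", "cough")
  expect_equal(sum(cm1), 1L)
  expect_equal(cm1["rest", "cough"], 1L)

  set.seed(2)
  a <- sample(cls, 321, replace = TRUE)
  b <- sample(cls, 321, replace = TRUE)
  expect_equal(sum(confusion_matrix(a, b)), 321L)
  expect_error(confusion_matrix(c("rest", "nap"), c("rest", "rest")),
               "valid labels")
  expect_error(confusion_matrix(a, b[-1]), "equal length")
})

test_that("metrics match their definitions and the printed-pair arithmetic", {
  perfect <- confusion_matrix(cls, cls)
  expect_equal(cm_accuracy(perfect), 1)
  for (cl in cls) {
    expect_equal(cm_sensitivity(perfect, cl), 1)
    expect_equal(cm_specificity(perfect, cl), 1)
  }
  # the 2-class collapse TP=79 FN=21 TN=99 FP=1 -> 0.79 / 0.99
  truth <- c(rep("silent_aspiration", 100), rep("rest", 100))
  pred <- c(rep("silent_aspiration", 79), rep("rest", 21),
            rep("rest", 99), rep("silent_aspiration", 1))
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm_sensitivity(cm, "silent_aspiration"), 0.79)
  expect_equal(cm_specificity(cm, "silent_aspiration"), 0.99)
  # undefined denominators raise, not return 0
  empty_row <- confusion_matrix(rep("rest", 5), rep("rest", 5))
  expect_error(cm_sensitivity(empty_row, "cough"), "undefined")
})

test_that("metrics equal brute-force one-vs-rest recomputation", {
  brute <- function(m, i) {
    tp <- m[i, i]; fn <- sum(m[i, ]) - tp
    fp <- sum(m[, i]) - tp; tn <- sum(m) - tp - fn - fp
    c(sens = tp / (tp + fn), spec = tn / (tn + fp))
  }
  set.seed(7)
  for (rep in 1:200) {
    m <- matrix(rpois(49, 4), 7, 7,
                dimnames = list(true = cls, predicted = cls))
    class(m) <- c("confusion_matrix", "matrix")
    expect_equal(cm_accuracy(m), sum(diag(m)) / sum(m))
    for (i in sample(7, 2)) {
      bf <- brute(m, i)
      if (is.finite(bf["sens"]))
        expect_equal(cm_sensitivity(m, i), unname(bf["sens"]))
      expect_equal(cm_specificity(m, i), unname(bf["spec"]))
    }
    # accuracy invariant under simultaneous row/column permutation
    p <- sample(7)
    m2 <- m[p, p]
    class(m2) <- c("confusion_matrix", "matrix")
    expect_equal(cm_accuracy(m2), cm_accuracy(m))
  }
})

test_that("placement check applies the 6 dB rule", {
  fs <- 2000
  sq <- rep(c(1, -1), fs)               # RMS exactly 1, 2 s
  mk <- function(burst_amp) {
    e <- c(sq, burst_amp * sq, sq)
    multimodal_recording(e, e, numeric(length(e)) + 1e-6, fs,
                         annotations = data.frame(
                           start_s = 2, end_s = 4,
                           class_label = "liquid"))
  }
  pc <- placement_check(mk(10), channel = 1)
  expect_equal(unname(pc$snr_db), 20, tolerance = 1e-9)
  expect_true(pc$verdict)
  pc_fail <- placement_check(mk(1.5), channel = 1)
  expect_equal(unname(pc_fail$snr_db), 20 * log10(1.5), tolerance = 1e-9)
  expect_false(pc_fail$verdict)
  expect_false(placement_check(mk(1), channel = 1)$verdict)   # 0 dB
  # monotone in burst amplitude
  snrs <- vapply(c(1, 2, 4, 8),
                 function(a) unname(placement_check(mk(a), 1)$snr_db), 0)
  expect_true(all(diff(snrs) > 0))
  # missing inactivity lead-in
  no_lead <- multimodal_recording(sq, sq, sq, fs,
                                  annotations = data.frame(
                                    start_s = 0, end_s = 2,
                                    class_label = "liquid"))
  expect_error(placement_check(no_lead), "inactivity")
  unannotated <- multimodal_recording(sq, sq, sq, fs)
  expect_error(placement_check(unannotated), "no annotated swallow")
})

test_that("session_report summarises and flags aspiration", {
  tl <- data.frame(
    start_s = c(0, 5, 7, 12, 14),
    end_s = c(5, 7, 12, 14, 20),
    class_label = c("rest", "silent_aspiration", "rest",
                    "silent_aspiration", "rest"),
    mean_prob = c(0.9, 0.8, 0.9, 0.7, 0.95))
  rep_ <- session_report(tl)
  expect_equal(nrow(rep_$aspiration_events), 2)
  expect_equal(rep_$aspiration_events$start_s, c(5, 12))
  expect_equal(sum(rep_$event_durations_s), 20)   # conservation
  txt <- format(rep_)
  expect_match(txt, "aspiration alerts: 2")

  allrest <- session_report(data.frame(start_s = 0, end_s = 10,
                                       class_label = "rest",
                                       mean_prob = 1))
  expect_equal(nrow(allrest$aspiration_events), 0)
  expect_match(format(session_report(tl[0, ])), "no events detected")
  # serialisation round-trip
  d <- withr::local_tempdir()
  write_session_report(rep_, d)
  expect_true(file.exists(file.path(d, "report.txt")))
  js <- jsonlite::read_json(file.path(d, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$event_counts$silent_aspiration, 2)
})
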