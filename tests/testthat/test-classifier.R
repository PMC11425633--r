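test_that("build matches the analytic parameter count and is deterministic", {
  m <- build_cnn_bilstm(architecture_config(), seed = 1)
  expect_equal(m$parameter_count, analytic_param_count())
  m2 <- build_cnn_bilstm(architecture_config(), seed = 1)
  expect_identical(lapply(m$params, dim), lapply(m2$params, dim))
  expect_identical(m$params, m2$params)      # same seed, same weights
  expect_equal(ncol(m$params$out_W), 7)
  expect_equal(dim(m$params$b1A_W), c(80L, 15L))
  expect_equal(dim(m$params$b3B_W), c(16L, 112L * 4L))
})

test_that("the compiled convolution agrees with a direct R convolution", {
  set.seed(6)
  Cin <- 2L; Cout <- 3L; k <- 4L; B <- 2L; Tn <- 9L
  X <- matrix(rnorm(Cin * B * Tn), Cin)
  W <- matrix(rnorm(Cout * Cin * k), Cout)
  bias <- rnorm(Cout)
  pad_l <- (k - 1L) %/% 2L
  Y <- deglutio:::conv1d_fwd(X, B, Tn, W, bias, k, pad_l, FALSE)$Y
  # naive loop oracle
  for (b in seq_len(B)) for (t in seq_len(Tn)) for (co in seq_len(Cout)) {
    acc <- bias[co]
    for (j in seq_len(k)) {
      ti <- t + j - 1L - pad_l
      if (ti >= 1L && ti <= Tn)
        acc <- acc + sum(W[co, (j - 1L) * Cin + seq_len(Cin)] *
                         X[, (b - 1L) * Tn + ti])
    }
    expect_equal(Y[co, (b - 1L) * Tn + t], acc, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  arch <- architecture_config(input_steps = 40, dropout = 0)
  model <- build_cnn_bilstm(arch, seed = 7)
  B <- 3
  vals <- array(runif(B * 3 * 40), c(B, 3, 40))
  X <- deglutio:::epochs_to_input(vals)
  Y <- deglutio:::one_hot(sample(swallow_classes(), B, replace = TRUE))
  loss_fn <- function(m) {
    fwd <- deglutio:::nn_forward(m, X, B, training = TRUE)
    -mean(rowSums(Y * log(pmax(fwd$probs, 1e-12))))
  }
  fwd <- deglutio:::nn_forward(model, X, B, training = TRUE)
  g <- deglutio:::nn_backward(model, fwd, Y)
  eps <- 1e-5
  # two random entries from a representative parameter of every layer kind
  for (nm in c("b1A_W", "b2B_gamma", "b3A_alpha", "lstm_f_Wh", "lstm_b_Wx",
               "d1_W", "d2_alpha", "out_W", "b1B_b", "lstm_f_b")) {
    p <- model$params[[nm]]
    for (i in sample(length(p), 2)) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      lp <- loss_fn(m2)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- loss_fn(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("prediction is a probability map, batch-invariant and strict", {
  model <- build_cnn_bilstm(architecture_config(), seed = 3)
  set.seed(10)
  vals <- array(runif(6 * 3 * 500), c(6, 3, 500))
  p <- predict_epochs(model, vals)
  expect_equal(dim(p), c(6L, 7L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  # duplicated epoch -> identical rows
  vals[2, , ] <- vals[1, , ]
  p2 <- predict_epochs(model, vals)
  expect_equal(p2[1, ], p2[2, ])
  # invariance to batch placement
  single <- predict_epochs(model, vals[4, , ])
  expect_equal(unname(single[1, ]), unname(p2[4, ]), tolerance = 1e-10)
  expect_error(predict_epochs(model, array(0, c(2, 3, 400))), "3 x 500")
})

test_that("training learns a separable toy and is seed-reproducible", {
  # two classes distinguished by a strong low-frequency burst on channel 1
  set.seed(21)
  n <- 48
  vals <- array(runif(n * 3 * 500, 0.45, 0.55), c(n, 3, 500))
  lab <- rep(c("rest", "cough"), n / 2)
  for (i in which(lab == "cough"))
    vals[i, 1, 100:250] <- vals[i, 1, 100:250] +
      0.4 * sin(2 * pi * (1:151) / 50)
  vals <- pmin(pmax(vals, 0), 1)
  # participants arranged so the split holds out whole subjects
  es <- epoch_set(vals, lab, rep(sprintf("P%d", 1:6), each = n / 6))
  sp <- interpatient_split(es, seed = 2)
  arch <- architecture_config(max_epochs = 30, batch_size = 8)
  run <- train_cnn_bilstm(sp, arch, seed = 2)
  expect_s3_class(run, "training_run")
  expect_equal(nrow(run$history), 30)
  expect_equal(run$best_val_accuracy, max(run$history$val_acc))
  expect_gte(run$best_val_accuracy, 1.0)   # separable toy reaches 100%

  # determinism of the first epoch's training loss
  r1 <- train_cnn_bilstm(sp, architecture_config(max_epochs = 1,
                                                 batch_size = 16), seed = 9)
  r2 <- train_cnn_bilstm(sp, architecture_config(max_epochs = 1,
                                                 batch_size = 16), seed = 9)
  expect_equal(r1$history$train_loss[1], r2$history$train_loss[1],
               tolerance = 1e-6)
  expect_error(train_cnn_bilstm(list()), "dataset_split")
})

test_that("classify_session slides, merges and absorbs correctly", {
  model <- build_cnn_bilstm(architecture_config(), seed = 1)
  rec <- toy_recording_250(event_start = 4, dur = 10)
  tl <- classify_session(model, rec)
  # window arithmetic: (10 - 2) / 0.2 + 1 = 41 evaluated windows
  expect_equal(attr(tl, "n_windows"), 41L)
  # the timeline tiles the whole recording
  expect_equal(tl$start_s[1], 0)
  expect_equal(tl$end_s[nrow(tl)], 10)
  if (nrow(tl) > 1)
    expect_equal(tl$start_s[-1], tl$end_s[-nrow(tl)])
  # no event shorter than the absorption threshold (except a lone event)
  if (nrow(tl) > 1)
    expect_true(all(tl$end_s - tl$start_s >= 0.4 - 1e-9))
  expect_true(all(tl$mean_prob > 0 & tl$mean_prob <= 1))
  shortrec <- multimodal_recording(rnorm(400), rnorm(400), rnorm(400), 250)
  expect_error(classify_session(model, shortrec), "2-s")
})
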