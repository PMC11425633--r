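#' Published CNN-BiLSTM architecture configuration
#'
#' Value object holding the hyperparameters of the swallowing-status
#' network: three convolutional blocks (first layers 80/48/112 filters with
#' kernels 5/3/3, second layer 16 filters with kernel 4 in every block,
#' each convolution followed by batch normalisation and PReLU, each block
#' closed by max-pooling of size 2), a bidirectional LSTM with 10 tanh
#' units, dense layers of 140/512/256 PReLU units with 0.2 dropout after
#' the 512 layer, and a 7-class softmax output.  Optimised with Adam at a
#' fixed learning rate of 0.001 under categorical cross-entropy.
#'
#' @param input_steps time steps per epoch (500 = 2 s at 250 Hz).
#' @param input_channels input channels, stacked as (emg1, emg2, sound).
#' @param n_classes number of output classes.
#' @param learning_rate Adam step size.
#' @param dropout dropout fraction after the second dense layer.
#' @param batch_size minibatch size used by [train_cnn_bilstm()].
#' @param max_epochs default training epoch budget.
#' @return Object of class `architecture_config`.
#' @export
architecture_config <- function(input_steps = 500, input_channels = 3,
                                n_classes = 7, learning_rate = 0.001,
                                dropout = 0.2, batch_size = 32,
                                max_epochs = 300) {
  stopifnot(input_steps > 0, input_channels > 0, n_classes > 0,
            learning_rate > 0, dropout >= 0, dropout < 1,
            batch_size > 0, max_epochs > 0)
  structure(list(
    conv_blocks = list(
      list(first = c(filters = 80, kernel = 5),
           second = c(filters = 16, kernel = 4)),
      list(first = c(filters = 48, kernel = 3),
           second = c(filters = 16, kernel = 4)),
      list(first = c(filters = 112, kernel = 3),
           second = c(filters = 16, kernel = 4))),
    pool_size = 2L,
    lstm_units = 10L,
    dense_units = c(140L, 512L, 256L),
    dropout_after_second_dense = dropout,
    n_classes = as.integer(n_classes),
    input_steps = as.integer(input_steps),
    input_channels = as.integer(input_channels),
    optimizer = list(name = "adam", learning_rate = learning_rate,
                     beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7),
    prelu_init = 0.25, bn_momentum = 0.9, bn_epsilon = 1e-3,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs)),
    class = "architecture_config")
}

# time-step lengths entering each block and the LSTM (floor rule per pool)
arch_time_steps <- function(arch) {
  Tn <- arch$input_steps
  out <- integer(0)
  for (blk in arch$conv_blocks) {
    out <- c(out, Tn)
    Tn <- Tn %/% arch$pool_size
  }
  c(out, Tn)
}

#' Build (initialise) the CNN-BiLSTM
#'
#' Allocates and seeds all trainable parameters for the configured
#' architecture (Glorot-uniform kernels, zero biases with the LSTM forget
#' gate biased to 1, PReLU slopes at 0.25, batch-norm gamma/beta at 1/0).
#'
#' @param arch an [architecture_config()].
#' @param seed integer seed for the initialisation.
#' @return Object of class `cnn_bilstm` with elements `params`, `running`
#'   (batch-norm inference statistics), `arch` and `parameter_count`
#'   (trainable parameters only).
#' @export
build_cnn_bilstm <- function(arch = architecture_config(), seed = 0) {
  stopifnot(inherits(arch, "architecture_config"))
  with_seed(seed, {
    params <- list()
    running <- list()
    cin <- arch$input_channels
    for (i in seq_along(arch$conv_blocks)) {
      blk <- arch$conv_blocks[[i]]
      for (half in c("A", "B")) {
        spec <- if (half == "A") blk$first else blk$second
        f <- spec[["filters"]]; k <- spec[["kernel"]]
        id <- paste0("b", i, half)
        params[[paste0(id, "_W")]] <- glorot(cin * k, f, c(f, cin * k))
        params[[paste0(id, "_b")]] <- numeric(f)
        params[[paste0(id, "_gamma")]] <- rep(1, f)
        params[[paste0(id, "_beta")]] <- numeric(f)
        params[[paste0(id, "_alpha")]] <- rep(arch$prelu_init, f)
        running[[paste0(id, "_mean")]] <- numeric(f)
        running[[paste0(id, "_var")]] <- rep(1, f)
        cin <- f
      }
    }
    u <- arch$lstm_units
    for (dir in c("f", "b")) {
      params[[paste0("lstm_", dir, "_Wx")]] <- glorot(cin, 4 * u, c(cin, 4 * u))
      params[[paste0("lstm_", dir, "_Wh")]] <- glorot(u, 4 * u, c(u, 4 * u))
      bias <- numeric(4 * u)
      bias[(u + 1):(2 * u)] <- 1   # forget-gate bias
      params[[paste0("lstm_", dir, "_b")]] <- bias
    }
    din <- 2 * u
    for (j in seq_along(arch$dense_units)) {
      dj <- arch$dense_units[j]
      params[[paste0("d", j, "_W")]] <- glorot(din, dj, c(din, dj))
      params[[paste0("d", j, "_b")]] <- numeric(dj)
      params[[paste0("d", j, "_alpha")]] <- rep(arch$prelu_init, dj)
      din <- dj
    }
    params[["out_W"]] <- glorot(din, arch$n_classes,
                                c(din, arch$n_classes))
    params[["out_b"]] <- numeric(arch$n_classes)
    structure(list(params = params, running = running, arch = arch,
                   parameter_count = sum(vapply(params, length, 0L))),
              class = "cnn_bilstm")
  })
}

#' @export
print.cnn_bilstm <- function(x, ...) {
  cat(sprintf("<cnn_bilstm> %d trainable parameters, input %d x %d, %d classes\n",
              x$parameter_count, x$arch$input_steps, x$arch$input_channels,
              x$arch$n_classes))
  invisible(x)
}

## ---- full forward / backward ----------------------------------------------

# epoch_set values (n x 3 x T) -> C x (n*T) with per-sample blocks
epochs_to_input <- function(values) {
  d <- dim(values)
  matrix(aperm(values, c(2, 3, 1)), nrow = d[2])
}

nn_forward <- function(model, X, B, training = FALSE) {
  arch <- model$arch
  p <- model$params
  run <- model$running
  Tn <- arch$input_steps
  cache <- list(B = B)
  for (i in seq_along(arch$conv_blocks)) {
    blk <- arch$conv_blocks[[i]]
    for (half in c("A", "B")) {
      spec <- if (half == "A") blk$first else blk$second
      k <- spec[["kernel"]]
      id <- paste0("b", i, half)
      pad_l <- (k - 1L) %/% 2L
      cv <- conv1d_fwd(X, B, Tn, p[[paste0(id, "_W")]],
                       p[[paste0(id, "_b")]], k, pad_l, training)
      Y <- cv$Y
      bn <- bn_forward(Y, p[[paste0(id, "_gamma")]],
                       p[[paste0(id, "_beta")]],
                       run[[paste0(id, "_mean")]],
                       run[[paste0(id, "_var")]],
                       arch$bn_epsilon, arch$bn_momentum, training)
      if (training) {
        run[[paste0(id, "_mean")]] <- bn$run_mean
        run[[paste0(id, "_var")]] <- bn$run_var
      }
      pr <- prelu_forward(bn$y, p[[paste0(id, "_alpha")]], byrow = TRUE)
      if (training)
        cache[[id]] <- list(XC = cv$XC, Y = Y, bn = bn, pr = pr, Tn = Tn,
                            k = k, pad_l = pad_l)
      X <- pr$y
    }
    idx <- pool_indices(B, Tn)
    mp <- maxpool_forward(X, idx)
    if (training) cache[[paste0("pool", i)]] <-
      list(mp = mp, idx = idx, ncol_in = ncol(X))
    X <- mp$y
    Tn <- idx$To
  }
  # sequence for the recurrent layer: list of B x C matrices
  Cn <- nrow(X)
  arr <- array(X, c(Cn, Tn, B))
  xs <- lapply(seq_len(Tn), function(t) t(matrix(arr[, t, ], nrow = Cn)))
  lf <- lstm_forward(xs, p$lstm_f_Wx, p$lstm_f_Wh, p$lstm_f_b)
  lb <- lstm_forward(rev(xs), p$lstm_b_Wx, p$lstm_b_Wh, p$lstm_b_b)
  H <- cbind(lf$h, lb$h)
  if (training) cache$lstm <- list(lf = lf, lb = lb, Tn = Tn, Cn = Cn)
  A <- H
  for (j in seq_along(arch$dense_units)) {
    Z <- sweep(A %*% p[[paste0("d", j, "_W")]], 2,
               p[[paste0("d", j, "_b")]], "+")
    pr <- prelu_forward(Z, p[[paste0("d", j, "_alpha")]], byrow = FALSE)
    if (training) cache[[paste0("d", j)]] <- list(Ain = A, Z = Z, pr = pr)
    A <- pr$y
    if (j == 2L && arch$dropout_after_second_dense > 0) {
      if (training) {
        keep <- 1 - arch$dropout_after_second_dense
        mask <- matrix(runif(length(A)) < keep, nrow(A), ncol(A)) / keep
        cache$dropout <- mask
        A <- A * mask
      }
    }
  }
  logits <- sweep(A %*% p$out_W, 2, p$out_b, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, A_last = A, cache = cache,
       running = run)
}

nn_backward <- function(model, fwd, Y_onehot) {
  arch <- model$arch
  p <- model$params
  cache <- fwd$cache
  B <- cache$B
  g <- list()
  dlogits <- (fwd$probs - Y_onehot) / B
  g$out_W <- crossprod(fwd$A_last, dlogits)
  g$out_b <- colSums(dlogits)
  dA <- dlogits %*% t(p$out_W)
  for (j in rev(seq_along(arch$dense_units))) {
    if (j == 2L && !is.null(cache$dropout)) dA <- dA * cache$dropout
    cc <- cache[[paste0("d", j)]]
    pb <- prelu_backward(dA, cc$Z, p[[paste0("d", j, "_alpha")]], cc$pr,
                         byrow = FALSE)
    g[[paste0("d", j, "_alpha")]] <- pb$dalpha
    g[[paste0("d", j, "_W")]] <- crossprod(cc$Ain, pb$dx)
    g[[paste0("d", j, "_b")]] <- colSums(pb$dx)
    dA <- pb$dx %*% t(p[[paste0("d", j, "_W")]])
  }
  u <- arch$lstm_units
  lc <- cache$lstm
  bf <- lstm_backward(dA[, 1:u, drop = FALSE], lc$lf$cache,
                      p$lstm_f_Wx, p$lstm_f_Wh)
  bb <- lstm_backward(dA[, (u + 1):(2 * u), drop = FALSE], lc$lb$cache,
                      p$lstm_b_Wx, p$lstm_b_Wh)
  g$lstm_f_Wx <- bf$dWx; g$lstm_f_Wh <- bf$dWh; g$lstm_f_b <- bf$db
  g$lstm_b_Wx <- bb$dWx; g$lstm_b_Wh <- bb$dWh; g$lstm_b_b <- bb$db
  # reassemble sequence gradient into C x (B*T)
  Tn <- lc$Tn; Cn <- lc$Cn
  dX <- matrix(0, Cn, B * Tn)
  for (t in seq_len(Tn)) {
    dstep <- t(bf$dxs[[t]] + bb$dxs[[Tn - t + 1L]])   # C x B
    dX[, (0:(B - 1L)) * Tn + t] <- dstep
  }
  for (i in rev(seq_along(arch$conv_blocks))) {
    pc <- cache[[paste0("pool", i)]]
    dX <- maxpool_backward(dX, pc$mp, pc$idx, pc$ncol_in)
    for (half in c("B", "A")) {
      id <- paste0("b", i, half)
      cc <- cache[[id]]
      pb <- prelu_backward(dX, cc$bn$y, p[[paste0(id, "_alpha")]], cc$pr,
                           byrow = TRUE)
      g[[paste0(id, "_alpha")]] <- pb$dalpha
      bnb <- bn_backward(pb$dx, cc$bn, p[[paste0(id, "_gamma")]])
      g[[paste0(id, "_gamma")]] <- bnb$dgamma
      g[[paste0(id, "_beta")]] <- bnb$dbeta
      cb <- conv1d_bwd(cc$XC, bnb$dx, B, cc$Tn,
                       p[[paste0(id, "_W")]], cc$k, cc$pad_l)
      g[[paste0(id, "_W")]] <- cb$dW
      g[[paste0(id, "_b")]] <- as.numeric(cb$db)
      dX <- cb$dX
    }
  }
  g
}

## ---- training / inference --------------------------------------------------

#' Train the CNN-BiLSTM on a dataset split
#'
#' Minibatch Adam optimisation of the categorical cross-entropy, with the
#' model checkpointed on best validation accuracy (the returned weights
#' are the best-validation ones, not the last).  Fully deterministic for a
#' fixed seed on a given platform.
#'
#' @param split a `dataset_split` from [interpatient_split()].
#' @param arch an [architecture_config()].
#' @param max_epochs training epochs; defaults to `arch$max_epochs`.
#' @param seed integer seed covering initialisation, shuffling and dropout.
#' @param batch_size minibatch size; defaults to `arch$batch_size`.
#' @param verbose print per-epoch progress.
#' @return Object of class `training_run`: `model` (best checkpoint),
#'   `history` (per-epoch losses/accuracies), `best_epoch`,
#'   `epochs_trained`, `seed`.
#' @export
train_cnn_bilstm <- function(split, arch = architecture_config(),
                             max_epochs = NULL, seed = 0,
                             batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(split, "dataset_split"))
  if (length(split$train) == 0L || length(split$validation) == 0L)
    stop("train and validation sets must be non-empty", call. = FALSE)
  if (is.null(max_epochs)) max_epochs <- arch$max_epochs
  if (is.null(batch_size)) batch_size <- arch$batch_size
  Ytr <- one_hot(split$train$label)
  if (nrow(Ytr) != length(split$train))
    stop("label/one-hot mismatch", call. = FALSE)
  Ttot <- dim(split$train$values)[3]
  if (Ttot != arch$input_steps)
    stop("epoch length does not match architecture input_steps",
         call. = FALSE)

  model <- build_cnn_bilstm(arch, seed = seed)
  Xtr_all <- split$train$values
  n <- dim(Xtr_all)[1]
  opt_state <- adam_init(model$params)
  history <- data.frame()
  best <- list(val_acc = -Inf, params = NULL, running = NULL, epoch = 0L)
  val_labels <- split$validation$label

  with_seed(seed + 1L, {
    for (ep in seq_len(max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        B <- length(idx)
        X <- epochs_to_input(Xtr_all[idx, , , drop = FALSE])
        Yb <- Ytr[idx, , drop = FALSE]
        fwd <- nn_forward(model, X, B, training = TRUE)
        model$running <- fwd$running
        loss <- -mean(rowSums(Yb * log(pmax(fwd$probs, 1e-12))))
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct +
          sum(max.col(fwd$probs, ties.method = "first") ==
              max.col(Yb, ties.method = "first"))
        grads <- nn_backward(model, fwd, Yb)
        upd <- adam_step(model$params, grads, opt_state, arch$optimizer)
        model$params <- upd$params
        opt_state <- upd$state
      }
      vp <- predict_epochs(model, split$validation)
      v_pred <- swallow_classes()[max.col(vp, ties.method = "first")]
      val_acc <- mean(v_pred == val_labels)
      val_loss <- -mean(log(pmax(vp[cbind(seq_along(val_labels),
                                          match(val_labels,
                                                swallow_classes()))],
                                 1e-12)))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val_loss, val_acc = val_acc))
      if (val_acc > best$val_acc) {
        best <- list(val_acc = val_acc, params = model$params,
                     running = model$running, epoch = ep)
      }
      if (verbose)
        message(sprintf(
          "epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
          ep, ep_loss / n, ep_correct / n, val_loss, val_acc))
    }
  })
  model$params <- best$params
  model$running <- best$running
  structure(list(model = model, history = history,
                 best_epoch = best$epoch,
                 best_val_accuracy = best$val_acc,
                 epochs_trained = max_epochs, seed = seed),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf(
    "<training_run> %d epochs, best validation accuracy %.3f at epoch %d\n",
    x$epochs_trained, x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' Per-epoch class probabilities
#'
#' Inference forward pass (batch-norm uses running statistics, dropout
#' disabled), so each epoch's probabilities are independent of the batch
#' it is evaluated in.  Rows sum to 1; argmax ties break toward the lowest
#' class index.
#'
#' @param model a `cnn_bilstm` (or `training_run`).
#' @param epochs an [epoch_set()], an `n x 3 x T` array, or one `3 x T`
#'   matrix.
#' @param batch_size inference batch size.
#' @return `n x 7` probability matrix with class-name columns.
#' @export
predict_epochs <- function(model, epochs, batch_size = 256L) {
  if (inherits(model, "training_run")) model <- model$model
  stopifnot(inherits(model, "cnn_bilstm"))
  vals <- if (inherits(epochs, "epoch_set")) epochs$values
          else if (is.matrix(epochs)) array(epochs, c(1, dim(epochs)))
          else epochs
  d <- dim(vals)
  if (length(d) != 3L || d[2] != model$arch$input_channels ||
      d[3] != model$arch$input_steps)
    stop(sprintf("epochs must be n x %d x %d",
                 model$arch$input_channels, model$arch$input_steps),
         call. = FALSE)
  n <- d[1]
  out <- matrix(0, n, model$arch$n_classes,
                dimnames = list(NULL, swallow_classes()[
                  seq_len(model$arch$n_classes)]))
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    X <- epochs_to_input(vals[idx, , , drop = FALSE])
    fwd <- nn_forward(model, X, length(idx), training = FALSE)
    out[idx, ] <- fwd$probs
  }
  out
}

#' Classify a whole recording into an event timeline
#'
#' Slides a 2-s window with 0.2-s hop over a preprocessed (250 Hz)
#' recording, takes the per-window argmax, merges consecutive identical
#' labels into events, and absorbs events shorter than `min_event_s` into
#' their longer neighbour.
#'
#' @param model a `cnn_bilstm` or `training_run`.
#' @param recording a [multimodal_recording()] at the model rate, at least
#'   2 s long.
#' @param hop_s sliding hop in seconds.
#' @param min_event_s minimum event duration; shorter runs are absorbed.
#' @return data.frame timeline: `start_s`, `end_s`, `class_label`,
#'   `mean_prob` (mean probability of the assigned class over the event's
#'   windows).
#' @export
classify_session <- function(model, recording, hop_s = 0.2,
                             min_event_s = 0.4) {
  if (inherits(model, "training_run")) model <- model$model
  stopifnot(inherits(recording, "multimodal_recording"))
  fs <- recording$fs_hz
  dur <- recording_duration(recording)
  if (dur < EPOCH_SECONDS)
    stop("recording shorter than one 2-s window", call. = FALSE)
  nsamp <- round(EPOCH_SECONDS * fs)
  starts <- seq(0, dur - EPOCH_SECONDS + 1e-9, by = hop_s)
  vals <- array(0, c(length(starts), 3L, nsamp))
  for (i in seq_along(starts))
    vals[i, , ] <- extract_window(recording, starts[i], nsamp)
  probs <- predict_epochs(model, vals)
  lab <- swallow_classes()[max.col(probs, ties.method = "first")]
  # each window owns [start, start + hop); the last runs to the end
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  begins <- c(1L, head(ends, -1L) + 1L)
  ev <- data.frame(start_s = starts[begins],
                   end_s = c(starts[head(ends, -1L) + 1L], dur),
                   class_label = r$values, stringsAsFactors = FALSE)
  # absorb sub-threshold events into the longer adjacent neighbour
  repeat {
    len <- ev$end_s - ev$start_s
    short <- which(len < min_event_s - 1e-9)
    if (!length(short) || nrow(ev) == 1L) break
    i <- short[which.min(len[short])]
    nb <- if (i == 1L) 2L
          else if (i == nrow(ev)) i - 1L
          else if (len[i - 1L] >= len[i + 1L]) i - 1L else i + 1L
    ev$class_label[i] <- ev$class_label[nb]
    # merge adjacent duplicates
    keep <- c(TRUE, ev$class_label[-1L] != head(ev$class_label, -1L))
    grp <- cumsum(keep)
    ev <- data.frame(start_s = tapply(ev$start_s, grp, min),
                     end_s = tapply(ev$end_s, grp, max),
                     class_label = ev$class_label[keep],
                     stringsAsFactors = FALSE)
    rownames(ev) <- NULL
  }
  ev$mean_prob <- vapply(seq_len(nrow(ev)), function(i) {
    inwin <- starts >= ev$start_s[i] - 1e-9 & starts < ev$end_s[i] - 1e-9
    if (!any(inwin)) inwin[which.min(abs(starts - ev$start_s[i]))] <- TRUE
    mean(probs[inwin, ev$class_label[i]])
  }, 0)
  attr(ev, "n_windows") <- length(starts)
  ev
}
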