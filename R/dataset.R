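## Epoching and dataset assembly: filtered 250 Hz recordings are cut into
## 2-s, 3-channel windows, min-max normalised to [0, 1], optionally
## augmented by +0.2 s time shifts with overlap-based re-labelling, and
## split into participant-disjoint train/validation/test sets.

EPOCH_SECONDS <- 2
SHIFT_SECONDS <- 0.2

#' Preprocess a raw recording for the classifier
#'
#' Applies the EMG bandpass + notch to both muscle channels, spectral
#' subtraction (noise profile from the leading rest gap when present) and
#' the 10--900 Hz bandpass to the acoustic channel, then Fourier-resamples
#' all channels to the model rate.  Annotations are carried over unchanged
#' (they are in seconds).
#'
#' @param rec a [multimodal_recording()] at the acquisition rate.
#' @param spec a [filter_spec()].
#' @param denoise_sound apply spectral subtraction using the pre-event rest
#'   segment as the noise profile.
#' @return A [multimodal_recording()] at `spec$model_fs_hz`.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(),
                                 denoise_sound = TRUE) {
  stopifnot(inherits(rec, "multimodal_recording"))
  fs <- rec$fs_hz
  e1 <- filter_emg(rec$emg_ch1, fs, spec)
  e2 <- filter_emg(rec$emg_ch2, fs, spec)
  rest_ref <- NULL
  if (denoise_sound) {
    first_ev <- if (nrow(rec$annotations)) min(rec$annotations$start_s)
                else recording_duration(rec)
    n_rest <- floor(min(first_ev, 2) * fs)
    if (n_rest >= 64L) rest_ref <- rec$sound[seq_len(n_rest)]
  }
  sd_ <- filter_sound(rec$sound, fs, spec, rest_ref = rest_ref)
  fo <- spec$model_fs_hz
  ann <- rec$annotations
  if (nrow(ann)) {
    # length rounding in the resampler can trim a few ms off the end
    new_dur <- round(length(e1) * fo / fs) / fo
    ann$end_s <- pmin(ann$end_s, new_dur)
  }
  rec$annotations <- ann
  multimodal_recording(resample_series(e1, fs, fo),
                       resample_series(e2, fs, fo),
                       resample_series(sd_, fs, fo),
                       fo, rec$participant_id, rec$annotations, rec$truth)
}

## ---- epoch container ------------------------------------------------------

#' Epoch set container
#'
#' Stores n epochs as an `n x 3 x T` array (channels emg1, emg2, sound)
#' plus per-epoch label, participant id and augmentation shift.
#'
#' @param values numeric array `n x 3 x T`.
#' @param label character vector of class labels.
#' @param participant_id character vector.
#' @param shift_s numeric vector of applied augmentation offsets (>= 0).
#' @param fs_hz sampling rate of the epochs.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(values, label, participant_id, shift_s = NULL,
                      fs_hz = 250) {
  n <- dim(values)[1]
  stopifnot(length(dim(values)) == 3L, dim(values)[2] == 3L,
            length(label) == n, length(participant_id) == n)
  if (is.null(shift_s)) shift_s <- rep(0, n)
  stopifnot(all(shift_s >= 0))
  lapply(unique(label), assert_class_label)
  structure(list(values = values, label = label,
                 participant_id = participant_id,
                 shift_s = shift_s, fs_hz = fs_hz),
            class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) dim(x$values)[1]

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d x %d), %d participants\n",
              length(x), dim(x$values)[2], dim(x$values)[3],
              length(unique(x$participant_id))))
  print(table(x$label))
  invisible(x)
}

# concatenate epoch sets
bind_epochs <- function(...) {
  sets <- Filter(function(s) length(s) > 0, list(...))
  if (!length(sets)) stop("nothing to bind", call. = FALSE)
  vals <- do.call(abind3, lapply(sets, `[[`, "values"))
  epoch_set(vals,
            unlist(lapply(sets, `[[`, "label")),
            unlist(lapply(sets, `[[`, "participant_id")),
            unlist(lapply(sets, `[[`, "shift_s")),
            sets[[1]]$fs_hz)
}

# rbind for n x 3 x T arrays
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], integer(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1]
    if (k) out[(at + 1L):(at + k), , ] <- x
    at <- at + k
  }
  out
}

subset_epochs <- function(es, idx) {
  epoch_set(es$values[idx, , , drop = FALSE], es$label[idx],
            es$participant_id[idx], es$shift_s[idx], es$fs_hz)
}

#' Min-max normalise one epoch
#'
#' Per-channel scaling of a `3 x T` matrix to the unit interval, as the
#' classifier expects.  A constant channel maps to all 0.5 (degenerate
#' rule, documented); the map is idempotent on non-degenerate input.
#'
#' @param m numeric `3 x T` matrix with finite entries.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
normalize_epoch <- function(m) {
  if (!is.matrix(m) || any(!is.finite(m)))
    stop("epoch must be a finite numeric matrix", call. = FALSE)
  out <- m
  for (c in seq_len(nrow(m))) {
    rng <- range(m[c, ])
    out[c, ] <- if (rng[2] > rng[1]) (m[c, ] - rng[1]) / (rng[2] - rng[1])
                else rep(0.5, ncol(m))
  }
  out
}

# z-score alternative kept behind a flag (the published description of the
# scaler is ambiguous; min-max is the default reading)
standardize_epoch <- function(m) {
  out <- m
  for (c in seq_len(nrow(m))) {
    s <- sd(m[c, ])
    out[c, ] <- if (s > 0) (m[c, ] - mean(m[c, ])) / s else 0
  }
  out
}

#' One-hot encode class labels
#'
#' @param label character vector of class labels.
#' @return `length(label) x 7` matrix; column order fixed by
#'   [swallow_classes()].
#' @export
one_hot <- function(label) {
  cls <- swallow_classes()
  lapply(label, assert_class_label)
  m <- matrix(0, length(label), length(cls),
              dimnames = list(NULL, cls))
  m[cbind(seq_along(label), match(label, cls))] <- 1
  m
}

# pull one window of all three channels, normalised
extract_window <- function(rec, start_s, nsamp) {
  i0 <- round(start_s * rec$fs_hz) + 1L
  idx <- i0:(i0 + nsamp - 1L)
  normalize_epoch(rbind(rec$emg_ch1[idx], rec$emg_ch2[idx], rec$sound[idx]))
}

#' Segment a preprocessed recording into labelled epochs
#'
#' Each annotated event is tiled with consecutive non-overlapping 2-s
#' windows anchored at the event start (an event shorter than 2 s still
#' yields one window, which runs into the following rest); trailing
#' partial windows are discarded.  Unannotated stretches are tiled with
#' rest epochs.
#'
#' @param rec a [multimodal_recording()] resampled to the model rate.
#' @return An [epoch_set()].
#' @export
segment_epochs <- function(rec) {
  stopifnot(inherits(rec, "multimodal_recording"))
  fs <- rec$fs_hz
  dur <- recording_duration(rec)
  if (dur < EPOCH_SECONDS - 1e-9)
    stop("recording shorter than one 2-s epoch", call. = FALSE)
  nsamp <- round(EPOCH_SECONDS * fs)
  windows <- list()
  ann <- rec$annotations
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      ev_dur <- ann$end_s[i] - ann$start_s[i]
      k_max <- max(1L, floor(ev_dur / EPOCH_SECONDS + 1e-9))
      for (k in seq_len(k_max)) {
        st <- ann$start_s[i] + (k - 1L) * EPOCH_SECONDS
        if (st + EPOCH_SECONDS <= dur + 1e-9)
          windows[[length(windows) + 1L]] <-
            list(start = st, label = ann$class_label[i])
      }
    }
  }
  # rest tiling of the gaps left between event windows
  occupied <- if (length(windows)) {
    cbind(vapply(windows, `[[`, 0, "start"),
          vapply(windows, `[[`, 0, "start") + EPOCH_SECONDS)
  } else matrix(numeric(0), ncol = 2)
  if (nrow(ann))
    occupied <- rbind(occupied, cbind(ann$start_s, ann$end_s))
  gaps <- free_intervals(occupied, dur)
  for (g in gaps) {
    n_rest <- floor((g[2] - g[1]) / EPOCH_SECONDS + 1e-9)
    for (k in seq_len(max(0L, n_rest)))
      windows[[length(windows) + 1L]] <-
        list(start = g[1] + (k - 1L) * EPOCH_SECONDS, label = "rest")
  }
  ord <- order(vapply(windows, `[[`, 0, "start"))
  windows <- windows[ord]
  vals <- array(0, c(length(windows), 3L, nsamp))
  for (i in seq_along(windows))
    vals[i, , ] <- extract_window(rec, windows[[i]]$start, nsamp)
  es <- epoch_set(vals,
                  vapply(windows, `[[`, "", "label"),
                  rep(rec$participant_id, length(windows)),
                  fs_hz = fs)
  attr(es, "window_start_s") <- vapply(windows, `[[`, 0, "start")
  es
}

# complement of a set of [start, end) intervals within [0, total]
free_intervals <- function(occ, total) {
  if (!nrow(occ)) return(list(c(0, total)))
  occ <- occ[order(occ[, 1]), , drop = FALSE]
  merged <- list()
  cur <- occ[1, ]
  for (i in seq_len(nrow(occ))[-1]) {
    if (occ[i, 1] <= cur[2] + 1e-9) cur[2] <- max(cur[2], occ[i, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- occ[i, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  gaps <- list()
  prev <- 0
  for (m in merged) {
    if (m[1] > prev + 1e-9) gaps[[length(gaps) + 1L]] <- c(prev, m[1])
    prev <- max(prev, m[2])
  }
  if (total > prev + 1e-9) gaps[[length(gaps) + 1L]] <- c(prev, total)
  gaps
}

# label a window by the annotation covering the majority of it; ties break
# toward the non-rest class; no majority -> rest
overlap_label <- function(ann, start_s, end_s) {
  if (!nrow(ann)) return("rest")
  ov <- pmin(ann$end_s, end_s) - pmax(ann$start_s, start_s)
  best <- which.max(ov)
  w <- end_s - start_s
  if (ov[best] >= w / 2 - 1e-9 && ov[best] > 0) ann$class_label[best]
  else "rest"
}

#' Time-shift augmentation
#'
#' For each source epoch, re-extracts up to `n_shifts` windows displaced by
#' positive multiples of 0.2 s and re-labels each by the class whose
#' annotation overlaps the majority of the shifted window (the automated
#' stand-in for the manual re-labelling of shifted samples).  Shifts
#' running past the recording end are skipped and tallied.
#'
#' @param epochs an [epoch_set()] produced by [segment_epochs()] from
#'   `recording` (window start times are taken from its attributes).
#' @param recording the source [multimodal_recording()].
#' @param shift_s shift grid step, seconds.
#' @param n_shifts shifted copies per source epoch.
#' @return An [epoch_set()] containing the originals followed by the
#'   shifted epochs; attribute `skipped` counts out-of-bounds shifts.
#' @export
augment_epochs <- function(epochs, recording, shift_s = SHIFT_SECONDS,
                           n_shifts = 3) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(recording, "multimodal_recording"))
  starts <- attr(epochs, "window_start_s")
  if (is.null(starts))
    stop("epochs must carry window start times (use segment_epochs)",
         call. = FALSE)
  if (n_shifts == 0) { attr(epochs, "skipped") <- 0L; return(epochs) }
  fs <- recording$fs_hz
  dur <- recording_duration(recording)
  nsamp <- round(EPOCH_SECONDS * fs)
  new_vals <- list(); new_lab <- character(0); new_shift <- numeric(0)
  skipped <- 0L
  for (i in seq_len(length(epochs))) {
    for (k in seq_len(n_shifts)) {
      st <- starts[i] + k * shift_s
      if (st + EPOCH_SECONDS > dur + 1e-9) { skipped <- skipped + 1L; next }
      new_vals[[length(new_vals) + 1L]] <-
        extract_window(recording, st, nsamp)
      new_lab <- c(new_lab,
                   overlap_label(recording$annotations, st,
                                 st + EPOCH_SECONDS))
      new_shift <- c(new_shift, round(k * shift_s, 6))
    }
  }
  if (!length(new_vals)) { attr(epochs, "skipped") <- skipped; return(epochs) }
  arr <- array(0, c(length(new_vals), 3L, nsamp))
  for (i in seq_along(new_vals)) arr[i, , ] <- new_vals[[i]]
  out <- bind_epochs(epochs,
                     epoch_set(arr, new_lab,
                               rep(recording$participant_id, length(new_lab)),
                               new_shift, fs))
  attr(out, "skipped") <- skipped
  out
}

#' Participant-disjoint train/validation/test split
#'
#' Whole participants are assigned to the three partitions so that no
#' participant's epochs (including augmented copies) appear in more than
#' one set.  A seeded greedy pass (largest participants first, assigned to
#' the arm with the largest remaining epoch deficit) is followed by a local
#' improvement pass moving single participants while it reduces the total
#' deviation from the target 60:20:20 epoch counts.
#'
#' @param epochs an [epoch_set()] with at least 3 distinct participants.
#' @param ratio length-3 target epoch fractions summing to 1.
#' @param seed integer; makes tie-breaking deterministic.
#' @return Object of class `dataset_split` with elements `train`,
#'   `validation`, `test` (epoch sets), `onehot` (list of matrices),
#'   `assignment` (participant -> arm) and `achieved` counts.
#' @export
interpatient_split <- function(epochs, ratio = c(0.6, 0.2, 0.2), seed = 0) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (abs(sum(ratio) - 1) > 1e-9 || length(ratio) != 3L)
    stop("ratio must be three fractions summing to 1", call. = FALSE)
  parts <- table(epochs$participant_id)
  if (length(parts) < 3L)
    stop("need at least 3 distinct participants for a disjoint 3-way split",
         call. = FALSE)
  counts <- as.integer(parts)
  ids <- names(parts)
  n <- length(epochs)
  target <- ratio * n
  ord <- with_seed(seed, {
    shuffled <- sample(seq_along(ids))
    shuffled[order(-counts[shuffled])]      # size-descending, seeded ties
  })
  arm <- integer(length(ids))
  tot <- numeric(3)
  for (i in ord) {
    deficit <- target - tot
    arm[i] <- which.max(deficit)
    tot[arm[i]] <- tot[arm[i]] + counts[i]
  }
  # repair: every arm must hold at least one participant
  for (a in 1:3) {
    if (!any(arm == a)) {
      donor_arm <- which.max(tabulate(arm, 3))
      cand <- which(arm == donor_arm)
      i <- cand[which.min(counts[cand])]
      tot[donor_arm] <- tot[donor_arm] - counts[i]
      arm[i] <- a
      tot[a] <- tot[a] + counts[i]
    }
  }
  # local improvement: single-participant moves and pairwise swaps while
  # the deviation from the target counts decreases
  dev <- function(tot) sum(abs(tot - target))
  repeat {
    improved <- FALSE
    for (i in seq_along(ids)) {
      for (a in 1:3) {
        if (a == arm[i]) next
        if (sum(arm == arm[i]) == 1L) next   # keep all arms non-empty
        tot2 <- tot
        tot2[arm[i]] <- tot2[arm[i]] - counts[i]
        tot2[a] <- tot2[a] + counts[i]
        if (dev(tot2) < dev(tot) - 1e-9) {
          tot <- tot2; arm[i] <- a; improved <- TRUE
        }
      }
    }
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (arm[i] == arm[j] || counts[i] == counts[j]) next
        tot2 <- tot
        tot2[arm[i]] <- tot2[arm[i]] - counts[i] + counts[j]
        tot2[arm[j]] <- tot2[arm[j]] - counts[j] + counts[i]
        if (dev(tot2) < dev(tot) - 1e-9) {
          tot <- tot2
          ai <- arm[i]; arm[i] <- arm[j]; arm[j] <- ai
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  assignment <- setNames(c("train", "validation", "test")[arm], ids)
  sel <- function(a) {
    idx <- which(epochs$participant_id %in% ids[arm == a])
    subset_epochs(epochs, idx)
  }
  out <- list(train = sel(1), validation = sel(2), test = sel(3),
              assignment = assignment,
              achieved = setNames(tot, c("train", "validation", "test")),
              target = setNames(target, c("train", "validation", "test")),
              ratio = ratio, seed = seed)
  out$onehot <- lapply(out[c("train", "validation", "test")],
                       function(s) one_hot(s$label))
  structure(out, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d epochs\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}
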