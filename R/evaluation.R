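#' Seven-class confusion matrix
#'
#' Rows are true classes, columns predicted classes, both in the fixed
#' [swallow_classes()] order.
#'
#' @param true_labels,predicted_labels equal-length character vectors over
#'   the 7-class set.
#' @return Object of class `confusion_matrix` (an integer matrix).
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label sequences must have equal length", call. = FALSE)
  cls <- swallow_classes()
  lapply(unique(c(true_labels, predicted_labels)), assert_class_label)
  m <- table(factor(true_labels, levels = cls),
             factor(predicted_labels, levels = cls))
  structure(matrix(as.integer(m), length(cls), length(cls),
                   dimnames = list(true = cls, predicted = cls)),
            class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") || (is.matrix(cm) &&
            nrow(cm) == ncol(cm)))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  invisible(cm)
}

#' Overall accuracy
#' @param cm a [confusion_matrix()].
#' @return trace / total, a fraction in `[0, 1]`.
#' @export
cm_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' One-vs-rest sensitivity (recall) for one class
#' @param cm a [confusion_matrix()].
#' @param class class label or index.
#' @return `TP / (TP + FN)`.
#' @export
cm_sensitivity <- function(cm, class) {
  check_cm(cm)
  i <- if (is.character(class)) match(class, rownames(cm)) else class
  if (is.na(i)) stop("unknown class", call. = FALSE)
  denom <- sum(cm[i, ])
  if (denom == 0)
    stop("sensitivity undefined: no true instances of class", call. = FALSE)
  cm[i, i] / denom
}

#' One-vs-rest specificity (true-negative rate) for one class
#' @param cm a [confusion_matrix()].
#' @param class class label or index.
#' @return `TN / (TN + FP)` treating all other classes as negative.
#' @export
cm_specificity <- function(cm, class) {
  check_cm(cm)
  i <- if (is.character(class)) match(class, rownames(cm)) else class
  if (is.na(i)) stop("unknown class", call. = FALSE)
  tn <- sum(cm[-i, -i])
  fp <- sum(cm[-i, i])
  if (tn + fp == 0)
    stop("specificity undefined: no negative instances", call. = FALSE)
  tn / (tn + fp)
}

#' Electrode-placement quality control
#'
#' Implements the pre-test rule: the SNR of the first annotated swallow
#' burst against the inactivity period immediately preceding it must
#' exceed 6 dB for the location to pass.  The noise window is the 2 s
#' before the first event (or as much of it as exists).
#'
#' @param pre_test_recording a [multimodal_recording()] with at least one
#'   annotated swallow and a leading inactivity segment.
#' @param channel which EMG channel to check, 1 or 2 (or `"both"`).
#' @param threshold_db pass threshold in dB.
#' @return Object of class `placement_check`: per-channel `snr_db` and
#'   logical `verdict` (pass above threshold).
#' @export
placement_check <- function(pre_test_recording, channel = "both",
                            threshold_db = 6) {
  rec <- pre_test_recording
  stopifnot(inherits(rec, "multimodal_recording"))
  ann <- rec$annotations
  if (!nrow(ann))
    stop("no annotated swallow in the pre-test recording", call. = FALSE)
  ev <- ann[which.min(ann$start_s), ]
  fs <- rec$fs_hz
  noise_start <- max(0, ev$start_s - 2)
  n0 <- floor(noise_start * fs) + 1L
  n1 <- floor(ev$start_s * fs)
  if (n1 - n0 < round(0.1 * fs))
    stop(paste("no inactivity segment identifiable before the first",
               "swallow; re-record with a resting lead-in of >= 2 s"),
         call. = FALSE)
  s0 <- floor(ev$start_s * fs) + 1L
  s1 <- min(length(rec$emg_ch1), floor(ev$end_s * fs))
  chans <- if (identical(channel, "both")) 1:2 else as.integer(channel)
  res <- lapply(chans, function(ch) {
    x <- if (ch == 1L) rec$emg_ch1 else rec$emg_ch2
    snr_db(x[s0:s1], x[n0:n1])$snr_db
  })
  snr <- setNames(unlist(res), paste0("emg_ch", chans))
  structure(list(snr_db = snr, threshold_db = threshold_db,
                 verdict = snr > threshold_db),
            class = "placement_check")
}

#' @export
print.placement_check <- function(x, ...) {
  for (nm in names(x$snr_db))
    cat(sprintf("%s: %.2f dB -> %s (threshold %g dB)\n", nm,
                x$snr_db[[nm]],
                if (x$verdict[[nm]]) "PASS" else "FAIL", x$threshold_db))
  invisible(x)
}

#' Automatic session report
#'
#' Summarises a classified timeline: per-class event counts and total
#' durations, every silent-aspiration event flagged with its timestamp,
#' and (optionally) the evaluation metrics of a supplied confusion matrix.
#' `format()`/`print()` render the human-readable page;
#' [write_session_report()] also serialises a machine-readable JSON
#' summary and diagnostic plots.
#'
#' @param timeline data.frame from [classify_session()].
#' @param cm optional [confusion_matrix()] to embed.
#' @return Object of class `session_report`.
#' @export
session_report <- function(timeline, cm = NULL) {
  stopifnot(is.data.frame(timeline))
  cls <- swallow_classes()
  if (nrow(timeline)) {
    durs <- timeline$end_s - timeline$start_s
    counts <- table(factor(timeline$class_label, levels = cls))
    total_dur <- tapply(durs, factor(timeline$class_label, levels = cls),
                        sum, default = 0)
    aspiration <- timeline[timeline$class_label == "silent_aspiration", ,
                           drop = FALSE]
  } else {
    counts <- table(factor(character(0), levels = cls))
    total_dur <- setNames(rep(0, length(cls)), cls)
    aspiration <- timeline
  }
  structure(list(timeline = timeline,
                 event_counts = counts,
                 event_durations_s = total_dur,
                 aspiration_events = aspiration,
                 confusion = cm),
            class = "session_report")
}

#' @export
format.session_report <- function(x, ...) {
  out <- c("=== Swallowing session report ===")
  if (!nrow(x$timeline)) {
    out <- c(out, "no events detected")
    return(paste(out, collapse = "\n"))
  }
  out <- c(out, sprintf("recording span: %.1f s, %d events",
                        max(x$timeline$end_s), nrow(x$timeline)))
  for (cls in names(x$event_counts)) {
    if (x$event_counts[[cls]] > 0)
      out <- c(out, sprintf("  %-18s %3d event(s), %6.1f s total", cls,
                            x$event_counts[[cls]],
                            x$event_durations_s[[cls]]))
  }
  na <- nrow(x$aspiration_events)
  out <- c(out, sprintf("silent aspiration alerts: %d", na))
  if (na > 0)
    out <- c(out, sprintf("  !! aspiration at %.1f s (%.1f s long, p=%.2f)",
                          x$aspiration_events$start_s,
                          x$aspiration_events$end_s -
                            x$aspiration_events$start_s,
                          x$aspiration_events$mean_prob))
  if (!is.null(x$confusion))
    out <- c(out, sprintf("test accuracy: %.2f%%",
                          100 * cm_accuracy(x$confusion)))
  paste(out, collapse = "\n")
}

#' @export
print.session_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a session report to disk
#'
#' Emits `report.txt` (human-readable page), `report.json`
#' (machine-readable summary) and, when a recording is supplied,
#' `report_plots.png` with the acoustic spectrogram and EMG envelopes.
#'
#' @param report a [session_report()].
#' @param dir output directory, created if missing.
#' @param recording optional preprocessed recording for the plots.
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(report, dir, recording = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(format(report), file.path(dir, "report.txt"))
  js <- list(event_counts = as.list(report$event_counts),
             event_durations_s = as.list(report$event_durations_s),
             aspiration_events = report$aspiration_events,
             timeline = report$timeline)
  if (!is.null(report$confusion))
    js$metrics <- list(
      accuracy = cm_accuracy(report$confusion),
      sensitivity = sapply(swallow_classes(), function(cl)
        tryCatch(cm_sensitivity(report$confusion, cl),
                 error = function(e) NA_real_)),
      specificity = sapply(swallow_classes(), function(cl)
        tryCatch(cm_specificity(report$confusion, cl),
                 error = function(e) NA_real_)))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(recording)) {
    grDevices::png(file.path(dir, "report_plots.png"), width = 900,
                   height = 600)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    sp <- stft_spectrogram(recording$sound, recording$fs_hz)
    graphics::image(sp$time_s, sp$freq_hz, t(log10(sp$magnitude + 1e-9)),
                    xlab = "time (s)", ylab = "frequency (Hz)",
                    main = "acoustic spectrogram")
    tt <- (seq_along(recording$emg_ch1) - 1) / recording$fs_hz
    graphics::plot(tt, abs(recording$emg_ch1), type = "l", col = "grey40",
                   xlab = "time (s)", ylab = "|EMG| (uV)",
                   main = "EMG envelopes")
    graphics::lines(tt, abs(recording$emg_ch2), col = "tomato")
  }
  invisible(dir)
}
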