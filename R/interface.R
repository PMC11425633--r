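## Project-wide configuration and file I/O.  Recordings travel as one
## delimited-text file per participant (time + 3 signal columns, with
## sampling rate and participant id in comment headers) plus an
## annotation sidecar; the acoustic channel can be mirrored to 16-bit PCM
## WAV.  The full pipeline chains simulate -> preprocess -> dataset ->
## train -> evaluate -> report from a single seed.

PIPELINE_CONFIG_VERSION <- "1.0"

#' Default pipeline configuration
#'
#' Every tunable default of the pipeline, grouped by stage.  The object
#' round-trips through JSON unchanged ([write_pipeline_config()] /
#' [read_pipeline_config()]); unknown keys are rejected on read.
#'
#' @param ... replacement values for top-level groups, e.g.
#'   `simulate = list(n_participants = 5)` (merged into the defaults).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    version = PIPELINE_CONFIG_VERSION,
    simulate = list(n_participants = 20L, events_per_participant = 10L,
                    gap_s = 5, seed_offset = 0L,
                    noise = default_noise_spec(),
                    gain_range = c(0.7, 1.3), template_jitter = 1),
    filters = unclass(filter_spec()),
    dataset = list(shift_s = SHIFT_SECONDS, n_shifts = 3L,
                   ratio = c(0.6, 0.2, 0.2)),
    classifier = list(batch_size = 32L, max_epochs = 30L,
                      learning_rate = 0.001, dropout = 0.2),
    evaluation = list(placement_threshold_db = 6,
                      min_event_s = 0.4, hop_s = 0.2))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown config group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots)) {
    bad_keys <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
    if (length(bad_keys))
      stop("unknown key(s) in '", nm, "': ",
           paste(bad_keys, collapse = ", "), call. = FALSE)
    cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- raw$version
  raw$version <- NULL
  cfg <- do.call(pipeline_config, raw)
  cfg$version <- ver
  cfg
}

## ---- recording I/O ---------------------------------------------------------

annotation_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0("_annotations.tsv")
}

#' Write / read a multimodal recording
#'
#' The signal file is tab-separated with columns `time_s`, `emg1_uV`,
#' `emg2_uV`, `sound`, preceded by `# fs_hz=` and `# participant=` header
#' comments; annotations go to a `<name>_annotations.tsv` sidecar with
#' columns `start_s`, `end_s`, `class_label`.  The round-trip is lossless
#' to the printed precision (15 significant digits).
#'
#' @param recording a [multimodal_recording()].
#' @param path signal file path (`.tsv`).
#' @param digits signal precision in significant digits.
#' @return `path` invisibly (write); a recording (read).
#' @export
write_recording <- function(recording, path, digits = 15) {
  stopifnot(inherits(recording, "multimodal_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs_hz=%.10g", recording$fs_hz),
               sprintf("# participant=%s", recording$participant_id),
               "time_s\temg1_uV\temg2_uV\tsound"), con)
  n <- length(recording$emg_ch1)
  df <- data.frame(
    time_s = signif((seq_len(n) - 1) / recording$fs_hz, digits),
    emg1_uV = signif(recording$emg_ch1, digits),
    emg2_uV = signif(recording$emg_ch2, digits),
    sound = signif(recording$sound, digits))
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  write.table(recording$annotations, annotation_path(path), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param path signal file path written by [write_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln))
      stop("missing '# ", key, "=' header in ", path, " (line 1-2)",
           call. = FALSE)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  fs <- as.numeric(getval("fs_hz"))
  pid <- getval("participant")
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  need <- c("time_s", "emg1_uV", "emg2_uV", "sound")
  if (!all(need %in% names(df)))
    stop("signal file ", path, " must have columns ",
         paste(need, collapse = ", "), "; found ",
         paste(names(df), collapse = ", "), call. = FALSE)
  apath <- annotation_path(path)
  if (!file.exists(apath))
    stop("missing annotation sidecar: expected ", apath, call. = FALSE)
  ann <- read.table(apath, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (nrow(ann) && !all(c("start_s", "end_s", "class_label") %in%
                        names(ann)))
    stop("annotation sidecar ", apath,
         " must have columns start_s, end_s, class_label", call. = FALSE)
  multimodal_recording(df$emg1_uV, df$emg2_uV, df$sound, fs,
                       participant_id = pid, annotations = ann)
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF container for mirroring the acoustic channel; samples are
#' scaled by `scale` and clipped to the 16-bit range, so the round-trip
#' error is at most one quantisation step.
#'
#' @param x numeric vector of samples.
#' @param path output `.wav` path.
#' @param fs_hz sampling rate.
#' @param scale full-scale amplitude (maps to 32767).
#' @return `path` invisibly (write); `list(x, fs_hz)` (read).
#' @export
write_wav <- function(x, path, fs_hz, scale = max(abs(x), 1e-12)) {
  pcm <- as.integer(pmax(-32767, pmin(32767, round(x / scale * 32767))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36 + 2 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16)
  w_u16(1); w_u16(1); w_u32(round(fs_hz)); w_u32(round(fs_hz) * 2)
  w_u16(2); w_u16(16)
  writeChar("data", con, eos = NULL); w_u32(2 * n)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  readChar(con, 8)                            # "WAVEfmt "
  fmt_len <- readBin(con, integer(), 1, size = 4, endian = "little")
  fmt <- readBin(con, integer(), fmt_len / 2, size = 2, endian = "little")
  fs_lo <- if (fmt[3] < 0) fmt[3] + 65536 else fmt[3]
  fs <- fs_lo + 65536 * fmt[4]
  readChar(con, 4)                            # "data"
  nbytes <- readBin(con, integer(), 1, size = 4, endian = "little")
  x <- readBin(con, integer(), nbytes / 2, size = 2, endian = "little")
  list(x = x / 32767, fs_hz = fs)
}

## ---- end-to-end pipeline ---------------------------------------------------

#' Run the full pipeline on synthetic data
#'
#' simulate -> write recordings -> preprocess -> epoch + augment ->
#' participant-disjoint split -> train -> test metrics -> session report,
#' everything seeded from the single `seed`.  Each stage logs its
#' parameters; artifacts land in `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param log_fn logging callback, default `message`.
#' @return Invisible list with the split, training run, confusion matrix
#'   and report paths.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = tempfile("deglutio_run_"),
                         log_fn = message) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    log_fn(sprintf("[%s] starting", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (partial artifacts in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE))
  }
  sim <- config$simulate
  recs <- stage("simulate", generate_session(
    sim$n_participants, sim$events_per_participant,
    noise_spec = sim$noise, seed = seed + sim$seed_offset,
    gap_s = sim$gap_s, gain_range = sim$gain_range,
    template_jitter = sim$template_jitter))
  stage("write", {
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in recs)
      write_recording(r, file.path(rec_dir,
                                   paste0(r$participant_id, ".tsv")),
                      digits = 6)
  })
  spec <- do.call(filter_spec, config$filters)
  pre <- stage("preprocess", lapply(recs, preprocess_recording,
                                    spec = spec))
  epochs <- stage("dataset", {
    sets <- lapply(pre, function(r)
      augment_epochs(segment_epochs(r), r,
                     shift_s = config$dataset$shift_s,
                     n_shifts = config$dataset$n_shifts))
    do.call(bind_epochs, sets)
  })
  split <- stage("split", interpatient_split(epochs,
                                             ratio = config$dataset$ratio,
                                             seed = seed))
  log_fn(sprintf("[split] train/val/test = %s",
                 paste(split$achieved, collapse = "/")))
  arch <- architecture_config(
    learning_rate = config$classifier$learning_rate,
    dropout = config$classifier$dropout,
    batch_size = config$classifier$batch_size,
    max_epochs = config$classifier$max_epochs)
  run <- stage("train", train_cnn_bilstm(split, arch, seed = seed))
  cmx <- stage("evaluate", {
    probs <- predict_epochs(run$model, split$test)
    pred <- swallow_classes()[max.col(probs, ties.method = "first")]
    cm <- confusion_matrix(split$test$label, pred)
    utils::write.table(unclass(cm), file.path(out_dir, "metrics_cm.tsv"),
                       sep = "\t", quote = FALSE)
    metrics <- data.frame(
      class = swallow_classes(),
      sensitivity = sapply(seq_len(7), function(i)
        tryCatch(cm_sensitivity(cm, i), error = function(e) NA_real_)),
      specificity = sapply(seq_len(7), function(i)
        tryCatch(cm_specificity(cm, i), error = function(e) NA_real_)))
    utils::write.table(metrics, file.path(out_dir, "metrics_per_class.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cm
  })
  report <- stage("report", {
    timeline <- classify_session(run$model, pre[[1]],
                                 hop_s = config$evaluation$hop_s,
                                 min_event_s = config$evaluation$min_event_s)
    rep <- session_report(timeline, cm = cmx)
    write_session_report(rep, file.path(out_dir, "report"),
                         recording = pre[[1]])
    rep
  })
  saveRDS(list(split_assignment = split$assignment, seed = seed,
               history = run$history), file.path(out_dir, "run_state.rds"))
  log_fn(sprintf("[done] accuracy %.3f, artifacts in %s",
                 cm_accuracy(cmx), out_dir))
  invisible(list(split = split, run = run, confusion = cmx,
                 report = report, out_dir = out_dir))
}
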