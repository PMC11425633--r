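## Synthetic multimodal swallowing sessions.
##
## The generative model mirrors the physiology of a normal swallow: the
## digastric (suprahyoid) burst leads, the first swallowing sound wave
## (SSW1) marks pharyngeal propulsion and airway closure, the sternohyoid
## (infrahyoid) burst begins between SSW1 and SSW2 as the hyoid is pulled
## back down, SSW2 marks pharyngoesophageal closure, and SSW3 marks
## laryngeal return and esophageal clearance.  Bolus consistency scales
## burst duration and intensity (liquid < soft food < dense food).  Silent
## aspiration is rendered as a stretched, desynchronised variant with a
## weakened infrahyoid burst; cough as a single loud broadband sound burst
## with brief EMG co-activation; chewing as rhythmic suprahyoid bursts with
## little sound.  All quantitative defaults are simulator choices (the
## underlying physiology is qualitative); they are exposed here and
## documented in the methods vignette.

#' Default event template for a swallowing class
#'
#' Returns the parameter set that [render_event()] turns into a
#' three-channel signal: onset/duration/amplitude of the digastric and
#' sternohyoid EMG bursts, onsets and durations of the three swallowing
#' sound waves, the aspiration desynchronisation jitter scale and the
#' whole-event transit stretch.
#'
#' @param class_label one of [swallow_classes()].
#' @return An object of class `swallow_template`.
#' @export
default_template <- function(class_label) {
  assert_class_label(class_label)
  base <- list(
    class_label = class_label,
    emg1_onset_s = 0.20, emg1_duration_s = 0.60, emg1_amplitude_uV = 40,
    emg2_onset_s = 0.50, emg2_duration_s = 0.55, emg2_amplitude_uV = 32,
    ssw_onsets_s = c(0.35, 0.70, 1.10),
    ssw_durations_s = c(0.10, 0.10, 0.12),
    ssw_amplitude = 1.0,
    desync_jitter_s = 0,
    transit_scale = 1,
    duration_s = 2.0
  )
  tpl <- switch(class_label,
    rest = modifyList(base, list(
      emg1_amplitude_uV = 0, emg2_amplitude_uV = 0, ssw_amplitude = 0)),
    liquid = base,
    soft_food = modifyList(base, list(
      emg1_duration_s = 0.80, emg1_amplitude_uV = 55,
      emg2_duration_s = 0.70, emg2_amplitude_uV = 44,
      ssw_durations_s = c(0.12, 0.12, 0.14), ssw_amplitude = 1.2)),
    dense_food = modifyList(base, list(
      emg1_duration_s = 1.00, emg1_amplitude_uV = 70,
      emg2_duration_s = 0.90, emg2_amplitude_uV = 58,
      ssw_durations_s = c(0.14, 0.14, 0.16), ssw_amplitude = 1.4)),
    silent_aspiration = modifyList(base, list(
      emg2_amplitude_uV = 16,      # weakened infrahyoid response
      desync_jitter_s = 0.5,
      transit_scale = 1.6,
      duration_s = 2.0)),
    cough = modifyList(base, list(
      emg1_onset_s = 0.45, emg1_duration_s = 0.25, emg1_amplitude_uV = 55,
      emg2_onset_s = 0.45, emg2_duration_s = 0.25, emg2_amplitude_uV = 45,
      ssw_onsets_s = c(0.50, 0.50, 0.50), ssw_durations_s = c(0.30, 0, 0),
      ssw_amplitude = 5.0, duration_s = 1.6)),
    chewing = modifyList(base, list(
      emg1_onset_s = 0.25, emg1_duration_s = 0.30, emg1_amplitude_uV = 50,
      emg2_amplitude_uV = 6,       # little infrahyoid involvement
      emg2_onset_s = 0.25, emg2_duration_s = 0.30,
      ssw_amplitude = 0.15, ssw_durations_s = c(0.05, 0.05, 0.05),
      duration_s = 2.6))
  )
  structure(tpl, class = "swallow_template")
}

validate_template <- function(tpl) {
  stopifnot(inherits(tpl, "swallow_template"))
  assert_class_label(tpl$class_label)
  with(tpl, {
    if (any(c(emg1_duration_s, emg2_duration_s) <= 0) && class_label != "rest")
      stop("durations must be strictly positive", call. = FALSE)
    if (any(c(emg1_onset_s, emg2_onset_s, ssw_onsets_s) < 0))
      stop("onsets must be non-negative", call. = FALSE)
    if (class_label %in% .normal_swallow_classes) {
      if (any(diff(ssw_onsets_s) <= 0))
        stop("SSW onsets must be strictly increasing", call. = FALSE)
      if (emg1_onset_s > ssw_onsets_s[1])
        stop("digastric burst must begin at or before SSW1", call. = FALSE)
      if (emg2_onset_s < ssw_onsets_s[1] || emg2_onset_s > ssw_onsets_s[2])
        stop("sternohyoid burst must begin within [SSW1, SSW2]",
             call. = FALSE)
    }
    if (class_label == "silent_aspiration" &&
        (transit_scale <= 1 || desync_jitter_s <= 0))
      stop("silent aspiration requires transit_scale > 1 and jitter > 0",
           call. = FALSE)
  })
  invisible(tpl)
}

## ---- rendering primitives -------------------------------------------------

# raised-cosine envelope on the full sample grid
burst_envelope <- function(n, fs, onset_s, duration_s) {
  env <- numeric(n)
  if (duration_s <= 0) return(env)
  i0 <- floor(onset_s * fs) + 1L
  i1 <- min(n, floor((onset_s + duration_s) * fs))
  if (i1 < i0 || i0 > n) return(env)
  m <- i1 - i0 + 1L
  env[i0:i1] <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
  env
}

# band-limited Gaussian noise, spectral content concentrated in [lo, hi]
bandnoise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  sos <- butter_bandpass_sos(4, lo, hi, fs)
  y <- sos_filtfilt(x, sos, padlen = min(n - 1L, 400L))
  y / max(rms(y), 1e-12)
}

# enveloped oscillatory packet (one swallowing sound wave)
ssw_packet <- function(n, fs, onset_s, duration_s, carrier_hz, amplitude) {
  if (duration_s <= 0 || amplitude == 0) return(numeric(n))
  env <- burst_envelope(n, fs, onset_s, duration_s)
  t <- (0:(n - 1L)) / fs
  phase <- runif(1, 0, 2 * pi)
  amplitude * env * sin(2 * pi * carrier_hz * (t - onset_s) + phase)
}

# default baseline noise levels (channel units): EMG thermal/electrode
# noise in uV RMS, microphone self-noise in arbitrary units RMS
default_noise_spec <- function() {
  list(emg_baseline_uV = 2.0, sound_baseline = 0.05,
       powerline_uV = 6.0, powerline_hz = 60)
}

#' Render one annotated event from a template
#'
#' Synthesises the two EMG channels (amplitude-modulated 20--100 Hz noise
#' bursts) and the acoustic channel (enveloped oscillatory SSW packets;
#' broadband burst for cough; rhythmic low-level clicks for chewing) at the
#' acquisition rate.  Rendering is deterministic in
#' `(template, fs_hz, seed)`.
#'
#' @param template a `swallow_template`.
#' @param fs_hz sampling rate, at least 2000 Hz so the 10--900 Hz acoustic
#'   band is representable.
#' @param seed integer seed for the event's private RNG stream.
#' @param noise_spec baseline-noise configuration, see
#'   `default_noise_spec()`.
#' @return A [multimodal_recording()] containing the single event, with a
#'   single annotation spanning it (none for rest) and the realised
#'   template stored as ground truth.
#' @export
render_event <- function(template, fs_hz = 2000, seed = 0,
                         noise_spec = default_noise_spec()) {
  validate_template(template)
  if (fs_hz < 2000)
    stop("fs_hz must be at least 2000 Hz (10-900 Hz sound band)",
         call. = FALSE)
  with_seed(seed, render_event_impl(template, fs_hz, noise_spec))
}

# uses the ambient RNG stream; callers are responsible for seeding
render_event_impl <- function(tpl, fs_hz, noise_spec) {
  ts <- tpl$transit_scale
  dur <- tpl$duration_s * ts
  n <- round(dur * fs_hz)
  t <- (0:(n - 1L)) / fs_hz

  # realised timing: transit stretch, then aspiration desynchronisation
  ssw_on <- tpl$ssw_onsets_s * ts
  ssw_du <- tpl$ssw_durations_s * ts
  emg1_on <- tpl$emg1_onset_s * ts
  emg2_on <- tpl$emg2_onset_s * ts
  if (tpl$desync_jitter_s > 0) {
    j <- tpl$desync_jitter_s
    ssw_on <- pmax(0, ssw_on + runif(3, -j, j))
    emg2_on <- max(0, emg2_on + runif(1, -j, j))
  }

  emg1 <- noise_spec$emg_baseline_uV * rnorm(n)
  emg2 <- noise_spec$emg_baseline_uV * rnorm(n)
  sound <- noise_spec$sound_baseline * rnorm(n)

  add_emg_burst <- function(x, onset, durn, amp) {
    if (amp <= 0 || durn <= 0) return(x)
    x + amp * burst_envelope(n, fs_hz, onset, durn) * bandnoise(n, fs_hz, 20, 100)
  }

  if (tpl$class_label == "chewing") {
    # rhythmic mastication: >= 3 suprahyoid bursts at ~1.5 Hz with faint
    # occlusion clicks, essentially silent acoustically
    period <- runif(1, 0.55, 0.75)
    onsets <- seq(tpl$emg1_onset_s, dur - tpl$emg1_duration_s - 0.05,
                  by = period)
    for (o in onsets) {
      emg1 <- add_emg_burst(emg1, o, tpl$emg1_duration_s,
                            tpl$emg1_amplitude_uV)
      emg2 <- add_emg_burst(emg2, o + 0.05, tpl$emg2_duration_s,
                            tpl$emg2_amplitude_uV)
      sound <- sound + ssw_packet(n, fs_hz, o + 0.1, tpl$ssw_durations_s[1],
                                  runif(1, 300, 500), tpl$ssw_amplitude)
    }
  } else if (tpl$class_label == "cough") {
    emg1 <- add_emg_burst(emg1, emg1_on, tpl$emg1_duration_s * ts,
                          tpl$emg1_amplitude_uV)
    emg2 <- add_emg_burst(emg2, emg2_on, tpl$emg2_duration_s * ts,
                          tpl$emg2_amplitude_uV)
    # single high-amplitude broadband expulsion
    env <- burst_envelope(n, fs_hz, ssw_on[1], ssw_du[1])
    sound <- sound + tpl$ssw_amplitude * env * bandnoise(n, fs_hz, 50, 900)
  } else {
    emg1 <- add_emg_burst(emg1, emg1_on, tpl$emg1_duration_s * ts,
                          tpl$emg1_amplitude_uV)
    emg2 <- add_emg_burst(emg2, emg2_on, tpl$emg2_duration_s * ts,
                          tpl$emg2_amplitude_uV)
    # SSW1-SSW3 dominant frequencies; kept below the 125 Hz model-rate
    # Nyquist so the acoustic channel stays informative after decimation
    carriers <- c(70, 110, 85)
    for (k in 1:3) {
      sound <- sound + ssw_packet(n, fs_hz, ssw_on[k], ssw_du[k],
                                  carriers[k] * runif(1, 0.9, 1.1),
                                  tpl$ssw_amplitude)
    }
  }

  truth <- tpl
  truth$realized_ssw_onsets_s <- ssw_on
  truth$realized_emg2_onset_s <- emg2_on
  ann <- if (tpl$class_label == "rest") {
    data.frame(start_s = numeric(0), end_s = numeric(0),
               class_label = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(start_s = 0, end_s = n / fs_hz,
               class_label = tpl$class_label, stringsAsFactors = FALSE)
  }
  multimodal_recording(emg1, emg2, sound, fs_hz,
                       participant_id = "synthetic",
                       annotations = ann, truth = list(truth))
}

#' Construct a multimodal recording
#'
#' Container for one participant's synchronized session: two EMG channels
#' (microvolts), one acoustic channel (arbitrary units), the sampling rate,
#' and annotated event intervals.
#'
#' @param emg_ch1,emg_ch2,sound equal-length numeric vectors.
#' @param fs_hz sampling rate, positive.
#' @param participant_id opaque identifier.
#' @param annotations data.frame with columns `start_s`, `end_s`,
#'   `class_label`; distinct events must not overlap and must lie within
#'   the recording.
#' @param truth optional list of realised templates (simulator ground
#'   truth).
#' @return An object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(emg_ch1, emg_ch2, sound, fs_hz,
                                 participant_id = "unknown",
                                 annotations = NULL, truth = NULL) {
  n <- length(emg_ch1)
  if (length(emg_ch2) != n || length(sound) != n)
    stop("all three channels must have equal length", call. = FALSE)
  if (fs_hz <= 0) stop("fs_hz must be positive", call. = FALSE)
  if (is.null(annotations))
    annotations <- data.frame(start_s = numeric(0), end_s = numeric(0),
                              class_label = character(0),
                              stringsAsFactors = FALSE)
  dur <- n / fs_hz
  if (nrow(annotations)) {
    stopifnot(all(annotations$start_s < annotations$end_s))
    if (any(annotations$start_s < -1e-9) ||
        any(annotations$end_s > dur + 1e-6))
      stop("annotations must lie within [0, duration]", call. = FALSE)
    ord <- order(annotations$start_s)
    annotations <- annotations[ord, , drop = FALSE]
    if (nrow(annotations) > 1 &&
        any(annotations$start_s[-1] < annotations$end_s[-nrow(annotations)] - 1e-9))
      stop("annotated events must not overlap", call. = FALSE)
    lapply(annotations$class_label, assert_class_label)
  }
  structure(list(emg_ch1 = emg_ch1, emg_ch2 = emg_ch2, sound = sound,
                 fs_hz = fs_hz, participant_id = participant_id,
                 annotations = annotations, truth = truth),
            class = "multimodal_recording")
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf(
    "<multimodal_recording> participant %s: %.1f s at %g Hz, %d annotated events\n",
    x$participant_id, length(x$emg_ch1) / x$fs_hz, x$fs_hz,
    nrow(x$annotations)))
  invisible(x)
}

recording_duration <- function(rec) length(rec$emg_ch1) / rec$fs_hz

# within-class variability applied to a default template for one event
jitter_template <- function(tpl, amount = 1) {
  if (tpl$class_label == "rest" || amount <= 0) return(tpl)
  scale_amp <- runif(1, 1 - 0.15 * amount, 1 + 0.15 * amount)
  scale_dur <- runif(1, 1 - 0.10 * amount, 1 + 0.10 * amount)
  tpl$emg1_amplitude_uV <- tpl$emg1_amplitude_uV * scale_amp
  tpl$emg2_amplitude_uV <- tpl$emg2_amplitude_uV * runif(1, 1 - 0.15 * amount,
                                                         1 + 0.15 * amount)
  tpl$emg1_duration_s <- tpl$emg1_duration_s * scale_dur
  tpl$emg2_duration_s <- tpl$emg2_duration_s * scale_dur
  tpl$ssw_amplitude <- tpl$ssw_amplitude * runif(1, 0.85, 1.15)
  if (tpl$class_label == "silent_aspiration")
    tpl$transit_scale <- tpl$transit_scale * runif(1, 0.95, 1.1)
  tpl
}

#' Generate annotated synthetic sessions
#'
#' One recording per participant: events drawn from `class_mix`, separated
#' by resting gaps (default 5 s, matching a typical test protocol), with
#' per-participant gain variability, 60 Hz powerline interference on the
#' EMG channels, and white baseline noise everywhere.
#'
#' @param n_participants number of participants (>= 1).
#' @param events_per_participant non-rest events per recording.
#' @param class_mix named numeric vector of sampling proportions over the
#'   six non-rest classes (rest arises from the gaps); proportions must sum
#'   to 1.  Default: uniform over the six.
#' @param noise_spec see `default_noise_spec()`.
#' @param seed integer master seed.
#' @param gap_s resting gap between events, seconds.
#' @param gain_range per-participant multiplicative gain range.
#' @param template_jitter within-class parameter variability (0 disables).
#' @return List of [multimodal_recording()] objects, participant ids
#'   `"P01"`, `"P02"`, ...
#' @export
generate_session <- function(n_participants, events_per_participant,
                             class_mix = NULL,
                             noise_spec = default_noise_spec(),
                             seed = 0, gap_s = 5,
                             gain_range = c(0.7, 1.3),
                             template_jitter = 1) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (events_per_participant < 0)
    stop("events_per_participant must be >= 0", call. = FALSE)
  if (is.null(class_mix)) {
    cls <- setdiff(swallow_classes(), "rest")
    class_mix <- setNames(rep(1 / length(cls), length(cls)), cls)
  }
  if (length(class_mix) == 0) stop("empty class_mix", call. = FALSE)
  if (any(class_mix < 0)) stop("negative class_mix entries", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-6)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  lapply(names(class_mix), assert_class_label)

  with_seed(seed, lapply(seq_len(n_participants), function(p) {
    gain_emg <- runif(1, gain_range[1], gain_range[2])
    gain_snd <- runif(1, gain_range[1], gain_range[2])
    fs <- 2000
    labels <- sample(names(class_mix), events_per_participant,
                     replace = TRUE, prob = class_mix)
    pieces <- list()
    ann <- list()
    cursor <- 0
    append_gap <- function(len_s) {
      ng <- round(len_s * fs)
      list(emg1 = noise_spec$emg_baseline_uV * rnorm(ng),
           emg2 = noise_spec$emg_baseline_uV * rnorm(ng),
           sound = noise_spec$sound_baseline * rnorm(ng))
    }
    pieces[[1]] <- append_gap(gap_s)
    cursor <- gap_s
    truths <- list()
    for (lab in labels) {
      tpl <- jitter_template(default_template(lab), template_jitter)
      ev <- render_event_impl(tpl, fs, noise_spec)
      dn <- length(ev$emg_ch1) / fs
      pieces[[length(pieces) + 1L]] <- list(emg1 = ev$emg_ch1,
                                            emg2 = ev$emg_ch2,
                                            sound = ev$sound)
      ann[[length(ann) + 1L]] <- data.frame(start_s = cursor,
                                            end_s = cursor + dn,
                                            class_label = lab,
                                            stringsAsFactors = FALSE)
      truths <- c(truths, ev$truth)
      cursor <- cursor + dn
      pieces[[length(pieces) + 1L]] <- append_gap(gap_s)
      cursor <- cursor + gap_s
    }
    emg1 <- gain_emg * unlist(lapply(pieces, `[[`, "emg1"))
    emg2 <- gain_emg * unlist(lapply(pieces, `[[`, "emg2"))
    sound <- gain_snd * unlist(lapply(pieces, `[[`, "sound"))
    # additive powerline interference on the EMG channels
    if (noise_spec$powerline_uV > 0) {
      tt <- (seq_along(emg1) - 1L) / fs
      ph <- runif(2, 0, 2 * pi)
      emg1 <- emg1 + noise_spec$powerline_uV *
        sin(2 * pi * noise_spec$powerline_hz * tt + ph[1])
      emg2 <- emg2 + noise_spec$powerline_uV *
        sin(2 * pi * noise_spec$powerline_hz * tt + ph[2])
    }
    anndf <- if (length(ann)) do.call(rbind, ann) else NULL
    multimodal_recording(emg1, emg2, sound, fs,
                         participant_id = sprintf("P%02d", p),
                         annotations = anndf, truth = truths)
  }))
}
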