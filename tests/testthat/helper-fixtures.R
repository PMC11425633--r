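# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# three participants, two events each: enough for a legal 3-way split
tiny_session <- function() {
  fixture("tiny_session", function() generate_session(3, 2, seed = 5))
}

# a hand-built 250 Hz recording: one 2-s liquid event at t = 4 s inside
# 10 s of rest-level noise
toy_recording_250 <- function(event_start = 4, dur = 10, fs = 250,
                              event_class = "liquid") {
  n <- round(dur * fs)
  set.seed(99)
  mk <- function() rnorm(n)
  ann <- data.frame(start_s = event_start, end_s = event_start + 2,
                    class_label = event_class, stringsAsFactors = FALSE)
  e1 <- mk(); e2 <- mk(); sd_ <- mk()
  idx <- (round(event_start * fs) + 1):round((event_start + 2) * fs)
  e1[idx] <- e1[idx] + 8 * sin(2 * pi * 50 * seq_along(idx) / fs)
  multimodal_recording(e1, e2, sd_, fs, participant_id = "TOY",
                       annotations = ann)
}

# measured single-frequency gain of a filter chain, via RMS on the
# central half of a long sinusoid (independent of the filter code path)
tone_gain <- function(f_hz, fs_hz, filtfun, dur_s = 4) {
  n <- round(fs_hz * dur_s)
  t <- (0:(n - 1)) / fs_hz
  x <- sin(2 * pi * f_hz * t)
  y <- filtfun(x)
  sel <- (n %/% 4):(3 * n %/% 4)
  sqrt(mean(y[sel]^2) / mean(x[sel]^2))
}

rms <- function(x) sqrt(mean(x^2))

# amplitude of the dominant FFT component (oracle for resampling tests)
fft_peak_amp <- function(x) {
  max(Mod(stats::fft(x))[-1]) * 2 / length(x)
}

# analytic parameter-count oracle: hand-derived layer-by-layer sum over the
# published architecture, independent of the builder's bookkeeping
analytic_param_count <- function(input_channels = 3) {
  firsts <- list(c(80, 5), c(48, 3), c(112, 3))
  cin <- input_channels
  total <- 0
  for (f1 in firsts) {
    for (lay in list(f1, c(16, 4))) {
      f <- lay[1]; k <- lay[2]
      total <- total + f * (cin * k) + f +   # conv kernel + bias
        2 * f +                              # batch-norm gamma/beta
        f                                    # PReLU slopes
      cin <- f
    }
  }
  u <- 10
  total <- total + 2 * (cin * 4 * u + u * 4 * u + 4 * u)  # BiLSTM
  din <- 2 * u
  for (d in c(140, 512, 256)) {
    total <- total + din * d + d + d         # dense + bias + PReLU
    din <- d
  }
  total + din * 7 + 7                        # softmax output layer
}
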