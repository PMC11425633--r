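#' Filtering specification for the preprocessing chain
#'
#' Bundles the passbands and sampling rates used to condition raw
#' recordings before epoching: a 20--100 Hz EMG bandpass with a 59--61 Hz
#' powerline notch, a 10--900 Hz acoustic bandpass applied at the 2 kHz
#' acquisition rate, and decimation to the 250 Hz rate the classifier
#' consumes.
#'
#' @param emg_band_hz length-2 numeric, EMG passband edges in Hz.
#' @param notch_band_hz length-2 numeric, notch stopband edges in Hz.
#' @param sound_band_hz length-2 numeric, acoustic passband edges in Hz.
#' @param model_fs_hz sampling rate of the classifier input.
#' @param acquisition_fs_hz sampling rate of the raw recording.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(emg_band_hz = c(20, 100),
                        notch_band_hz = c(59, 61),
                        sound_band_hz = c(10, 900),
                        model_fs_hz = 250,
                        acquisition_fs_hz = 2000) {
  for (b in list(emg_band_hz, notch_band_hz, sound_band_hz)) {
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0) || b[1] >= b[2])
      stop("band edges must be positive with lower < upper", call. = FALSE)
  }
  if (model_fs_hz <= 0 || acquisition_fs_hz <= 0 ||
      model_fs_hz >= acquisition_fs_hz)
    stop("need 0 < model_fs_hz < acquisition_fs_hz", call. = FALSE)
  structure(list(emg_band_hz = as.numeric(emg_band_hz),
                 notch_band_hz = as.numeric(notch_band_hz),
                 sound_band_hz = as.numeric(sound_band_hz),
                 model_fs_hz = as.numeric(model_fs_hz),
                 acquisition_fs_hz = as.numeric(acquisition_fs_hz)),
            class = "filter_spec")
}

## ---- IIR design -----------------------------------------------------------
## Butterworth bandpass designed as second-order sections (analog prototype
## -> lowpass-to-bandpass transform -> bilinear).  SOS form keeps the wide
## 10-900 Hz band numerically sane where a flat transfer function would not.

butter_bandpass_sos <- function(order, lo_hz, hi_hz, fs_hz) {
  stopifnot(order >= 1, lo_hz > 0, hi_hz > lo_hz, hi_hz < fs_hz / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # Re < 0
  # prewarped analog edges
  w1 <- 2 * fs_hz * tan(pi * lo_hz / fs_hz)
  w2 <- 2 * fs_hz * tan(pi * hi_hz / fs_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass prototype pole -> two bandpass poles
  s_poles <- unlist(lapply(proto, function(p) {
    d <- sqrt((bw * p)^2 - 4 * w0^2 + 0i)
    c((bw * p + d) / 2, (bw * p - d) / 2)
  }))
  z_poles <- (2 * fs_hz + s_poles) / (2 * fs_hz - s_poles)
  # group into conjugate pairs
  up <- z_poles[Im(z_poles) >= 0]
  up <- up[order(Re(up), Im(up))]
  sos <- lapply(up, function(p) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    list(b = c(1, 0, -1), a = a)     # zeros at z = +1 and z = -1
  })
  # unit gain at the geometric-centre frequency
  wc <- 2 * pi * sqrt(lo_hz * hi_hz) / fs_hz
  g <- prod(vapply(sos, function(s) {
    z <- exp(-1i * wc * (0:2))
    Mod(sum(s$b * z) / sum(s$a * z))
  }, numeric(1)))
  sos[[1]]$b <- sos[[1]]$b / g
  sos
}

# second-order IIR notch (constrained biquad), bandwidth set by the
# stopband edges; exact null at the centre frequency
notch_sos <- function(lo_hz, hi_hz, fs_hz) {
  f0 <- sqrt(lo_hz * hi_hz)
  q <- f0 / (hi_hz - lo_hz)
  w0 <- 2 * pi * f0 / fs_hz
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(list(b = c(1, -2 * cos(w0), 1) / a0,
            a = c(1, -2 * cos(w0) / a0, (1 - alpha) / a0)))
}

# single-pass direct-form filtering; MA part via one-sided convolution,
# AR part via the C recursive filter in stats
iir_filter <- function(x, b, a) {
  n <- length(x)
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(n + nb - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# zero-phase application of a cascade of biquads: odd-reflection padding,
# forward pass, time reversal, second pass (squares the magnitude response,
# cancels the phase)
sos_filtfilt <- function(x, sos, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * 200L)
  padlen <- max(0L, min(n - 1L, as.integer(padlen)))
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    y <- c(pre, x, post)
  } else y <- x
  for (s in sos) y <- iir_filter(y, s$b, s$a)
  y <- rev(y)
  for (s in sos) y <- iir_filter(y, s$b, s$a)
  y <- rev(y)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)] else y
  y
}

#' Condition an EMG channel
#'
#' Applies the 20--100 Hz Butterworth bandpass followed by the 59--61 Hz
#' powerline notch, both forward-backward (zero phase) so burst timing is
#' preserved.  Output length equals input length.
#'
#' @param series numeric vector of EMG samples (microvolts).
#' @param fs_hz sampling rate in Hz; must exceed 200 so the passband is
#'   representable.
#' @param spec a [filter_spec()].
#' @return Filtered numeric vector, same length as `series`.
#' @export
filter_emg <- function(series, fs_hz, spec = filter_spec()) {
  if (fs_hz <= 200)
    stop("fs_hz must exceed 200 Hz for the 20-100 Hz EMG band", call. = FALSE)
  minlen <- 24L
  if (length(series) < minlen)
    stop("series shorter than the filter warm-up (", minlen, " samples)",
         call. = FALSE)
  bp <- butter_bandpass_sos(4, spec$emg_band_hz[1], spec$emg_band_hz[2], fs_hz)
  y <- sos_filtfilt(series, bp,
                    padlen = min(length(series) - 1L,
                                 ceiling(3 * fs_hz / spec$emg_band_hz[1])))
  if (spec$notch_band_hz[2] < fs_hz / 2) {
    nt <- notch_sos(spec$notch_band_hz[1], spec$notch_band_hz[2], fs_hz)
    y <- sos_filtfilt(y, nt,
                      padlen = min(length(series) - 1L, as.integer(fs_hz)))
  }
  y
}

#' Condition the acoustic channel
#'
#' Optional magnitude spectral subtraction (noise profile estimated from a
#' caller-supplied rest segment) followed by a 10--900 Hz zero-phase
#' Butterworth bandpass at the acquisition rate.
#'
#' @param series numeric vector of microphone samples.
#' @param fs_hz sampling rate; at least 1800 Hz so the 900 Hz edge exists.
#' @param spec a [filter_spec()].
#' @param rest_ref optional numeric vector of resting-baseline samples at the
#'   same rate, used as the noise profile; `NULL` skips noise reduction.
#' @param oversubtraction spectral-subtraction factor (1 = plain subtraction).
#' @return Filtered numeric vector, same length as `series`.
#' @export
filter_sound <- function(series, fs_hz, spec = filter_spec(),
                         rest_ref = NULL, oversubtraction = 1.0) {
  if (fs_hz < 1800)
    stop("fs_hz must be at least 1800 Hz (900 Hz band edge unrepresentable)",
         call. = FALSE)
  if (length(series) < 24L)
    stop("series shorter than the filter warm-up", call. = FALSE)
  y <- series
  if (!is.null(rest_ref) && length(rest_ref) >= 64L) {
    y <- spectral_subtract(y, rest_ref, fs_hz, oversubtraction)
  }
  hi <- min(spec$sound_band_hz[2], 0.45 * fs_hz)
  bp <- butter_bandpass_sos(4, spec$sound_band_hz[1], hi, fs_hz)
  sos_filtfilt(y, bp,
               padlen = min(length(series) - 1L,
                            ceiling(3 * fs_hz / spec$sound_band_hz[1])))
}

## ---- STFT / spectral subtraction ------------------------------------------

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

stft_frames <- function(x, nfft, hop) {
  starts <- seq(1L, max(1L, length(x) - nfft + 1L), by = hop)
  w <- hann_window(nfft)
  sapply(starts, function(s) fft(x[s:(s + nfft - 1)] * w))
}

# magnitude spectral subtraction with overlap-add resynthesis (Hann, 50%
# overlap satisfies constant-overlap-add up to a known scale)
spectral_subtract <- function(x, noise_ref, fs_hz, oversubtraction = 1.0,
                              floor_frac = 0.05) {
  nfft <- 2^max(6L, floor(log2(0.064 * fs_hz)))
  hop <- nfft %/% 2L
  n <- length(x)
  xp <- c(x, rep(0, nfft))
  S <- stft_frames(xp, nfft, hop)
  if (is.null(dim(S))) S <- matrix(S, ncol = 1)
  noise_mag <- if (length(noise_ref) >= nfft) {
    N <- stft_frames(noise_ref, nfft, hop)
    if (is.null(dim(N))) N <- matrix(N, ncol = 1)
    rowMeans(Mod(N))
  } else {
    Mod(fft(c(noise_ref * hann_window(length(noise_ref)),
              rep(0, nfft - length(noise_ref)))))
  }
  mag <- Mod(S)
  mag2 <- pmax(mag - oversubtraction * noise_mag, floor_frac * mag)
  S2 <- S * (mag2 / pmax(mag, .Machine$double.eps))
  # overlap-add
  w <- hann_window(nfft)
  y <- numeric(ncol(S2) * hop + nfft)
  wsum <- numeric(length(y))
  for (j in seq_len(ncol(S2))) {
    seg <- Re(fft(S2[, j], inverse = TRUE)) / nfft
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + nfft)
    y[idx] <- y[idx] + seg * w
    wsum[idx] <- wsum[idx] + w^2
  }
  y <- y / pmax(wsum, 1e-8)
  y[seq_len(n)]
}

#' Fourier resampling
#'
#' Rate conversion in the frequency domain: the spectrum is truncated (or
#' zero-padded) to the target rate, which gives inherently brick-wall
#' anti-aliasing and exactly unity DC gain.
#'
#' @param series numeric vector.
#' @param fs_in input sampling rate in Hz.
#' @param fs_out output sampling rate in Hz; must satisfy
#'   `0 < fs_out <= fs_in`.
#' @return Numeric vector of length `round(length(series) * fs_out / fs_in)`.
#' @export
resample_series <- function(series, fs_in, fs_out = 250) {
  if (fs_out <= 0 || fs_out > fs_in)
    stop("need 0 < fs_out <= fs_in", call. = FALSE)
  n0 <- length(series)
  m0 <- round(n0 * fs_out / fs_in)
  if (m0 == n0) return(series)
  # pad (signal reflection) to a 2-3-5-smooth length divisible by the
  # reduced rate denominator: keeps the FFT O(n log n) for any input
  # length and the output length integral
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  den <- round(fs_in / g(round(fs_in), round(fs_out)))
  N <- den * stats::nextn(ceiling(n0 / den), c(2, 3, 5))
  series <- if (N > n0) {
    refl <- rev(series)[seq_len(min(N - n0, n0))]
    c(series, refl, rep(series[n0], max(0, N - n0 - length(refl))))
  } else series
  n <- N
  m <- round(N * fs_out / fs_in)
  X <- fft(series)
  Y <- complex(m)
  nh <- min(n, m)
  half <- nh %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half > 0) Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  if (nh %% 2L == 0L && half > 0) {
    # split the shared Nyquist bin symmetrically
    if (m < n) {
      Y[half + 1L] <- (X[half + 1L] + X[n - half + 1L]) / 2
    } else {
      Y[half + 1L] <- X[half + 1L] / 2
      Y[m - half + 1L] <- X[half + 1L] / 2
    }
  }
  Re(fft(Y, inverse = TRUE))[seq_len(m0)] / n
}

#' Short-time Fourier spectrogram
#'
#' Hann-windowed STFT magnitude, for reports and visual inspection of
#' swallowing sound waves (not a model input).
#'
#' @param series numeric vector.
#' @param fs_hz sampling rate.
#' @param window_s analysis window length in seconds (at least 8 samples).
#' @param hop_s hop between adjacent frames in seconds; at most `window_s`.
#' @return A list of class `spectrogram` with `magnitude`
#'   (frequency x time), `freq_hz`, and `time_s` (frame centres).
#' @export
stft_spectrogram <- function(series, fs_hz, window_s = 0.128,
                             hop_s = window_s / 2) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  nfft <- round(window_s * fs_hz)
  if (nfft < 8L) stop("window shorter than 8 samples", call. = FALSE)
  if (hop_s > window_s) stop("hop_s must not exceed window_s", call. = FALSE)
  hop <- max(1L, round(hop_s * fs_hz))
  xp <- if (length(series) < nfft) c(series, rep(0, nfft - length(series)))
        else series
  S <- stft_frames(xp, nfft, hop)
  if (is.null(dim(S))) S <- matrix(S, ncol = 1)
  nf <- nfft %/% 2L + 1L
  starts <- seq(1L, max(1L, length(xp) - nfft + 1L), by = hop)
  structure(list(magnitude = Mod(S[1:nf, , drop = FALSE]),
                 freq_hz = (0:(nf - 1L)) * fs_hz / nfft,
                 time_s = (starts - 1L + nfft / 2) / fs_hz),
            class = "spectrogram")
}

#' Signal-to-noise ratio in decibels
#'
#' `SNR_dB = 20 log10(A_signal / A_noise)` with amplitude measured as RMS
#' by default (a peak-amplitude option is provided); the resting inactivity
#' period before a swallow is the conventional noise segment.
#'
#' @param signal_segment,noise_segment non-empty numeric vectors.
#' @param method amplitude definition, `"rms"` (default) or `"peak"`.
#' @return An object of class `snr_result` with fields `a_signal`,
#'   `a_noise`, `snr_db`.
#' @export
snr_db <- function(signal_segment, noise_segment,
                   method = c("rms", "peak")) {
  method <- match.arg(method)
  if (length(signal_segment) == 0L || length(noise_segment) == 0L)
    stop("segments must be non-empty", call. = FALSE)
  amp <- function(x) if (method == "rms") rms(x) else max(abs(x))
  a_n <- amp(noise_segment)
  if (a_n == 0)
    stop("noise segment has zero amplitude; SNR undefined", call. = FALSE)
  a_s <- amp(signal_segment)
  structure(list(a_signal = a_s, a_noise = a_n,
                 snr_db = 20 * log10(a_s / a_n)),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR %.2f dB (A_signal %.4g / A_noise %.4g)\n",
              x$snr_db, x$a_signal, x$a_noise))
  invisible(x)
}
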