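---
title: "Methods: simulated swallowing signals and CNN-BiLSTM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated swallowing signals and CNN-BiLSTM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deglutio)
```

## The problem

Dysphagia — impaired swallowing, common after stroke — is screened by
videofluoroscopy, which is expensive and radiological. A wearable
alternative records two surface-EMG channels (digastric muscle under the
chin, sternohyoid muscle on the neck) together with a contact microphone
over the thyroid cartilage, and classifies short signal windows into seven
states: rest, liquid swallow, soft-food swallow, dense-food swallow,
silent aspiration, cough, and chewing. Silent aspiration — a bolus
entering the airway without any protective cough — is the clinically
critical and hardest class.

`deglutio` implements the full offline chain for this task: a
physiology-grounded signal simulator, the preprocessing front-end, epoch
construction with subject-wise splitting, a from-scratch CNN-BiLSTM
classifier, and the evaluation/report surface. Because no public
recordings exist for this device, the simulator is the package's only
required data source, and every claim a green test makes should be read
against what the simulator does and does not emulate.

## The generative model

A normal pharyngeal swallow is a tightly choreographed sequence. The
simulator reproduces its observable signature:

1. the digastric burst begins first, elevating the hyolaryngeal complex;
2. the first swallowing sound wave (SSW1) marks bolus propulsion and
   airway closure; the digastric burst always begins at or before SSW1;
3. the sternohyoid burst begins between SSW1 and SSW2 as the infrahyoid
   muscles pull the hyoid back down; SSW2 marks pharyngoesophageal
   closure;
4. SSW3 marks laryngeal return and esophageal clearance.

EMG bursts are rendered as raised-cosine-enveloped Gaussian noise
band-limited to 20–100 Hz; SSWs as enveloped sinusoidal packets. Bolus
consistency scales burst duration and amplitude monotonically (liquid <
soft food < dense food), mirroring the heavier oropharyngeal work of
thicker boluses.

Silent aspiration is rendered as the three qualitative deviations a
fluoroscopically confirmed aspiration shows on this sensor set: (a) the
whole event is stretched (`transit_scale = 1.6`, longer bolus transit),
(b) SSW and sternohyoid onsets receive uniform timing jitter
(`desync_jitter_s = 0.5`), and (c) the sternohyoid burst is weakened
(half amplitude — the failed counter-movement). With these defaults the
SSW order or the EMG/SSW phase relation is violated in roughly two thirds
of aspiration renders while holding in 100% of normal renders; this
separation, not any single feature, is what makes the class learnable.

Cough is a single high-amplitude broadband acoustic burst with brief
co-activation of both muscles; chewing is ≥3 rhythmic digastric bursts at
~1.5 Hz with almost no acoustic energy at the model rate. Sessions
concatenate events with 5-s resting gaps (the standard inter-swallow
interval of clinical test protocols), add 60 Hz powerline interference to
the EMG channels plus white baseline noise, and draw per-participant
gains from ±30% to emulate electrode placement and anatomy differences.

**Chosen, not measured.** All quantitative simulator defaults (amplitudes,
durations, carrier frequencies, jitter scales) are package choices: the
physiology they encode is qualitative. Two are worth flagging. First, SSW
carriers are set to 70/110/85 Hz, lower than typical cervical-auscultation
spectra, so that the acoustic channel keeps its information after
decimation to the 250 Hz model rate (see below). Second, within-class
variability (±15% amplitude, ±10% duration) plus the participant gains is
the only "biological" variance; real patient data are far messier. A green
surrogate test therefore establishes that the pipeline and model are
correct and can learn this class structure — not that the published
patient-data accuracy is reproduced.

## Preprocessing

* EMG: 4th-order Butterworth bandpass 20–100 Hz plus a 59–61 Hz notch,
  both applied forward-backward. Zero-phase application preserves burst
  timing, which matters because the classes differ in timing; the
  magnitude response is squared, so single-pass −3 dB edges become −6 dB.
* Sound: optional magnitude spectral subtraction (noise profile from a
  caller-supplied resting segment; the pipeline uses the leading rest
  gap), then a 10–900 Hz Butterworth bandpass at the 2 kHz acquisition
  rate. Which noise-reduction algorithm the original device used is
  unstated; spectral subtraction is the standard choice and can be
  disabled.
* Resampling to 250 Hz: Fourier-domain rate conversion (brick-wall
  anti-aliasing, exact DC gain). The input is reflection-padded to a
  2-3-5-smooth length so the FFT never degenerates on awkward lengths.
  A 10–900 Hz acoustic band cannot survive a 250 Hz representation
  (Nyquist 125 Hz); decimation-after-filtering is this package's declared
  resolution of that tension, and is why the simulator keeps its acoustic
  energy low.

Filter design (analog Butterworth prototype → lowpass-to-bandpass
transform → bilinear transform, realised as second-order sections for
numerical stability on the very wide sound band) was validated against an
independent reference implementation during development; the tests pin
the response contracts (≥30 dB at 60 and 1200 Hz, ±3 dB at 50 Hz) via
measured tone gains.

## Epochs, augmentation, splitting

Windows are 2 s at 250 Hz (3×500), min-max normalised to [0, 1] per
channel. The published description of the scaler ("Standard Scaler" with
values "between 0 and 1") is self-contradictory; min-max is adopted and a
z-score variant kept behind an internal flag. A constant channel maps to
0.5. Events are tiled with non-overlapping windows anchored at event
start; unannotated stretches yield rest epochs.

Augmentation shifts windows by +k·0.2 s and re-labels each shifted window
by the class owning the majority (≥50%, ties toward non-rest) of it — the
automated stand-in for the manual re-labelling used with the original
data. Shifts past the recording end are skipped and tallied.

Splitting is by whole participants (60:20:20 target on epoch counts):
greedy size-descending assignment with seeded tie-breaking, then local
improvement by single-participant moves and pairwise swaps. The swap step
is required for configurations that admit an exact split (e.g. 950 epochs
over twenty 47/48-epoch participants → exactly 570/190/190). Participant
disjointness is asserted on every split, augmented epochs included.

## The classifier

Three convolutional blocks — first layers (80 filters, kernel 5),
(48, 3), (112, 3); second layer (16, 4) in every block; each convolution
followed by batch normalisation and PReLU, each block closed by
max-pooling of 2 (500 → 250 → 125 → 62 time steps, floor rule) — then a
bidirectional LSTM with 10 tanh units (final states of both directions
concatenated), dense layers 140/512/256 with PReLU and 0.2 dropout after
the 512 layer, and a 7-way softmax. Adam, learning rate 0.001,
categorical cross-entropy, minibatches of 32, checkpoint on best
validation accuracy.

No deep-learning framework exists in this R stack, so forward and
backward passes are written out by hand (conv1d via im2col/GEMM in
RcppArmadillo; everything else vectorised R) and verified against central
finite differences (worst relative error ~5e-7 across every layer type; a
reduced gradient check runs in the test suite).

Choices the published description leaves open, fixed here: max-pool size
2; "same" convolution padding (left pad `floor((k-1)/2)`); batch norm
between convolution and activation; PReLU slopes per channel, initialised
at 0.25; batch-norm inference statistics tracked with momentum 0.9 — at
0.99 (the common framework default) the running statistics were still
dominated by their initialisation after several epochs at this dataset
scale, making inference disagree wildly with training; channel order
(emg1, emg2, sound); sound enters as a raw 250 Hz waveform channel.
Argmax ties break toward the lowest class index.

Session classification slides the 2-s window at 0.2 s hop (a 10-s
recording yields 41 windows), merges identical consecutive labels, and
absorbs events shorter than 0.4 s into their longer neighbour.

## Evaluation and QC

The confusion matrix is 7×7 (rows true, columns predicted, fixed class
order); accuracy is trace/total; per-class sensitivity and specificity
are one-vs-rest (the only reading under which a single specificity per
class is well defined). Undefined denominators raise errors rather than
returning 0.

Electrode-placement QC follows the pre-test rule: SNR of the first
annotated swallow against the 2 s of inactivity preceding it, with
`SNR_dB = 20 log10(A_signal/A_noise)`, amplitude as RMS (a peak option
exists; "amplitude" is not further specified in the source protocol), and
a pass verdict strictly above 6 dB.

## Numerical and degenerate-input conventions

* Filters reject sampling rates that cannot represent their bands
  (EMG > 200 Hz, sound ≥ 1800 Hz) and series shorter than the warm-up.
* `snr_db` rejects an all-zero noise segment (undefined ratio).
* Segmentation rejects recordings shorter than one window; a sub-2-s
  event still yields one window that runs into the following rest.
* All randomness (simulator, initialisation, shuffling, dropout) flows
  through per-call seeds via a private RNG stream that restores the
  caller's RNG state; identical seeds give bit-identical simulations and
  epoch-1 training losses reproducible to 1e-6 on one platform.

## Scale of the shipped checks, and limitations

The end-to-end surrogate check trains on 20 simulated participants × 10
events with one augmentation shift (~1300 epochs) for 20 Adam epochs —
about ten minutes on one CPU — and requires ≥85% held-out-participant
accuracy and ≥0.7 silent-aspiration sensitivity. The first full run of
this configuration measured 95.7% accuracy and 0.875 aspiration
sensitivity. These thresholds are a synthetic analogue of, not a
reproduction of, the published patient-data performance (89.47% overall,
aspiration 0.79/0.99), which was measured against videofluoroscopic
labels on data that were never released.

Known limitations: no respiratory/cardiac artifact or motion-noise
modelling; no absolute µV/Pa calibration; rest dominates session time (as
it does clinically), so overall accuracy is an optimistic summary —
per-class sensitivities are the informative numbers; hyperparameter
search is out of scope (the published winning values are taken as fixed).

One artifact deserves emphasis. Session-level timelines over-flag silent
aspiration at event boundaries: a sliding window that holds only the
first fragment of an incoming swallow contains a partial, apparently
desynchronised pattern, and such lead-in windows never occur in the
training set (training windows are anchored at event starts and shifted
only in the positive direction, as published). The per-epoch metrics are
unaffected — the surrogate criterion is evaluated on properly anchored
epochs — but timeline consumers should treat clusters of sub-second
aspiration alerts adjacent to a confidently labelled swallow as boundary
echoes. For a screening instrument this errs on the sensitive side; a
production system would add negative-shift augmentation or
majority-vote pooling over overlapping windows, both deliberately out of
scope here because the published pipeline specifies positive shifts and
per-window argmax.
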