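---
title: "Sonified ECG: FM multiplexing of eight leads and CNN-based demodulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sonified ECG: FM multiplexing and CNN demodulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A resting 12-lead ECG is the clinical standard for cardiac diagnosis, but
transmitting it from a patient-worn device usually requires a paired radio
link. An alternative is to *sonify* the ECG: encode all leads into a single
audible waveform that can travel over any voice channel — a phone call held
near the device — and decode it server-side back into diagnostic-quality
signals. `ecgsonify` implements both directions of that chain and the
metrics used to judge whether the reconstruction is diagnostically faithful.

Only 8 of the 12 standard leads are independent: I, II and V1–V6 determine
the rest through the Einthoven/Goldberger identities (III = II − I,
aVR = −(I + II)/2, aVL = I − II/2, aVF = II − I/2), which
`reduce_to_8()` / `derive_12()` implement exactly.

## Forward transform: FM multiplexing

Each lead $L$ modulates its own carrier. With amplitude $a_L(t)$ in mV,
clipped to $\pm A_R$:

$$ f_L(t) = F_C^L + F_D \, \frac{a_L(t)}{A_R}, \qquad
   s_L(t) = A_C \cos\!\Big(2\pi \int_0^t f_L(\tau)\, d\tau\Big), \qquad
   \text{audio}(t) = \sum_{L=1}^{8} s_L(t). $$

Defaults (all of them design constants of the method, exposed in
`fm_config()`):

| parameter | value | meaning |
|---|---|---|
| $F_C^L$ | 450, 750, …, 2550 Hz | per-lead carriers, 300 Hz apart, inside the 300–3000 Hz band a phone microphone passes |
| $F_D$ | 125 Hz | deviation at full scale; modulation index $F_D/A_R = 50$ Hz/mV |
| $A_R$ | 2.5 mV | supported amplitude range; inputs are hard-clipped |
| $F_S$ | 11 000 Hz | audio rate (11 000 exactly; configurable to 11 025) |
| $A_C$ | 1/8 | carrier amplitude, so the 8-band sum stays within ±1 for 16-bit WAV |

At full modulation adjacent bands are separated by a 50 Hz guard gap
(300 − 2·125). Discretely, the phase is an unwrapped running sum
$\phi[n] = 2\pi \sum_{k \le n} f_L[k]/F_S$ in double precision; quantization
to 16 bits happens only at WAV write. Leads are Fourier-resampled to $F_S$
before modulation (the FFT zero-padding method; it preserves band-limited
tones exactly) and re-clipped afterwards so interpolation overshoot cannot
push a band into its neighbour's slot.

## Inverse transforms

Two independent inverses are provided, by design:

**DSP oracle** (`dsp_demodulate()`), a training-free reference
demodulator: per band, a zero-phase 6th-order Butterworth band-pass
(half-width 150 Hz = deviation + half guard; order chosen so a full-scale
tone in an adjacent band leaves under 1% RMS residual), the analytic
signal, the instantaneous frequency from the central difference of the
unwrapped phase smoothed by a sub-millisecond moving average, inversion of
the modulation law
$a = (f - F_C)\,A_R/F_D$, a 100 Hz low-pass, and Fourier resampling to
250 Hz. Its first and last 100 ms carry filter transients and are excluded
from error metrics (`edge_trim_ms` attribute). The oracle exists so the
learned demodulator can be validated against something that does not share
its failure modes.

**CNN demodulator** (`build_model()`, `train_cnn()`, `predict_ecg()`): a
four-layer 1D convolutional network mapping 10 s of audio at 11 kHz
(110 000 × 1) to 10 s of 8-lead ECG at 250 Hz (2500 × 8):

conv 220@24 → maxpool 11 → conv 20@24 → maxpool 2 → conv 10@24 →
maxpool 2 → conv 5@8,

all activations linear, dropout 0.1 after every layer during training,
23 600 trainable parameters (5 304 + 11 544 + 5 784 + 968). Linear
activations are appropriate for a regression that must reproduce positive
and negative deflections symmetrically; the max pooling is the essential
nonlinearity — it acts as an envelope detector over non-overlapping
windows, which is exactly what turns the output of a frequency-selective
(discriminator-slope) filter into an amplitude estimate. The published
pool chain (110 000→10 000, →500, →250) is arithmetically inconsistent
with the printed output size (2500, 8); the windows (11, 2, 2) forced by
the input/output sizes give 110 000→10 000→5 000→2 500 and are what this
package implements. Because pooling windows are non-overlapping, the
downsampling factor is exactly 44 = 11·2·2.

The network is implemented in single precision (the customary arithmetic
for this kind of model) with im2col + BLAS matrix products; forward and
backward passes, Adam, dropout and early stopping are all in compiled code,
seeded from R so fixed-seed runs reproduce bit-identically on one machine.
With zero biases at initialization the untrained network is positively
homogeneous (`predict(a·x) = a·predict(x)` for `a > 0`) — not fully linear,
because of the max pooling.

Training is unsupervised regression: minimize the error between the
network's output and the original (monitoring-filtered) ECG. We optimize
MSE and report RMSE; the full-scale protocol is Adam at learning rate
0.001, batch 256, a 70/30 record-level split (segments of one record never
straddle the split), at most 1000 epochs, early stopping after 150
patience epochs, and restoration of the minimum-validation-loss weights.
Checkpoints are self-describing JSON (architecture + full-precision
weights), so `load_cnn()` needs no side information.

Where the published description leaves choices open, this package decides:
dropout is placed after each pooling stage (equivalent regularization,
cheaper); `same` padding pads evenly with the extra sample on the right;
batch-wise MSE is optimized while RMSE is reported.

## Preprocessing

`monitoring_filter()` simulates an ambulatory front end: first-order
Butterworth high-pass at 0.64 Hz and low-pass at 30 Hz, applied causally
(single-pass) per lead, as the hardware it models would; zero-phase
filtering is available behind a flag. Filtering happens at the source rate;
the 250 Hz training target is produced afterwards by Fourier resampling.
`clip_amplitude()` is the ±2.5 mV limiter at the transformer input.

## The synthetic generator

`generate_record()` replaces a clinical archive for all desk-scale work.
Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with typical
amplitudes (0.12, −0.10, 1.10, −0.20, 0.30 mV), widths (25, 10, 12, 12,
60 ms as standard deviations) and offsets relative to the R peak; a
per-lead projection vector (0.6, 1.0, −0.5, 0.7, 1.1, 1.3, 1.1, 0.9 for
I, II, V1–V6, sign flip on V1) spreads the common shape across leads.
Rhythm modes: `sinus` (uniform RR jitter, default 3%), `irregular_rr`
(P waves suppressed, RR jitter ≥ 20% — an atrial-fibrillation-like
surrogate), and `ectopic` (wide-QRS beats without P at a configurable
rate). White noise (default 20 µV RMS) and sinusoidal baseline wander at
0.2–0.4 Hz (default 50 µV) model the dominant artifact classes; everything
is clipped to ±2.5 mV. These defaults were chosen once as representative
resting-ECG values and are the package's study conditions.

The generator emits fiducial ground truth (P-peak, Q-point, R-peak,
S-peak, J-point, T-peak times) with every record, which is what lets the
evaluation stack be tested against known truth rather than against itself.

What the generator does *not* emulate: real torso lead fields, pathologic
morphologies beyond wide-QRS ectopy, electrode motion artifacts, powerline
interference, or inter-patient variability of a clinical archive. Passing
tests on synthetic data therefore demonstrate that the transformation
chain is a faithful codec under controlled morphology — they do not, by
themselves, establish clinical-grade performance on hospital data.

## Evaluation

* `rmse()` and `prd()` — amplitude errors; PRD is the RMSE normalized by
  the RMS of the original, in percent.
* `detect_fiducials()` — a deterministic squared-derivative QRS detector
  (40 ms smoothing, adaptive threshold at 15% of the peak energy, 250 ms
  refractory period) with constrained extremum searches for the other
  waves, polarity-aware. The published evaluation used an external
  toolbox's detector; since the diagnostic-error metrics only require the
  *same* detector applied to both signals, a documented built-in detector
  plus a plug-in interface (`qrs_detector` argument) replaces it.
* `match_fiducials()` — one-to-one greedy matching by ascending |Δt|
  within ±50 ms (ties toward the earlier reference point); MAD over
  matched pairs, Se = TP/(TP+FN), PPV = TP/(TP+FP). MAD statistics are
  kept per wave per lead.
* `normalized_psd_error()` — Welch PSDs (periodic Hann, mean detrend, 50%
  overlap, 5 s segments at 250 Hz → 0.2 Hz bins, 0–100 Hz), compared as
  |PSDₓ − PSDᵧ| divided by the *global* maximum of both PSDs, ×100; the
  scalar normalizer keeps every bin in [0, 100]%.
* `spectrogram()` — STFT with a 1 s window and half-window overlap (19
  frames over 10 s), the view used to confirm the eight carrier ridges.

## Desk-scale training protocol

The tests train the full architecture on synthetic data at a scale a
single CPU handles in minutes. Because the network is fully convolutional
and the audio-to-ECG mapping is local (receptive field ≈ 75 ms), training
uses 500 one-second pairs cut from fifty 10 s records (mixed rhythm modes
and heart rates 55–95 bpm). The batch size is reduced to 8 so that the
number of optimizer steps per epoch (≈ 44) stays near the full-scale
protocol's (7 000 pairs / batch 256 ≈ 27); the learning rate stays at
0.001 and epochs are reduced to 80. Validation-best weights are kept.
Held-out performance is measured as per-lead PRD on 200 fresh 10 s
records. The overfit sanity check memorizes 16 two-second pairs for 200
epochs at batch size 1. These sizes are the package's own desk-scale
choices; the full-scale protocol remains available through
`train_config()` defaults.

## Numerical choices and degenerate inputs

Fourier resampling follows the classical FFT method, including the
Nyquist-bin split (upsampling) and fold (downsampling), and matches the
common scientific-Python implementation to machine precision. PRD is
undefined (an error) for an all-zero reference; Se/PPV are reported as
`NA` when their denominators are zero; flat records yield empty fiducial
sets; records shorter than 2 s (detection), one Welch segment (PSD), or
one STFT window are rejected with named errors. WAV I/O is 16-bit PCM
mono little-endian; out-of-range samples clip with a warning. The WFDB
reader handles the format-16 dialect and returns µV.

## Known limitations

* The acoustic over-the-air channel (speaker/microphone nonlinearity,
  ambient noise, voice-codec effects) is explicitly out of scope; the
  audio stream moves between the transformers as digital data.
* The built-in QRS detector is designed for monitoring-band signals; very
  low-amplitude or highly irregular morphologies may need a plugged-in
  detector.
* Desk-scale CNN training demonstrates that the architecture learns FM
  demodulation; matching the error levels achievable with a large
  clinical archive and long training runs requires exactly that — more
  data and more epochs than a test suite should spend.
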