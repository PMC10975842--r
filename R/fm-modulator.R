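# Transformer (ECG-to-Audio): each of the 8 independent leads frequency-
# modulates its own carrier (450..2550 Hz in 300 Hz steps, deviation 125 Hz,
# modulation index 50 Hz/mV), and the eight band signals are summed into a
# single mono audio stream at 11 kHz.

#' Frequency-modulation configuration
#'
#' @param carriers_hz Per-lead carrier frequencies, strictly increasing.
#'   Defaults to 450, 750, ..., 2550 Hz for leads I, II, V1--V6.
#' @param deviation_hz Frequency deviation at full-scale input (125 Hz).
#' @param amp_range_mv Supported amplitude range A_R in mV; inputs are
#'   clipped to `[-amp_range_mv, +amp_range_mv]` (2.5 mV).
#' @param carrier_amp Amplitude of each carrier; default 1/8 so the 8-band
#'   sum is bounded by 1 and survives 16-bit WAV quantization.
#' @param audio_fs Audio sampling rate in Hz (11,000).
#' @param initial_phase_rad Per-lead initial phase (default all zero).
#' @return An object of class `fm_config`.
#' @export
fm_config <- function(carriers_hz = seq(450, 2550, by = 300),
                      deviation_hz = 125, amp_range_mv = 2.5,
                      carrier_amp = 1 / 8, audio_fs = 11000,
                      initial_phase_rad = rep(0, length(carriers_hz))) {
  n <- length(carriers_hz)
  if (n < 1 || any(diff(carriers_hz) <= 0))
    stop("`carriers_hz` must be strictly increasing")
  if (deviation_hz <= 0) stop("`deviation_hz` must be positive")
  if (n > 1 && any(diff(carriers_hz) - 2 * deviation_hz < 0))
    stop("adjacent FM bands overlap: need spacing >= 2 * deviation_hz")
  if (max(carriers_hz) + deviation_hz >= audio_fs / 2)
    stop("highest band exceeds the audio Nyquist frequency")
  if (amp_range_mv <= 0) stop("`amp_range_mv` must be positive")
  if (carrier_amp * n > 1 + 1e-12)
    stop("`carrier_amp` times the number of leads must not exceed 1")
  if (length(initial_phase_rad) != n)
    stop("`initial_phase_rad` needs one entry per carrier")
  structure(list(carriers_hz = carriers_hz, deviation_hz = deviation_hz,
                 amp_range_mv = amp_range_mv, carrier_amp = carrier_amp,
                 audio_fs = audio_fs, initial_phase_rad = initial_phase_rad),
            class = "fm_config")
}

#' Instantaneous frequency of a lead's FM band
#'
#' Maps an instantaneous ECG amplitude to the instantaneous frequency of the
#' lead's band: carrier + deviation * amplitude / amplitude-range. With the
#' defaults the modulation index is 125/2.5 = 50 Hz/mV and 0 mV maps to the
#' carrier exactly.
#'
#' @param amplitude_mv ECG amplitude(s) in mV, already clipped to the
#'   supported range.
#' @param lead_index Lead index (1-based) into `config$carriers_hz`.
#' @param config An [fm_config()].
#' @return Instantaneous frequency in Hz (vectorized over `amplitude_mv`).
#' @export
instantaneous_frequency <- function(amplitude_mv, lead_index,
                                    config = fm_config()) {
  if (lead_index < 1 || lead_index > length(config$carriers_hz))
    stop("`lead_index` out of range")
  config$carriers_hz[lead_index] +
    config$deviation_hz * amplitude_mv / config$amp_range_mv
}

#' Frequency-modulate one lead
#'
#' Discrete FM with accumulated phase: the output is
#' `A_C * cos(phase0 + 2*pi*cumsum(f)/F_S)` where `f` is the instantaneous
#' frequency of each sample. The phase is a running sum in double precision
#' and is never wrapped.
#'
#' @param lead_samples Lead amplitudes in mV, already clipped and resampled
#'   to `config$audio_fs`.
#' @param lead_index Lead index (1-based).
#' @param config An [fm_config()].
#' @return Numeric vector of audio samples with `|s| <= carrier_amp`.
#' @export
modulate_lead <- function(lead_samples, lead_index, config = fm_config()) {
  f <- instantaneous_frequency(lead_samples, lead_index, config)
  phase <- config$initial_phase_rad[lead_index] +
    2 * pi * cumsum(f) / config$audio_fs
  config$carrier_amp * cos(phase)
}

#' Sonify an 8-lead ECG record into one audio stream
#'
#' Pipeline per lead: clip to the supported amplitude range, resample to the
#' audio rate (Fourier method), frequency-modulate; the eight band signals
#' are then summed. Input amplitudes are re-clipped after resampling so
#' interpolation overshoot cannot push a band outside its frequency slot.
#'
#' @param record A canonical 8-lead [ecg_record()] in mV (see
#'   [reduce_to_8()]). Records in uV are converted.
#' @param config An [fm_config()].
#' @return An [audio_stream()] at `config$audio_fs` whose length is
#'   `round(duration * audio_fs)`.
#' @export
sonify <- function(record, config = fm_config()) {
  record <- convert_units(record, "mV")
  if (ncol(record$samples) != length(config$carriers_hz))
    stop("record has ", ncol(record$samples), " leads but the FM config ",
         "defines ", length(config$carriers_hz), " carriers; reduce_to_8() first")
  a_r <- config$amp_range_mv
  record <- clip_amplitude(record, a_r)
  n_out <- round(n_samples(record) * config$audio_fs / record$fs)
  audio <- numeric(n_out)
  for (j in seq_len(ncol(record$samples))) {
    x <- resample_fourier(record$samples[, j], record$fs, config$audio_fs)
    x <- pmin(a_r, pmax(-a_r, x))
    audio <- audio + modulate_lead(x, j, config)
  }
  audio_stream(audio, fs = config$audio_fs)
}
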