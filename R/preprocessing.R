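# Patient-module analog conditioning, simulated in software: monitoring-band
# Butterworth filtering, hard amplitude limiting, and Fourier-method rate
# conversion.

#' Monitoring-band filter specification
#'
#' Defaults reproduce an ambulatory ECG front end: first-order Butterworth
#' high-pass at 0.64 Hz (baseline-wander rejection) cascaded with a
#' first-order Butterworth low-pass at 30 Hz (muscle-artifact rejection).
#'
#' @param hp_cutoff High-pass cutoff in Hz.
#' @param lp_cutoff Low-pass cutoff in Hz (must exceed `hp_cutoff`).
#' @param order Filter order of each section (default 1).
#' @param causal Apply each section forward-only, as analog hardware would
#'   (default). `FALSE` uses zero-phase (forward-backward) filtering.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(hp_cutoff = 0.64, lp_cutoff = 30, order = 1L,
                        causal = TRUE) {
  if (!(hp_cutoff > 0 && lp_cutoff > hp_cutoff))
    stop("need 0 < hp_cutoff < lp_cutoff")
  if (order < 1) stop("`order` must be >= 1")
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 order = as.integer(order), causal = isTRUE(causal)),
            class = "filter_spec")
}

apply_butter <- function(x, flt, causal) {
  if (causal) as.numeric(signal::filter(flt, x))
  else as.numeric(signal::filtfilt(flt, x))
}

#' Apply the monitoring-band filter to every lead
#'
#' Each lead is filtered independently by the high-pass then the low-pass
#' Butterworth section, single-pass causal by default.
#'
#' @param record An [ecg_record()].
#' @param spec A [filter_spec()].
#' @return The filtered record.
#' @export
monitoring_filter <- function(record, spec = filter_spec()) {
  nyq <- record$fs / 2
  if (spec$lp_cutoff >= nyq)
    stop("lp_cutoff (", spec$lp_cutoff, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  hp <- signal::butter(spec$order, spec$hp_cutoff / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$lp_cutoff / nyq, type = "low")
  record$samples <- apply(record$samples, 2, function(x)
    apply_butter(apply_butter(x, hp, spec$causal), lp, spec$causal))
  record
}

#' Hard-limit record amplitudes
#'
#' All samples outside `[-a_r, +a_r]` are clipped to the boundary, matching
#' the amplitude limiter at the input of the sonification transformer.
#'
#' @param record An [ecg_record()].
#' @param a_r Supported amplitude range in the record's units (default
#'   2.5 mV).
#' @return The clipped record.
#' @export
clip_amplitude <- function(record, a_r = 2.5) {
  if (!is.numeric(a_r) || a_r <= 0) stop("`a_r` must be positive")
  record$samples <- pmin(pmax(record$samples, -a_r), a_r)
  record
}

#' Fourier-method resampling
#'
#' Resamples a signal by zero-padding/truncating its discrete Fourier
#' transform (the classical FFT resampler, with the Nyquist bin split or
#' folded for even lengths). Output length is `round(length(x) * fs_out /
#' fs_in)`. Assumes the signal is approximately periodic over its window;
#' band-limited tones are preserved exactly.
#'
#' @param x Numeric signal vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return The resampled signal.
#' @export
resample_fourier <- function(x, fs_in, fs_out) {
  if (length(x) == 0) stop("cannot resample an empty signal")
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  n_in <- length(x)
  n_out <- round(n_in * fs_out / fs_in)
  if (n_out == n_in) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  m <- min(n_in, n_out)
  nyq <- m %/% 2 + 1
  Y[1:nyq] <- X[1:nyq]
  if (m > 2) {
    k <- m - nyq
    Y[(n_out - k + 1):n_out] <- X[(n_in - k + 1):n_in]
  }
  if (m %% 2 == 0) {
    if (n_out < n_in) {
      # downsampling: fold the mirrored component onto the new Nyquist bin
      Y[m / 2 + 1] <- Y[m / 2 + 1] + X[n_in - m / 2 + 1]
    } else {
      # upsampling: split the old Nyquist bin between +/- frequencies
      Y[m / 2 + 1] <- Y[m / 2 + 1] / 2
      Y[n_out - m / 2 + 1] <- Y[m / 2 + 1]
    }
  }
  Re(fft(Y, inverse = TRUE)) / n_in
}

#' Resample every lead of a record
#'
#' @param record An [ecg_record()].
#' @param fs_out Target sampling rate in Hz.
#' @return The record resampled to `fs_out` (fiducial times unchanged).
#' @export
resample_record <- function(record, fs_out) {
  if (record$fs == fs_out) return(record)
  samples <- apply(record$samples, 2, resample_fourier,
                   fs_in = record$fs, fs_out = fs_out)
  record$samples <- samples
  record$fs <- fs_out
  record
}
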