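# Classical FM demodulation oracle: an independent, training-free inverse of
# the modulator. Each band is isolated with a zero-phase Butterworth
# band-pass, the instantaneous frequency is read off the phase derivative of
# the analytic signal, and the carrier offset is mapped back to mV.

# Analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' FM band specification
#'
#' @param center_hz Band center (the lead's carrier frequency).
#' @param half_width_hz Half-width of the isolation band-pass; the default
#'   150 Hz is the 125 Hz deviation plus half of the 50 Hz guard band, the
#'   widest setting that keeps adjacent bands disjoint.
#' @param lead_index Lead index the band belongs to (1-based).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center_hz, half_width_hz = 150, lead_index = 1L) {
  if (center_hz <= half_width_hz)
    stop("band extends below 0 Hz")
  structure(list(center_hz = center_hz, half_width_hz = half_width_hz,
                 lead_index = as.integer(lead_index)),
            class = "band_spec")
}

#' Derive the per-lead band specs from an FM configuration
#'
#' @param config An [fm_config()].
#' @return List of [band_spec()], one per carrier; mutually disjoint.
#' @export
bands_from_config <- function(config = fm_config()) {
  guard <- if (length(config$carriers_hz) > 1)
    min(diff(config$carriers_hz)) - 2 * config$deviation_hz
  else config$deviation_hz
  hw <- config$deviation_hz + guard / 2
  lapply(seq_along(config$carriers_hz), function(j)
    band_spec(config$carriers_hz[j], hw, j))
}

#' Isolate one FM band as an analytic signal
#'
#' Band-pass filters the audio around the band center (4th-order Butterworth,
#' zero-phase) and returns the complex analytic signal (Hilbert transform),
#' from which envelope and instantaneous phase can be read directly.
#'
#' @param audio An [audio_stream()].
#' @param band A [band_spec()].
#' @return Complex vector, same length as the audio.
#' @export
isolate_band <- function(audio, band) {
  nyq <- audio$fs / 2
  lo <- band$center_hz - band$half_width_hz
  hi <- band$center_hz + band$half_width_hz
  if (hi >= nyq || lo <= 0)
    stop("band [", lo, ", ", hi, "] Hz outside (0, Nyquist)")
  if (length(audio$samples) < audio$fs / 10)
    stop("audio too short to accommodate the band filter transient")
  bp <- signal::butter(6, c(lo, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bp, audio$samples)
  analytic_signal(y)
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y <- as.numeric(y)
  # fill the half-window edges with the nearest computed value
  first <- which(!is.na(y))[1]
  last <- tail(which(!is.na(y)), 1)
  y[seq_len(first - 1)] <- y[first]
  if (last < length(y)) y[(last + 1):length(y)] <- y[last]
  y
}

#' Demodulate an FM audio stream back to an 8-lead ECG (DSP oracle)
#'
#' For every band: isolate the analytic signal, differentiate its unwrapped
#' phase (central differences) to get the instantaneous frequency, smooth it
#' with a short moving average, invert the modulation law
#' `amplitude = (f - F_C) * A_R / F_D`, low-pass, and resample to `out_fs`.
#' The first and last 100 ms are distorted by filter transients; downstream
#' error metrics should trim them (see `attr(result, "edge_trim_ms")`).
#'
#' @param audio An [audio_stream()] at `config$audio_fs`.
#' @param config The [fm_config()] used for sonification.
#' @param out_fs Output ECG sampling rate in Hz (default 250).
#' @param lead_names Names for the output leads; defaults to the canonical
#'   8-lead set when the config has 8 carriers.
#' @return An [ecg_record()] in mV at `out_fs`, with attribute
#'   `edge_trim_ms = 100`.
#' @export
dsp_demodulate <- function(audio, config = fm_config(), out_fs = 250,
                           lead_names = NULL) {
  if (abs(audio$fs - config$audio_fs) > 1e-9)
    stop("audio is sampled at ", audio$fs, " Hz but the FM config expects ",
         config$audio_fs, " Hz")
  n_lead <- length(config$carriers_hz)
  if (is.null(lead_names))
    lead_names <- if (n_lead == 8) LEADS8 else paste0("ch", seq_len(n_lead))
  bands <- bands_from_config(config)
  n_out <- round(length(audio$samples) * out_fs / audio$fs)
  lp <- signal::butter(4, min(100, out_fs / 2 * 0.8) / (audio$fs / 2),
                       type = "low")
  smooth_k <- max(3L, 2L * floor(config$audio_fs / 4000) + 1L)
  out <- matrix(0, n_out, n_lead, dimnames = list(NULL, lead_names))
  for (j in seq_len(n_lead)) {
    z <- isolate_band(audio, bands[[j]])
    phase <- signal::unwrap(Arg(z))
    n <- length(phase)
    f_inst <- numeric(n)
    f_inst[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) *
      audio$fs / (4 * pi)
    f_inst[1] <- f_inst[2]
    f_inst[n] <- f_inst[n - 1]
    f_inst <- moving_average(f_inst, smooth_k)
    amp <- (f_inst - config$carriers_hz[j]) *
      config$amp_range_mv / config$deviation_hz
    amp <- signal::filtfilt(lp, amp)
    out[, j] <- resample_fourier(amp, audio$fs, out_fs)
  }
  rec <- ecg_record(out, fs = out_fs, units = "mV")
  attr(rec, "edge_trim_ms") <- 100
  rec
}
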