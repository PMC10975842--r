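# Synthetic multi-lead ECG generator. Each beat is a sum of five Gaussian
# bumps (P, Q, R, S, T), projected onto leads by a per-lead scaling vector.
# The generator emits fiducial ground truth alongside the samples so the
# evaluation stack can be tested against known truth.

WAVE_LABELS <- c("P-peak", "Q-point", "R-peak", "S-peak", "J-point", "T-peak")

default_wave_params <- function() {
  data.frame(
    wave     = c("P", "Q", "R", "S", "T"),
    amp_mv   = c(0.12, -0.10, 1.10, -0.20, 0.30),
    width_s  = c(0.025, 0.010, 0.012, 0.012, 0.060),
    offset_s = c(-0.18, -0.030, 0.000, 0.030, 0.28)
  )
}

default_lead_projection <- function(n_leads = 8L) {
  base <- c(I = 0.6, II = 1.0, V1 = -0.5, V2 = 0.7,
            V3 = 1.1, V4 = 1.3, V5 = 1.1, V6 = 0.9)
  if (n_leads == 8L) return(base)
  p <- rep_len(unname(base), n_leads)
  names(p) <- paste0("ch", seq_len(n_leads))
  p
}

#' Configuration for the synthetic ECG generator
#'
#' @param duration_s Record duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (> 0).
#' @param n_leads Number of leads (default 8, named I, II, V1--V6).
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param rr_jitter_frac Fractional uniform jitter of each RR interval, in
#'   `[0, 1)`.
#' @param rhythm_mode `"sinus"` (quasi-periodic PQRST), `"irregular_rr"`
#'   (P waves suppressed, RR strongly randomized, an atrial-fibrillation-like
#'   surrogate), or `"ectopic"` (wide-QRS beats without P inserted at rate
#'   `ectopic_prob`).
#' @param ectopic_prob Per-beat probability of an ectopic beat in
#'   `rhythm_mode = "ectopic"`.
#' @param wave_params Data frame with columns `wave`, `amp_mv`, `width_s`
#'   (Gaussian standard deviation), `offset_s` (peak time relative to the
#'   R peak) for the five waves P, Q, R, S, T.
#' @param lead_projection Per-lead scaling applied to the common beat shape
#'   (sign flips allowed, e.g. V1).
#' @param noise_rms_mV RMS of additive white Gaussian noise, per lead.
#' @param baseline_wander_mV Amplitude of a sinusoidal baseline wander at a
#'   random frequency in 0.2--0.4 Hz, per lead.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   records.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 10, fs = 250, n_leads = 8L,
                         heart_rate_bpm = 70, rr_jitter_frac = 0.03,
                         rhythm_mode = c("sinus", "irregular_rr", "ectopic"),
                         ectopic_prob = 0.15,
                         wave_params = default_wave_params(),
                         lead_projection = default_lead_projection(n_leads),
                         noise_rms_mV = 0.02, baseline_wander_mV = 0.05,
                         seed = 1L) {
  rhythm_mode <- match.arg(rhythm_mode)
  chk <- function(ok, field, what) if (!ok) stop("invalid `", field, "`: ", what)
  chk(is.numeric(duration_s) && length(duration_s) == 1 && duration_s > 0,
      "duration_s", "must be a positive number")
  chk(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs",
      "must be a positive number")
  chk(is.numeric(n_leads) && n_leads >= 1, "n_leads", "must be >= 1")
  chk(is.numeric(heart_rate_bpm) && heart_rate_bpm > 0, "heart_rate_bpm",
      "must be positive")
  chk(is.numeric(rr_jitter_frac) && rr_jitter_frac >= 0 && rr_jitter_frac < 1,
      "rr_jitter_frac", "must lie in [0, 1)")
  chk(is.numeric(ectopic_prob) && ectopic_prob >= 0 && ectopic_prob <= 1,
      "ectopic_prob", "must lie in [0, 1]")
  chk(is.data.frame(wave_params) &&
        all(c("wave", "amp_mv", "width_s", "offset_s") %in% names(wave_params)),
      "wave_params", "must have columns wave, amp_mv, width_s, offset_s")
  chk(length(lead_projection) == n_leads, "lead_projection",
      "length must equal n_leads")
  chk(is.numeric(noise_rms_mV) && noise_rms_mV >= 0, "noise_rms_mV",
      "must be >= 0")
  chk(is.numeric(baseline_wander_mV) && baseline_wander_mV >= 0,
      "baseline_wander_mV", "must be >= 0")
  structure(list(duration_s = duration_s, fs = fs, n_leads = as.integer(n_leads),
                 heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_frac = rr_jitter_frac, rhythm_mode = rhythm_mode,
                 ectopic_prob = ectopic_prob, wave_params = wave_params,
                 lead_projection = lead_projection,
                 noise_rms_mV = noise_rms_mV,
                 baseline_wander_mV = baseline_wander_mV,
                 seed = as.integer(seed)),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-lead ECG record
#'
#' Lays out beats at the configured heart rate (with optional RR jitter or
#' rhythm disturbances), renders each as a sum of five Gaussian waves,
#' projects the common shape onto the leads, adds white noise and baseline
#' wander, and hard-limits amplitudes to +/-2.5 mV. Ground-truth fiducial
#' times (P-peak, Q-point, R-peak, S-peak, J-point, T-peak) are attached to
#' the returned record.
#'
#' @param config A [synth_config()].
#' @return An [ecg_record()] in mV with fiducial ground truth.
#' @export
generate_record <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("`config` must be a synth_config object")
  with_seed(config$seed, {
    n <- round(config$duration_s * config$fs)
    t <- (seq_len(n) - 1) / config$fs
    rr <- 60 / config$heart_rate_bpm
    jit <- switch(config$rhythm_mode,
                  irregular_rr = max(config$rr_jitter_frac, 0.2),
                  config$rr_jitter_frac)

    # Beat schedule: R-peak times, each RR uniformly jittered.
    r_times <- numeric(0)
    tb <- rr / 2
    while (tb < config$duration_s + rr) {
      r_times <- c(r_times, tb)
      tb <- tb + rr * (1 + if (jit > 0) runif(1, -jit, jit) else 0)
    }
    ectopic <- if (config$rhythm_mode == "ectopic")
      runif(length(r_times)) < config$ectopic_prob
    else rep(FALSE, length(r_times))

    wp <- config$wave_params
    shape <- numeric(n)
    fid_time <- c(); fid_wave <- c()
    for (b in seq_along(r_times)) {
      tr <- r_times[b]
      for (k in seq_len(nrow(wp))) {
        w <- wp$wave[k]
        if (w == "P" && (config$rhythm_mode == "irregular_rr" || ectopic[b]))
          next
        amp <- wp$amp_mv[k]
        wid <- wp$width_s[k]
        off <- wp$offset_s[k]
        if (ectopic[b] && w %in% c("Q", "R", "S")) {
          wid <- wid * 2.5        # wide QRS
          off <- off * 2.5
          if (w == "R") amp <- amp * 1.2
        }
        ctr <- tr + off
        idx <- which(t >= ctr - 5 * wid & t <= ctr + 5 * wid)
        if (length(idx))
          shape[idx] <- shape[idx] + amp * exp(-(t[idx] - ctr)^2 / (2 * wid^2))
        lab <- switch(w, P = "P-peak", Q = "Q-point", R = "R-peak",
                      S = "S-peak", T = "T-peak")
        if (ctr >= 0 && ctr < config$duration_s) {
          fid_time <- c(fid_time, ctr); fid_wave <- c(fid_wave, lab)
        }
        if (w == "S") {           # J point: end of the S deflection
          tj <- ctr + 2 * wid
          if (tj >= 0 && tj < config$duration_s) {
            fid_time <- c(fid_time, tj); fid_wave <- c(fid_wave, "J-point")
          }
        }
      }
    }

    proj <- config$lead_projection
    nm <- names(proj)
    if (is.null(nm)) nm <- if (config$n_leads == 8L) LEADS8
                           else paste0("ch", seq_len(config$n_leads))
    samples <- matrix(0, n, config$n_leads, dimnames = list(NULL, nm))
    for (j in seq_len(config$n_leads)) {
      x <- shape * proj[j]
      if (config$noise_rms_mV > 0)
        x <- x + rnorm(n, sd = config$noise_rms_mV)
      if (config$baseline_wander_mV > 0) {
        fbw <- runif(1, 0.2, 0.4)
        x <- x + config$baseline_wander_mV * sin(2 * pi * fbw * t + runif(1, 0, 2 * pi))
      }
      samples[, j] <- pmin(2.5, pmax(-2.5, x))
    }

    ord <- order(fid_wave, fid_time)
    fid <- do.call(rbind, lapply(nm, function(ld)
      data.frame(lead = ld, wave = fid_wave[ord],
                 time_ms = fid_time[ord] * 1000)))
    ecg_record(samples, fs = config$fs, units = "mV", fiducials = fid)
  })
}
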