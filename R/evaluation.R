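# Quality metrics for the transformed ECG: amplitude errors (RMSE, PRD),
# diagnostic errors (fiducial-point matching with +/-50 ms tolerance: MAD,
# Se, PPV), spectral errors (normalized Welch PSD difference, 0-100 Hz in
# 0.2 Hz bins), and STFT monitoring of the audio band structure.

#' Root mean squared error between two signals
#'
#' `sqrt(mean((x - y)^2))`; symmetric, zero iff the signals are identical.
#' The result is in the units of the inputs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y))
    stop("signals differ in length (", length(x), " vs ", length(y), ")")
  sqrt(mean((x - y)^2))
}

#' Percentage root-mean-square difference
#'
#' RMSE of the transformed signal against the original, normalized by the
#' RMS of the original, times 100. A perfect reconstruction gives 0%; an
#' all-zero reconstruction gives 100%.
#'
#' @param transformed,original Numeric vectors of equal length; `original`
#'   must not be identically zero.
#' @return PRD in percent.
#' @export
prd <- function(transformed, original) {
  rms_orig <- sqrt(mean(original^2))
  if (rms_orig == 0) stop("PRD undefined for an all-zero original signal")
  100 * rmse(transformed, original) / rms_orig
}

default_qrs_detector <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  e <- moving_average(d^2, max(3L, 2L * floor(0.04 * fs) + 1L))
  peak <- max(e)
  if (peak <= 0 || sqrt(peak) < 1e-6) return(integer(0))
  thr <- 0.15 * peak
  refractory <- round(0.25 * fs)
  above <- which(e > thr)
  if (length(above) == 0) return(integer(0))
  r_idx <- integer(0)
  last <- -Inf
  for (i in above) {
    if (i - last < refractory) {
      # keep the larger local energy within the refractory window
      if (e[i] > e[last]) {
        r_idx[length(r_idx)] <- i
        last <- i
      }
      next
    }
    r_idx <- c(r_idx, i)
    last <- i
  }
  # refine to the extremum of |x| near each energy peak
  half <- round(0.06 * fs)
  as.integer(vapply(r_idx, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    lo + which.max(abs(x[lo:hi])) - 1
  }, numeric(1)))
}

locate_extremum <- function(x, lo, hi, sign) {
  if (lo > hi) return(NA_integer_)
  lo + which.max(sign * x[lo:hi]) - 1L
}

#' Detect fiducial points in every lead
#'
#' Default detector: QRS complexes from the smoothed squared derivative with
#' an adaptive threshold and a 250 ms refractory period; the R peak is the
#' largest absolute deflection near each energy peak, and P-peak, Q-point,
#' S-peak, J-point and T-peak are located by constrained extremum searches
#' in physiologic windows around each R, following the R polarity of the
#' lead. A different QRS detector can be plugged in via `qrs_detector`
#' (a `function(x, fs)` returning R-peak sample indices).
#'
#' Intended for records band-limited to the monitoring band; the detector is
#' deterministic, so identical inputs give identical outputs.
#'
#' @param record An [ecg_record()] of at least 2 s.
#' @param qrs_detector Optional replacement QRS detector.
#' @return Data frame (`lead`, `wave`, `time_ms`), sorted within lead; empty
#'   for flat records.
#' @export
detect_fiducials <- function(record, qrs_detector = default_qrs_detector) {
  if (duration_s(record) < 2)
    stop("record shorter than 2 s: too short for fiducial detection")
  fs <- record$fs
  ms <- function(i) (i - 1) / fs * 1000
  out <- list()
  for (lead in lead_names(record)) {
    x <- record$samples[, lead]
    r_idx <- qrs_detector(x, fs)
    if (length(r_idx) == 0) next
    pol <- sign(x[r_idx])
    pol[pol == 0] <- 1
    n <- length(x)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    rows <- list()
    for (b in seq_along(r_idx)) {
      r <- r_idx[b]; s <- pol[b]
      add <- function(wave, idx) {
        if (!is.na(idx))
          rows[[length(rows) + 1]] <<- data.frame(lead = lead, wave = wave,
                                                  time_ms = ms(idx))
      }
      add("R-peak", r)
      q <- locate_extremum(x, max(1, r - round(0.08 * fs)),
                           max(1, r - round(0.006 * fs)), -s)
      add("Q-point", q)
      s_pk <- locate_extremum(x, min(n, r + round(0.006 * fs)),
                              min(n, r + round(0.08 * fs)), -s)
      add("S-peak", s_pk)
      if (!is.na(s_pk)) {
        # J point: QRS offset, where the slope first flattens after S
        jlim <- min(n, s_pk + round(0.10 * fs))
        seg <- abs(d[s_pk:jlim])
        flat <- which(seg < 0.05 * max(abs(d[max(1, r - round(0.08 * fs)):jlim])))
        add("J-point", if (length(flat)) s_pk + flat[1] - 1L
                       else min(n, s_pk + round(0.04 * fs)))
      }
      prev_r <- if (b > 1) r_idx[b - 1] else 1L
      next_r <- if (b < length(r_idx)) r_idx[b + 1] else n
      p_lo <- max(prev_r + round(0.12 * fs), r - round(0.30 * fs), 1)
      p_hi <- max(1, r - round(0.10 * fs))
      p <- locate_extremum(x, p_lo, p_hi, s)
      if (!is.na(p) && abs(x[p]) > 0.05 * abs(x[r])) add("P-peak", p)
      t_lo <- min(n, r + round(0.15 * fs))
      t_hi <- min(next_r - round(0.12 * fs), r + round(0.45 * fs), n)
      t_pk <- locate_extremum(x, t_lo, t_hi, s)
      add("T-peak", t_pk)
    }
    if (length(rows)) out[[lead]] <- do.call(rbind, rows)
  }
  if (length(out) == 0)
    return(data.frame(lead = character(0), wave = character(0),
                      time_ms = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$lead, lead_names(record)), res$wave, res$time_ms), ]
}

match_one <- function(ref, test, tol_ms) {
  pairs <- data.frame(ref_ms = numeric(0), test_ms = numeric(0),
                      dt_ms = numeric(0))
  if (length(ref) && length(test)) {
    cand <- expand.grid(i = seq_along(ref), j = seq_along(test))
    cand$dt <- abs(ref[cand$i] - test[cand$j])
    cand <- cand[cand$dt <= tol_ms, ]
    # greedy one-to-one by ascending |dt|, ties toward the earlier reference
    cand <- cand[order(cand$dt, ref[cand$i]), ]
    used_i <- logical(length(ref)); used_j <- logical(length(test))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs <- rbind(pairs, data.frame(ref_ms = ref[i], test_ms = test[j],
                                       dt_ms = abs(ref[i] - test[j])))
    }
    tp <- sum(used_i)
  } else tp <- 0L
  list(pairs = pairs, TP = as.integer(tp),
       FP = as.integer(length(test) - tp),
       FN = as.integer(length(ref) - tp))
}

#' Match fiducial-point sets within a time tolerance
#'
#' One-to-one nearest-neighbor matching of test against reference times,
#' per lead and wave, within `tol_ms`. Matched pairs are true positives;
#' unmatched reference points are false negatives, unmatched test points
#' false positives. MAD is the mean absolute time difference over matched
#' pairs; sensitivity `Se = TP/(TP+FN)` and positive predictive value
#' `PPV = TP/(TP+FP)` are reported in percent (`NA` when a denominator is
#' zero).
#'
#' @param reference,test Fiducial data frames (`lead`, `wave`, `time_ms`),
#'   as returned by [detect_fiducials()].
#' @param tol_ms Matching tolerance (default 50 ms).
#' @return A `match_report`: list with `by_wave` (per lead/wave counts,
#'   MAD +/- sd, Se, PPV) and `pairs` (matched pairs with `|dt|`).
#' @export
match_fiducials <- function(reference, test, tol_ms = 50) {
  keys <- unique(rbind(reference[c("lead", "wave")], test[c("lead", "wave")]))
  by_wave <- list(); pairs <- list()
  for (k in seq_len(nrow(keys))) {
    ld <- keys$lead[k]; wv <- keys$wave[k]
    r <- sort(reference$time_ms[reference$lead == ld & reference$wave == wv])
    t <- sort(test$time_ms[test$lead == ld & test$wave == wv])
    m <- match_one(r, t, tol_ms)
    by_wave[[k]] <- data.frame(
      lead = ld, wave = wv, TP = m$TP, FP = m$FP, FN = m$FN,
      mad_ms = if (m$TP > 0) mean(m$pairs$dt_ms) else NA_real_,
      sd_ms = if (m$TP > 1) sd(m$pairs$dt_ms) else NA_real_,
      se_pct = if (m$TP + m$FN > 0) 100 * m$TP / (m$TP + m$FN) else NA_real_,
      ppv_pct = if (m$TP + m$FP > 0) 100 * m$TP / (m$TP + m$FP) else NA_real_)
    if (nrow(m$pairs))
      pairs[[length(pairs) + 1]] <- cbind(lead = ld, wave = wv, m$pairs)
  }
  structure(list(
    by_wave = if (length(by_wave)) do.call(rbind, by_wave)
              else data.frame(),
    pairs = if (length(pairs)) do.call(rbind, pairs)
            else data.frame(lead = character(0), wave = character(0),
                            ref_ms = numeric(0), test_ms = numeric(0),
                            dt_ms = numeric(0)),
    tol_ms = tol_ms), class = "match_report")
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: periodic Hann window, mean-detrended
#' segments, 50% overlap, one-sided density scaling (power per Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples; the bin width is
#'   `fs / nperseg`.
#' @return List with `freq_hz` and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = round(5 * fs)) {
  n <- length(x)
  if (n < nperseg)
    stop("record too short for one Welch segment (", n, " < ", nperseg, ")")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))
  step <- nperseg %/% 2
  starts <- seq(1, n - nperseg + 1, by = step)
  acc <- numeric(nperseg %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- Mod(X[seq_len(nperseg %/% 2 + 1)])^2 / (fs * sum(w^2))
    last <- length(p)
    scale2 <- rep(2, last); scale2[1] <- 1
    if (nperseg %% 2 == 0) scale2[last] <- 1
    acc <- acc + p * scale2
  }
  list(freq_hz = (seq_len(nperseg %/% 2 + 1) - 1) * fs / nperseg,
       psd = acc / length(starts))
}

#' Normalized PSD error between two signals
#'
#' Welch PSDs of both signals on a common 0.2 Hz grid, compared bin-wise as
#' `|PSD_x - PSD_y| / max(PSD_x, PSD_y) * 100`, where the normalizer is the
#' global maximum over both PSDs (a scalar), so errors always lie in
#' `[0, 100]`%.
#'
#' @param x,y Numeric signals of equal length (transformed and original).
#' @param fs Sampling rate in Hz (must be at least 200 for the 0--100 Hz
#'   grid).
#' @param fmax Upper frequency bound of the grid (default 100 Hz).
#' @param bin_hz Bin width (default 0.2 Hz).
#' @return Data frame (`freq_hz`, `error_pct`) restricted to `[0, fmax]`.
#' @export
normalized_psd_error <- function(x, y, fs, fmax = 100, bin_hz = 0.2) {
  if (length(x) != length(y)) stop("signals differ in length")
  if (fs < 2 * fmax) stop("need fs >= ", 2 * fmax, " Hz for a 0-", fmax,
                          " Hz grid")
  nperseg <- round(fs / bin_hz)
  px <- welch_psd(x, fs, nperseg)
  py <- welch_psd(y, fs, nperseg)
  keep <- px$freq_hz <= fmax + 1e-9
  norm <- max(px$psd[keep], py$psd[keep])
  err <- if (norm > 0) abs(px$psd[keep] - py$psd[keep]) / norm * 100
         else rep(0, sum(keep))
  data.frame(freq_hz = px$freq_hz[keep], error_pct = err)
}

#' Short-time Fourier transform of an audio stream
#'
#' 1 s observation window shifted with half-window overlap, the monitoring
#' view used to verify that the eight FM bands sit at their carriers.
#'
#' @param audio An [audio_stream()] of at least `window_s` seconds.
#' @param window_s Window length in seconds (default 1).
#' @param overlap Fractional window overlap (default 0.5).
#' @return List with `time_s` (frame centers), `freq_hz`, and `magnitude`
#'   (frequency x frame matrix).
#' @export
spectrogram <- function(audio, window_s = 1, overlap = 0.5) {
  x <- audio$samples
  n_win <- round(window_s * audio$fs)
  if (length(x) < n_win)
    stop("audio shorter than one observation window")
  step <- n_win - round(overlap * n_win)
  starts <- seq(1, length(x) - n_win + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_win - 1)) / n_win))
  frames <- vapply(starts, function(s0) x[s0:(s0 + n_win - 1)] * w,
                   numeric(n_win))
  spec <- Mod(stats::mvfft(frames))[seq_len(n_win %/% 2 + 1), , drop = FALSE]
  list(time_s = (starts - 1 + n_win / 2) / audio$fs,
       freq_hz = (seq_len(n_win %/% 2 + 1) - 1) * audio$fs / n_win,
       magnitude = spec)
}

trim_record_edges <- function(record, trim_ms) {
  k <- round(trim_ms / 1000 * record$fs)
  n <- n_samples(record)
  if (2 * k >= n) stop("record too short for the requested edge trim")
  record$samples <- record$samples[(k + 1):(n - k), , drop = FALSE]
  record
}

#' Evaluate a transformed ECG against the original
#'
#' Computes, per lead: RMSE (uV), PRD (%), QRS detection counts and Se/PPV
#' from R-peak matching within the tolerance, per-wave MAD of fiducial
#' times (the same detector applied to both signals), and the median
#' normalized PSD error. Both records must share sampling rate and length.
#'
#' @param original,transformed [ecg_record()] objects with identical leads,
#'   fs and length.
#' @param trim_ms Edge trim applied to both records before all metrics
#'   (default 100 ms, covering demodulation filter transients).
#' @param tol_ms Fiducial matching tolerance (default 50 ms).
#' @param psd Also compute the PSD error (needs >= 5 s of signal).
#' @return An `eval_report`: list with `per_lead` (rmse_uv, prd_pct, QRS
#'   TP/FP/FN/Se/PPV, median PSD error), `mad_by_wave`, and the underlying
#'   `match_report`.
#' @export
evaluate_transformation <- function(original, transformed, trim_ms = 100,
                                    tol_ms = 50, psd = TRUE) {
  if (!identical(lead_names(original), lead_names(transformed)))
    stop("lead sets differ between original and transformed records")
  if (original$fs != transformed$fs)
    stop("sampling rates differ")
  if (n_samples(original) != n_samples(transformed))
    stop("record lengths differ")
  orig <- convert_units(original, "mV")
  trans <- convert_units(transformed, "mV")
  if (trim_ms > 0) {
    orig <- trim_record_edges(orig, trim_ms)
    trans <- trim_record_edges(trans, trim_ms)
  }
  ref_fid <- detect_fiducials(orig)
  test_fid <- detect_fiducials(trans)
  mr <- match_fiducials(ref_fid, test_fid, tol_ms)
  per_lead <- do.call(rbind, lapply(lead_names(orig), function(ld) {
    x <- orig$samples[, ld]; y <- trans$samples[, ld]
    r <- mr$by_wave[mr$by_wave$lead == ld & mr$by_wave$wave == "R-peak", ]
    data.frame(
      lead = ld,
      rmse_uv = rmse(y, x) * 1000,
      prd_pct = prd(y, x),
      qrs_tp = if (nrow(r)) r$TP else 0L,
      qrs_fp = if (nrow(r)) r$FP else 0L,
      qrs_fn = if (nrow(r)) r$FN else 0L,
      qrs_se_pct = if (nrow(r)) r$se_pct else NA_real_,
      qrs_ppv_pct = if (nrow(r)) r$ppv_pct else NA_real_,
      psd_err_median_pct = if (psd)
        median(normalized_psd_error(y, x, orig$fs)$error_pct)
      else NA_real_)
  }))
  structure(list(per_lead = per_lead,
                 mad_by_wave = mr$by_wave,
                 match = mr, trim_ms = trim_ms, tol_ms = tol_ms),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> per-lead amplitude and diagnostic errors\n")
  print(x$per_lead, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(per_lead = report$per_lead,
                            mad_by_wave = report$mad_by_wave,
                            trim_ms = report$trim_ms,
                            tol_ms = report$tol_ms),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
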