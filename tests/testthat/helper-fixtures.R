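# Shared fixtures, all built in code.

zero_record8 <- function(duration_s = 10, fs = 250) {
  ecg_record(matrix(0, round(duration_s * fs), 8,
                    dimnames = list(NULL, c("I", "II", "V1", "V2",
                                            "V3", "V4", "V5", "V6"))),
             fs = fs, units = "mV")
}

constant_record8 <- function(values, duration_s = 10, fs = 250) {
  rec <- zero_record8(duration_s, fs)
  for (j in seq_along(values)) rec$samples[, j] <- values[j]
  rec
}

# FFT peak frequencies of an audio stream, above a relative magnitude floor
fft_peaks <- function(stream, rel_floor = 0.5) {
  n <- length(stream$samples)
  X <- Mod(fft(stream$samples))[seq_len(n %/% 2 + 1)]
  f <- (seq_len(n %/% 2 + 1) - 1) * stream$fs / n
  idx <- which(X > max(X) * rel_floor)
  groups <- split(idx, cumsum(c(1, diff(idx) > 2)))
  sort(unname(vapply(groups, function(i) f[i[which.max(X[i])]], numeric(1))))
}

# amplitude of a steady-state tone via least squares on a sin/cos basis
fit_tone_amplitude <- function(x, freq, fs) {
  t <- (seq_along(x) - 1) / fs
  b <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- coef(lm(x ~ b - 1))
  sqrt(sum(cf^2))
}

tiny_cnn_arch <- function() {
  cnn_architecture(conv_kernels = c(8L, 4L), conv_filters = c(4L, 2L),
                   pool_windows = c(2L, 2L), dropout_rate = 0.1)
}

# small paired dataset for CNN mechanics tests (not for accuracy claims)
tiny_pairs <- function(n = 8, segment_s = 0.5, seed = 5) {
  make_training_pairs(n_records = max(1, ceiling(n * segment_s / 10)),
                      segment_s = segment_s, seed = seed)[seq_len(n)]
}

python_available <- function() {
  nzchar(Sys.which("python"))
}
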