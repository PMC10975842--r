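test_that("the high-pass section fully rejects DC", {
  rec <- constant_record8(rep(1, 8), duration_s = 15, fs = 250)
  out <- monitoring_filter(rec, filter_spec())
  tail_part <- out$samples[(10 * 250):(15 * 250 - 1), ]
  expect_lt(max(abs(tail_part)), 0.01)
})

test_that("steady-state gain matches the analytic Butterworth cascade", {
  fs <- 250
  t <- (0:(40 * fs - 1)) / fs
  gain_analytic <- function(f, hp = 0.64, lp = 30) {
    (f / hp) / sqrt(1 + (f / hp)^2) / sqrt(1 + (f / lp)^2)
  }
  rec <- zero_record8(40, fs)
  rec$samples[, 1] <- sin(2 * pi * 10 * t)
  out <- monitoring_filter(rec, filter_spec())
  ss <- out$samples[(20 * fs):(40 * fs - 1), 1]
  amp <- fit_tone_amplitude(ss, 10, fs)
  expect_equal(amp, gain_analytic(10), tolerance = 0.01)
})

test_that("the high-pass section alone is -3 dB at its 0.64 Hz cutoff", {
  fs <- 250
  t <- (0:(120 * fs - 1)) / fs
  x <- sin(2 * pi * 0.64 * t)
  hp <- signal::butter(1, 0.64 / (fs / 2), type = "high")
  y <- as.numeric(signal::filter(hp, x))
  amp <- fit_tone_amplitude(y[(60 * fs):length(y)], 0.64, fs)
  expect_lt(abs(20 * log10(amp) - (-3.0103)), 0.1)
})

test_that("low-pass cutoff at or above Nyquist is rejected", {
  rec <- zero_record8(2, fs = 50)
  expect_error(monitoring_filter(rec, filter_spec(lp_cutoff = 30)), "Nyquist")
  expect_error(filter_spec(hp_cutoff = 40, lp_cutoff = 30), "hp_cutoff")
})

test_that("filtering is linear", {
  fs <- 250
  set.seed(11)
  x <- rnorm(fs * 4); y <- rnorm(fs * 4)
  mk <- function(v) {
    r <- zero_record8(4, fs); r$samples[, 1] <- v; r
  }
  f <- function(v) monitoring_filter(mk(v))$samples[, 1]
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-10)
})

test_that("amplitude clipping is symmetric, tight and idempotent", {
  rec <- constant_record8(c(3, -4, 1, 0, 2.5, -2.5, 0.1, -0.1),
                          duration_s = 1)
  out <- clip_amplitude(rec, 2.5)
  expect_equal(unname(out$samples[1, ]), c(2.5, -2.5, 1, 0, 2.5, -2.5,
                                           0.1, -0.1))
  expect_identical(clip_amplitude(out, 2.5)$samples, out$samples)
  in_range <- constant_record8(rep(0.5, 8), duration_s = 1)
  expect_identical(clip_amplitude(in_range, 2.5)$samples, in_range$samples)
})

test_that("Fourier resampling has the required lengths and identities", {
  set.seed(12)
  x <- rnorm(2500)
  expect_length(resample_fourier(x, 250, 11000), 110000)
  expect_identical(resample_fourier(x, 250, 250), x)
  expect_error(resample_fourier(numeric(0), 250, 500), "empty")
})

test_that("resampling preserves tone frequency below both Nyquist limits", {
  fs_in <- 250
  t <- (0:(fs_in * 4 - 1)) / fs_in
  x <- sin(2 * pi * 5 * t)
  for (fs_out in c(11000, 100)) {
    y <- resample_fourier(x, fs_in, fs_out)
    n <- length(y)
    X <- Mod(fft(y))[seq_len(n %/% 2)]
    f_peak <- (which.max(X) - 1) * fs_out / n
    expect_lt(abs(f_peak - 5), fs_out / n + 1e-9)
  }
})

test_that("Fourier resampling agrees with the reference FFT resampler", {
  skip_if_not(python_available(), "python not on PATH")
  set.seed(13)
  x <- rnorm(250)
  y_up <- resample_fourier(x, 250, 1000)
  y_dn <- resample_fourier(x, 250, 100)
  xf <- tempfile(); yf <- tempfile()
  writeLines(as.character(x), xf)
  code <- sprintf(paste0(
    "import numpy as np; from scipy.signal import resample; ",
    "x = np.loadtxt('%s'); ",
    "np.savetxt('%s', np.concatenate([resample(x,1000), resample(x,100)]))"),
    xf, yf)
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)
  ref <- as.numeric(readLines(yf))
  expect_equal(c(y_up, y_dn), ref, tolerance = 1e-10)
  unlink(c(xf, yf))
})
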