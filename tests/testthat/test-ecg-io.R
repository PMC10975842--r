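make_12_lead <- function(n = 500, fs = 250, seed = 1) {
  set.seed(seed)
  I <- rnorm(n, sd = 0.3); II <- rnorm(n, sd = 0.5)
  chest <- matrix(rnorm(6 * n, sd = 0.4), n, 6,
                  dimnames = list(NULL, paste0("V", 1:6)))
  samples <- cbind(III = II - I, aVR = -(I + II) / 2, aVL = I - II / 2,
                   aVF = II - I / 2, I = I, II = II, chest)
  ecg_record(samples, fs = fs, units = "mV")
}

test_that("reduce_to_8 selects the canonical leads in canonical order", {
  rec12 <- make_12_lead()
  rec8 <- reduce_to_8(rec12)
  expect_identical(colnames(rec8$samples),
                   c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  expect_identical(rec8$samples[, "I"], rec12$samples[, "I"])
  # canonical input is passed through unchanged
  expect_identical(reduce_to_8(rec8)$samples, rec8$samples)
})

test_that("reduce_to_8 names the missing lead", {
  rec <- make_12_lead()
  rec$samples <- rec$samples[, setdiff(colnames(rec$samples), "V3")]
  expect_error(reduce_to_8(rec), "V3")
})

test_that("derive_12 applies the Einthoven and Goldberger identities", {
  rec <- constant_record8(c(0.5, 1.0, 0, 0, 0, 0, 0, 0), duration_s = 1)
  full <- derive_12(rec)
  expect_equal(unname(full$samples[1, "III"]), 0.5)
  expect_equal(unname(full$samples[1, "aVR"]), -0.75)
  expect_equal(unname(full$samples[1, "aVL"]), 0.0)
  expect_equal(unname(full$samples[1, "aVF"]), 0.75)
  expect_error(derive_12(make_12_lead()), "canonical")
})

test_that("derive_12 after reduce_to_8 reproduces consistent limb leads", {
  rec12 <- make_12_lead(seed = 2)
  back <- derive_12(reduce_to_8(rec12))
  for (ld in c("III", "aVR", "aVL", "aVF"))
    expect_equal(back$samples[, ld], rec12$samples[, ld], tolerance = 1e-12)
})

test_that("unit conversion is an exact factor 1000 in both directions", {
  rec <- constant_record8(rep(1.5, 8), duration_s = 1)
  uv <- convert_units(rec, "uV")
  expect_equal(unname(uv$samples[1, 1]), 1500)
  expect_identical(convert_units(uv, "uV"), uv)   # idempotent
  expect_equal(convert_units(uv, "mV")$samples, rec$samples)
})

test_that("WAV round trip is exact to 16-bit quantization", {
  fs <- 11000
  t <- (0:(fs - 1)) / fs
  tone <- audio_stream(0.9 * sin(2 * pi * 1000 * t), fs)
  path <- file.path(tempdir(), "tone.wav")
  write_wav(tone, path)
  back <- read_wav(path)
  expect_equal(back$fs, fs)
  expect_lte(max(abs(back$samples - tone$samples)), 2^-15)
  # zero signal round-trips exactly
  write_wav(audio_stream(numeric(1000), fs), path)
  expect_identical(read_wav(path)$samples, numeric(1000))
  unlink(path)
})

test_that("a 110,000-sample stream at 11 kHz reads back as 10 s", {
  path <- file.path(tempdir(), "ten.wav")
  write_wav(audio_stream(numeric(110000), 11000), path)
  back <- read_wav(path)
  expect_equal(length(back$samples) / back$fs, 10)
  unlink(path)
})

test_that("out-of-range audio is clipped with a warning; bad files error", {
  path <- file.path(tempdir(), "clip.wav")
  expect_warning(write_wav(audio_stream(c(0, 1.5, -2), 11000), path),
                 "clipped")
  expect_equal(read_wav(path)$samples[2], 1)
  writeBin(as.raw(1:64), path)
  expect_error(read_wav(path), "RIFF")
  unlink(path)
})

test_that("WFDB records round-trip exactly for integer-uV data", {
  set.seed(3)
  samples <- matrix(sample(-3000:3000, 8 * 400, replace = TRUE), 400, 8)
  rec <- ecg_record(samples, fs = 500, units = "uV",
                    lead_names = c("I", "II", "V1", "V2", "V3", "V4",
                                   "V5", "V6"))
  path <- file.path(tempdir(), "wfdbrec")
  write_wfdb(rec, path)
  back <- read_wfdb(path)
  expect_identical(unname(back$samples), unname(samples * 1.0))
  expect_equal(back$fs, 500)
  expect_identical(colnames(back$samples), colnames(rec$samples))
  unlink(paste0(path, c(".hea", ".dat")))
})

test_that("degenerate WFDB headers are rejected", {
  path <- file.path(tempdir(), "bad")
  writeLines("bad 0 500 100", paste0(path, ".hea"))
  expect_error(read_wfdb(path), "0 signals")
  expect_error(read_wfdb(file.path(tempdir(), "missing-record")),
               "missing WFDB header")
  unlink(paste0(path, ".hea"))
})
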