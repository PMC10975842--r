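test_that("rmse satisfies its defining identities", {
  set.seed(51)
  x <- rnorm(100)
  expect_identical(rmse(x, x), 0)
  expect_equal(rmse(x, x + 5), 5)
  expect_equal(rmse(c(0, 0), c(3, 4)), 5 / sqrt(2))
  y <- x + rnorm(100)
  expect_identical(rmse(x, y), rmse(y, x))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("prd follows the scaling identity and guards the zero case", {
  set.seed(52)
  x <- rnorm(500)
  expect_identical(prd(x, x), 0)
  expect_equal(prd(numeric(500), x), 100)
  expect_equal(prd(1.1 * x, x), 10, tolerance = 1e-9)
  for (a in c(0.5, 2))
    expect_equal(prd(a * x, x), abs(a - 1) * 100, tolerance = 1e-9)
  expect_error(prd(x, numeric(500)), "all-zero")
})

test_that("R peaks are detected within 8 ms of ground truth on clean data", {
  rec <- generate_record(synth_config(noise_rms_mV = 0,
                                      baseline_wander_mV = 0, seed = 53))
  rec <- monitoring_filter(rec, filter_spec())
  fid <- detect_fiducials(rec)
  truth <- generate_record(synth_config(noise_rms_mV = 0,
                                        baseline_wander_mV = 0,
                                        seed = 53))$fiducials
  for (ld in c("II", "V4")) {
    tr <- truth$time_ms[truth$lead == ld & truth$wave == "R-peak"]
    det <- fid$time_ms[fid$lead == ld & fid$wave == "R-peak"]
    err <- vapply(tr, function(t0) min(abs(det - t0)), numeric(1))
    expect_gte(mean(err <= 8), 0.95)
  }
})

test_that("the fiducial detector is deterministic and silent on flat input", {
  rec <- monitoring_filter(generate_record(synth_config(seed = 54)))
  expect_identical(detect_fiducials(rec), detect_fiducials(rec))
  expect_identical(nrow(detect_fiducials(zero_record8(5, 250))), 0L)
  expect_error(detect_fiducials(zero_record8(1, 250)), "2 s")
})

test_that("fiducial matching reproduces hand-computed toy cases", {
  mk <- function(times) data.frame(lead = rep("II", length(times)),
                                   wave = rep("R-peak", length(times)),
                                   time_ms = times)
  m1 <- match_fiducials(mk(1000), mk(1040))
  expect_identical(m1$by_wave$TP, 1L)
  expect_equal(m1$by_wave$mad_ms, 40)

  m2 <- match_fiducials(mk(1000), mk(1060))
  expect_identical(c(m2$by_wave$TP, m2$by_wave$FP, m2$by_wave$FN),
                   c(0L, 1L, 1L))

  m3 <- match_fiducials(mk(c(1000, 2000)), mk(c(1010, 1990, 3000)))
  expect_identical(c(m3$by_wave$TP, m3$by_wave$FP, m3$by_wave$FN),
                   c(2L, 1L, 0L))
  expect_equal(m3$by_wave$mad_ms, 10)
  expect_equal(m3$by_wave$se_pct, 100)
  expect_equal(m3$by_wave$ppv_pct, 66.67, tolerance = 1e-3)

  # Se/PPV arithmetic on constructed counts: TP = 9, FN = 1, FP = 0
  m4 <- match_fiducials(mk(seq(1000, 10000, by = 1000)),
                        mk(seq(1000, 9000, by = 1000)))
  expect_identical(c(m4$by_wave$TP, m4$by_wave$FP, m4$by_wave$FN),
                   c(9L, 0L, 1L))
  expect_equal(m4$by_wave$se_pct, 90)
  expect_equal(m4$by_wave$ppv_pct, 100)

  # empty sets are tolerated; undefined rates reported as NA
  m5 <- match_fiducials(mk(numeric(0)), mk(1000))
  expect_true(is.na(m5$by_wave$se_pct))
})

test_that("identical signals give MAD 0 and Se = PPV = 100%", {
  rec <- monitoring_filter(generate_record(synth_config(seed = 55)))
  fid <- detect_fiducials(rec)
  m <- match_fiducials(fid, fid)
  r <- m$by_wave[m$by_wave$wave == "R-peak", ]
  expect_true(all(r$mad_ms == 0))
  expect_true(all(r$se_pct == 100 & r$ppv_pct == 100))
})

test_that("normalized PSD error honors its closed-form cases", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 7 * t)
  same <- normalized_psd_error(x, x, fs)
  expect_true(all(same$error_pct == 0))
  vs_zero <- normalized_psd_error(x, numeric(length(x)), fs)
  peak_bin <- which.min(abs(vs_zero$freq_hz - 7))
  expect_equal(vs_zero$error_pct[peak_bin], 100)
  # half amplitude: PSD scales with amplitude^2, so error = 75% at the peak
  halved <- normalized_psd_error(x, 0.5 * x, fs)
  expect_equal(halved$error_pct[peak_bin], 75, tolerance = 0.1)
  expect_true(all(halved$error_pct >= 0 & halved$error_pct <= 100))
  expect_error(normalized_psd_error(x[1:100], numeric(100), fs), "Welch")
})

test_that("Welch PSD matches the reference implementation", {
  skip_if_not(python_available(), "python not on PATH")
  set.seed(56)
  x <- rnorm(2500)
  p <- welch_psd(x, 250)
  xf <- tempfile(); yf <- tempfile()
  writeLines(as.character(x), xf)
  code <- sprintf(paste0(
    "import numpy as np; from scipy.signal import welch; ",
    "x = np.loadtxt('%s'); f, p = welch(x, fs=250, nperseg=1250); ",
    "np.savetxt('%s', p)"), xf, yf)
  expect_identical(system2("python", c("-c", shQuote(code))), 0L)
  ref <- as.numeric(readLines(yf))
  expect_equal(p$psd, ref, tolerance = 1e-10)
  unlink(c(xf, yf))
})

test_that("the spectrogram shows the carrier ridges and frame layout", {
  au <- sonify(zero_record8(10, 250), fm_config())
  sg <- spectrogram(au)
  expect_identical(length(sg$time_s), 19L)      # 1 s window, 0.5 s hop
  mean_mag <- rowMeans(sg$magnitude)
  ridge_idx <- which(mean_mag > 0.5 * max(mean_mag))
  clusters <- split(ridge_idx, cumsum(c(1, diff(ridge_idx) > 2)))
  ridge_f <- sort(vapply(clusters, function(i)
    sg$freq_hz[i[which.max(mean_mag[i])]], numeric(1)))
  expect_identical(length(ridge_f), 8L)
  expect_equal(unname(ridge_f), seq(450, 2550, by = 300),
               tolerance = 1e-6)
  # pure tone: single ridge at its bin
  t <- (0:109999) / 11000
  sg2 <- spectrogram(audio_stream(sin(2 * pi * 1000 * t), 11000))
  peak_f <- sg2$freq_hz[which.max(rowMeans(sg2$magnitude))]
  expect_equal(peak_f, 1000, tolerance = 1)
  expect_error(spectrogram(audio_stream(numeric(100), 11000)), "window")
})

test_that("evaluate_transformation populates a full per-lead report", {
  cfg <- fm_config()
  rec <- monitoring_filter(generate_record(synth_config(seed = 57)))
  dem <- dsp_demodulate(sonify(rec, cfg), cfg)
  ref <- resample_record(rec, 250)
  colnames(dem$samples) <- colnames(ref$samples)
  rep <- evaluate_transformation(ref, dem)
  expect_identical(nrow(rep$per_lead), 8L)
  expect_true(all(rep$per_lead$prd_pct < 10))
  expect_true(all(rep$per_lead$qrs_se_pct == 100))
  path <- file.path(tempdir(), "report.json")
  write_eval_report(rep, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
  unlink(path)
})
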