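# File input/output: ECG as CSV, audio as 16-bit PCM WAV, and a minimal
# reader/writer for WFDB format-16 records (.hea/.dat). The WAV and WFDB
# codecs are self-contained: both formats are simple enough that the few
# dozen lines below cover everything this package needs.

#' Write an ECG record to CSV
#'
#' Layout: first column `time_s`, then one column per lead with the lead name
#' as header. If the record carries fiducials they are written alongside to
#' `<path>` with suffix `_fiducials.csv` (columns `lead`, `wave`, `time_ms`).
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path.
#' @param write_fiducials Write the companion fiducial file when fiducials
#'   are present (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, write_fiducials = TRUE) {
  t <- (seq_len(n_samples(record)) - 1L) / record$fs
  df <- data.frame(time_s = t, record$samples, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (write_fiducials && !is.null(record$fiducials)) {
    fpath <- sub("\\.csv$", "", path)
    write.csv(record$fiducials, paste0(fpath, "_fiducials.csv"),
              row.names = FALSE)
  }
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Expects the layout produced by [write_ecg_csv()]: a `time_s` first column
#' (used to infer the sampling rate) followed by one column per lead.
#'
#' @param path CSV path.
#' @param units Amplitude unit of the stored samples (default `"mV"`).
#' @return An [ecg_record()]. A companion `_fiducials.csv` file, if present,
#'   is attached as the record's fiducials.
#' @export
read_ecg_csv <- function(path, units = "mV") {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L)
    stop("CSV must have a `time_s` column followed by one column per lead")
  t <- df$time_s
  if (length(t) < 2L) stop("CSV must contain at least two samples")
  fs <- 1 / median(diff(t))
  samples <- as.matrix(df[setdiff(names(df), "time_s")])
  fid <- NULL
  fpath <- paste0(sub("\\.csv$", "", path), "_fiducials.csv")
  if (file.exists(fpath)) fid <- read.csv(fpath)
  ecg_record(samples, fs = fs, units = units, fiducials = fid)
}

#' Write an audio stream as 16-bit PCM mono WAV
#'
#' Samples outside `[-1, 1]` are clipped with a warning before quantization
#' to 16-bit (`round(x * 32767)`).
#'
#' @param stream An [audio_stream()].
#' @param path Output `.wav` path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(stream, path) {
  x <- stream$samples
  if (any(x < -1 | x > 1)) {
    warning("audio samples outside [-1, 1] clipped before 16-bit quantization")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(stream$fs))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(2L * fs, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path `.wav` path. Only uncompressed 16-bit PCM mono is supported;
#'   anything else is an error.
#' @return An [audio_stream()] with samples scaled to `[-1, 1]` (divided by
#'   32767).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; fmt <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(fmt) || is.null(pcm)) stop("malformed WAV file: ", path)
  if (fmt != 1L || bits != 16L)
    stop("unsupported WAV encoding (need 16-bit PCM): ", path)
  if (channels != 1L)
    stop("non-mono WAV not supported (", channels, " channels): ", path)
  audio_stream(pcm / 32767, fs = fs)
}

#' Read a WFDB record (.hea + .dat, format 16)
#'
#' Minimal reader for the WFDB dialect used by clinical ECG archives: a text
#' header naming the signal files, gains and units, and little-endian 16-bit
#' sample files. Physical values are returned in microvolts regardless of the
#' header unit (mV headers are converted exactly, factor 1000).
#'
#' @param path Record path without extension (e.g. `"dir/rec001"`).
#' @return An [ecg_record()] in uV at the source sampling rate with the
#'   source lead names.
#' @export
read_wfdb <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing WFDB header: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4) stop("malformed WFDB header record line: ", hea)
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  n_samp <- as.integer(rec[4])
  if (is.na(n_sig) || n_sig <= 0)
    stop("WFDB header advertises ", rec[2], " signals")
  if (length(lines) < 1 + n_sig)
    stop("WFDB header has fewer signal lines than advertised")
  sig <- lapply(lines[2:(1 + n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3) stop("malformed WFDB signal line: ", ln)
    gain_spec <- f[3]
    units <- "mV"
    baseline <- 0
    m <- regmatches(gain_spec, regexec(
      "^([0-9.eE+-]+)(\\(([0-9+-]+)\\))?(/(\\S+))?$", gain_spec))[[1]]
    gain <- as.numeric(m[2])
    if (nzchar(m[4])) baseline <- as.numeric(m[4])
    if (length(m) >= 6 && nzchar(m[6])) units <- m[6]
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         units = units, name = if (length(f) >= 9)
           paste(f[9:length(f)], collapse = " ") else f[length(f)])
  })
  fmts <- unique(vapply(sig, `[[`, "", "format"))
  if (!identical(fmts, "16"))
    stop("only WFDB format 16 is supported (got ", paste(fmts, collapse = ","), ")")
  dat_files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(dat_files) != 1)
    stop("multi-file WFDB records are not supported")
  dat <- file.path(dirname(path), dat_files)
  if (!file.exists(dat)) stop("missing WFDB signal file: ", dat)
  raw <- readBin(dat, "integer", n = n_sig * n_samp, size = 2,
                 endian = "little")
  if (length(raw) < n_sig * n_samp)
    stop("WFDB signal file shorter than header advertises: ", dat)
  adc <- matrix(raw, ncol = n_sig, byrow = TRUE)
  phys <- sapply(seq_len(n_sig), function(j) {
    s <- sig[[j]]
    v <- (adc[, j] - s$baseline) / s$gain
    switch(s$units,
           uV = v, mV = v * 1000,
           stop("unsupported WFDB unit: ", s$units))
  })
  ecg_record(phys, fs = fs, units = "uV",
             lead_names = vapply(sig, `[[`, "", "name"))
}

#' Write a WFDB record (.hea + .dat, format 16)
#'
#' Counterpart of [read_wfdb()], used mainly to build round-trip fixtures.
#' Samples are stored as 16-bit integers in uV (gain 1 adu/uV, baseline 0),
#' so amplitudes must round-trip within +/-32.767 mV.
#'
#' @param record An [ecg_record()].
#' @param path Record path without extension; writes `<path>.hea` and
#'   `<path>.dat`.
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path) {
  rec_uv <- convert_units(record, "uV")
  adc <- round(rec_uv$samples)
  if (any(abs(adc) > 32767))
    stop("amplitudes exceed the 16-bit uV range (+/-32.767 mV)")
  name <- basename(path)
  n_sig <- ncol(adc)
  hea <- c(sprintf("%s %d %g %d", name, n_sig, record$fs, nrow(adc)),
           sprintf("%s.dat 16 1(0)/uV 16 0 %d 0 0 %s",
                   name, as.integer(adc[1, ]), colnames(adc)))
  writeLines(hea, paste0(path, ".hea"))
  writeBin(as.integer(t(adc)), paste0(path, ".dat"), size = 2,
           endian = "little")
  invisible(path)
}
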