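#' @useDynLib ecgsonify, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd median quantile approx
#' @importFrom utils head tail read.csv write.csv
NULL

# Canonical ordering of the 8 independent leads; III/aVR/aVL/aVF follow by
# linear identities, so these determine all 12 standard leads.
LEADS8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
LEADS12 <- c(LEADS8, "III", "aVR", "aVL", "aVF")

#' Construct a multi-lead ECG record
#'
#' An `ecg_record` holds a time-by-lead sample matrix together with its
#' sampling rate, amplitude unit, and (optionally) a table of fiducial-point
#' ground truth or measurements.
#'
#' @param samples Numeric matrix, one column per lead, one row per sample.
#'   A vector is treated as a single lead.
#' @param fs Sampling frequency in Hz (`> 0`).
#' @param units Amplitude unit, `"mV"` or `"uV"`.
#' @param lead_names Character vector of unique lead names, one per column.
#' @param fiducials Optional data frame with columns `lead`, `wave`,
#'   `time_ms` (times from record start).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, units = c("mV", "uV"),
                       lead_names = NULL, fiducials = NULL) {
  units <- match.arg(units)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (time x leads)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(lead_names)) {
    lead_names <- colnames(samples)
    if (is.null(lead_names))
      lead_names <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(lead_names) != ncol(samples))
    stop("`lead_names` length must match the number of sample columns")
  if (anyDuplicated(lead_names))
    stop("`lead_names` must be unique")
  colnames(samples) <- lead_names
  if (!is.null(fiducials)) {
    stopifnot(is.data.frame(fiducials),
              all(c("lead", "wave", "time_ms") %in% names(fiducials)))
  }
  structure(list(samples = samples, fs = fs, units = units,
                 fiducials = fiducials),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz [%s]\n",
              ncol(x$samples), nrow(x$samples), x$fs, x$units))
  cat("  leads:", paste(colnames(x$samples), collapse = ", "), "\n")
  if (!is.null(x$fiducials))
    cat(sprintf("  fiducials: %d annotated points\n", nrow(x$fiducials)))
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$samples)

lead_names <- function(record) colnames(record$samples)

n_samples <- function(record) nrow(record$samples)

duration_s <- function(record) nrow(record$samples) / record$fs

#' Convert record amplitudes between mV and uV
#'
#' The conversion factor is exactly 1000; converting to the unit the record
#' is already in returns it unchanged.
#'
#' @param record An [ecg_record()].
#' @param units Target unit, `"mV"` or `"uV"`.
#' @return The record expressed in `units`.
#' @export
convert_units <- function(record, units = c("mV", "uV")) {
  units <- match.arg(units)
  if (record$units == units) return(record)
  factor <- if (units == "mV") 1e-3 else 1e3
  record$samples <- record$samples * factor
  record$units <- units
  record
}

#' Reduce a record to the 8 independent leads
#'
#' Selects leads I, II, V1--V6 in canonical order and drops any others
#' (typically the derived limb leads III, aVR, aVL, aVF of a 12-lead set,
#' which carry no independent information).
#'
#' @param record An [ecg_record()] containing at least the 8 required leads.
#' @return An `ecg_record` with exactly the 8 canonical leads, in order.
#' @export
reduce_to_8 <- function(record) {
  missing <- setdiff(LEADS8, lead_names(record))
  if (length(missing) > 0)
    stop("lead ", missing[1], " absent: cannot form the canonical 8-lead set")
  record$samples <- record$samples[, LEADS8, drop = FALSE]
  if (!is.null(record$fiducials))
    record$fiducials <- record$fiducials[record$fiducials$lead %in% LEADS8, ,
                                         drop = FALSE]
  record
}

#' Derive the 12 standard leads from the canonical 8
#'
#' Appends the four dependent limb leads sample-wise from the Einthoven and
#' Goldberger identities: III = II - I, aVR = -(I + II)/2, aVL = I - II/2,
#' aVF = II - I/2.
#'
#' @param record A canonical 8-lead [ecg_record()] (leads I, II, V1--V6 in
#'   order).
#' @return A 12-lead `ecg_record`.
#' @export
derive_12 <- function(record) {
  if (!identical(lead_names(record), LEADS8))
    stop("input must be a canonical 8-lead record (I, II, V1-V6, in order)")
  I <- record$samples[, "I"]
  II <- record$samples[, "II"]
  extra <- cbind(III = II - I,
                 aVR = -(I + II) / 2,
                 aVL = I - II / 2,
                 aVF = II - I / 2)
  record$samples <- cbind(record$samples, extra)
  record
}

#' Construct a mono audio stream
#'
#' @param samples Numeric vector of audio samples, nominally in `[-1, 1]`.
#' @param fs Sampling frequency in Hz.
#' @return An object of class `audio_stream`.
#' @export
audio_stream <- function(samples, fs) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "audio_stream")
}

#' @export
print.audio_stream <- function(x, ...) {
  cat(sprintf("<audio_stream> %d samples @ %g Hz (%.3f s), range [%.3f, %.3f]\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}
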