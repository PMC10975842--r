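# Construction of paired (audio, target ECG) training data from the
# synthetic generator: each record is filtered to the monitoring band,
# sonified, and cut into aligned fixed-length segments. Training on short
# segments is possible because the network is fully convolutional; the
# mapping it must learn is local (receptive field ~75 ms).

#' Build paired sonified-audio / target-ECG training data
#'
#' Generates `n_records` synthetic records (seeds `seed`, `seed + 1`, ...),
#' applies the monitoring filter, sonifies each, and cuts the audio and the
#' filtered ECG into aligned `segment_s`-second pairs. The target ECG is the
#' filtered original resampled to `fm$audio_fs / 44` (250 Hz by default) —
#' the signal the demodulator is supposed to reproduce.
#'
#' @param n_records Number of synthetic records to generate.
#' @param segment_s Segment length in seconds (default 1).
#' @param synth Base [synth_config()]; its seed is re-derived per record.
#'   Heart rate is varied uniformly across records (55--95 bpm) and rhythm
#'   modes are cycled (sinus, irregular RR, ectopic) so the network sees
#'   narrow and wide complexes, with and without P waves.
#' @param filter A [filter_spec()].
#' @param fm An [fm_config()].
#' @param seed Base seed.
#' @param vary_rhythm Cycle rhythm modes and heart rates across records
#'   (default `TRUE`).
#' @return List of `list(audio = numeric, ecg = matrix)` pairs; attribute
#'   `"records"` gives the record index each pair came from.
#' @export
make_training_pairs <- function(n_records = 50, segment_s = 1,
                                synth = synth_config(), filter = filter_spec(),
                                fm = fm_config(), seed = 1L,
                                vary_rhythm = TRUE) {
  out_fs <- fm$audio_fs / 44
  modes <- c("sinus", "irregular_rr", "ectopic")
  rates <- with_seed(seed, runif(n_records, 55, 95))
  pairs <- list()
  origin <- integer(0)
  for (r in seq_len(n_records)) {
    cfg <- synth
    cfg$seed <- as.integer(seed + r)
    if (vary_rhythm) {
      cfg$rhythm_mode <- modes[(r - 1) %% 3 + 1]
      cfg$heart_rate_bpm <- rates[r]
    }
    rec <- monitoring_filter(generate_record(cfg), filter)
    audio <- sonify(rec, fm)
    target <- resample_record(rec, out_fs)
    n_seg <- floor(duration_s(rec) / segment_s)
    na <- round(segment_s * fm$audio_fs)
    ne <- round(segment_s * out_fs)
    for (i in seq_len(n_seg)) {
      pairs[[length(pairs) + 1]] <- list(
        audio = audio$samples[((i - 1) * na + 1):(i * na)],
        ecg = target$samples[((i - 1) * ne + 1):(i * ne), , drop = FALSE])
      origin <- c(origin, r)
    }
  }
  attr(pairs, "records") <- origin
  pairs
}
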