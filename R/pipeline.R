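# End-to-end pipeline: generate or load ECG, preprocess, sonify, demodulate
# (DSP oracle or CNN), and evaluate. A single YAML file configures every
# stage; every default equals the design constant where one exists.

#' Assemble a pipeline configuration
#'
#' @param synth A [synth_config()].
#' @param filter A [filter_spec()].
#' @param fm An [fm_config()].
#' @param train A [train_config()].
#' @param method Demodulation method, `"dsp"` (training-free oracle) or
#'   `"cnn"`.
#' @param model_path Path to a CNN checkpoint (required for
#'   `method = "cnn"`).
#' @param out_dir Directory for WAV/CSV/JSON outputs (`NULL`: no files
#'   written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), filter = filter_spec(),
                            fm = fm_config(), train = train_config(),
                            method = c("dsp", "cnn"), model_path = NULL,
                            out_dir = NULL) {
  method <- match.arg(method)
  ecg_nyq <- synth$fs / 2
  if (filter$lp_cutoff >= ecg_nyq)
    stop("filter lp_cutoff must be below the ECG Nyquist frequency")
  if (max(fm$carriers_hz) + fm$deviation_hz >= fm$audio_fs / 2)
    stop("FM carriers must fit below the audio Nyquist frequency")
  structure(list(synth = synth, filter = filter, fm = fm, train = train,
                 method = method, model_path = model_path, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `synth`, `filter`, `fm`, `train`, `method`, `model_path`,
#' `out_dir`; each section holds the arguments of the corresponding
#' constructor and omitted values keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, args) do.call(fun, if (is.null(args)) list() else args)
  pipeline_config(
    synth = build(synth_config, y$synth),
    filter = build(filter_spec, y$filter),
    fm = build(fm_config, y$fm),
    train = build(train_config, y$train),
    method = if (is.null(y$method)) "dsp" else y$method,
    model_path = y$model_path,
    out_dir = y$out_dir)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full signal chain and evaluate it
#'
#' Generates a synthetic record (or loads `record`), applies the
#' monitoring-band filter, sonifies it, demodulates the audio with the
#' configured method, and evaluates the reconstruction against the filtered
#' original. When `config$out_dir` is set, the audio (WAV), original and
#' transformed ECG (CSV), and the evaluation report (JSON) are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @param record Optional input [ecg_record()]; defaults to a synthetic one.
#' @return List with `report` (an `eval_report`), `original` (filtered, at
#'   the demodulator output rate), `transformed`, `audio`, and `config`.
#' @export
run_end_to_end <- function(config = pipeline_config(), record = NULL) {
  out_fs <- config$fm$audio_fs / 44   # matches the CNN downsampling factor
  if (is.null(record))
    record <- stage("synth", generate_record(config$synth))
  record <- stage("preprocess", {
    rec <- convert_units(record, "mV")
    if (ncol(rec$samples) > 8) rec <- reduce_to_8(rec)
    monitoring_filter(rec, config$filter)
  })
  audio <- stage("sonify", sonify(record, config$fm))
  transformed <- stage("desonify", {
    if (config$method == "dsp") {
      dsp_demodulate(audio, config$fm, out_fs = out_fs,
                     lead_names = lead_names(record))
    } else {
      if (is.null(config$model_path) || !file.exists(config$model_path %||% ""))
        stop("CNN model file not found: ",
             if (is.null(config$model_path)) "<unset>" else config$model_path)
      model <- load_cnn(config$model_path)
      predict_ecg(model, audio, expected_fs = config$fm$audio_fs)
    }
  })
  reference <- stage("evaluate-prep",
                     resample_record(record, transformed$fs))
  # restore lead names lost if the demodulator emitted generic channels
  colnames(transformed$samples) <- lead_names(reference)
  report <- stage("evaluate",
                  evaluate_transformation(reference, transformed,
                                          psd = duration_s(reference) >= 5))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_wav(audio, file.path(config$out_dir, "audio_ecg.wav"))
    write_ecg_csv(reference, file.path(config$out_dir, "original_ecg.csv"))
    write_ecg_csv(transformed, file.path(config$out_dir, "transformed_ecg.csv"))
    write_eval_report(report, file.path(config$out_dir, "report.json"))
  }
  list(report = report, original = reference, transformed = transformed,
       audio = audio, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
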