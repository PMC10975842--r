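# Transformer (Audio-to-ECG): R-side interface to the compiled 1D CNN.
# The default architecture maps 10 s of audio at 11 kHz (110,000 samples,
# 1 channel) to 10 s of 8-lead ECG at 250 Hz (2,500 samples): four conv
# layers 220@24, 20@24, 10@24, 5@8 with linear activations, max pooling
# 11/2/2 interleaved after the first three convs, dropout 0.1, for a total
# of 23,600 trainable parameters.

#' CNN demodulator architecture
#'
#' @param conv_kernels Kernel sizes of the four conv layers.
#' @param conv_filters Filter counts; the last one fixes the number of
#'   output leads.
#' @param pool_windows Non-overlapping max-pool windows placed after each of
#'   the first `length(pool_windows)` conv layers. Their product is the
#'   audio-to-ECG downsampling factor (44 by default: 11,000 Hz to 250 Hz).
#' @param dropout_rate Dropout rate applied after every layer during
#'   training (inference is deterministic).
#' @param input_channels Number of input channels (1: mono audio).
#' @return An object of class `cnn_arch`.
#' @export
cnn_architecture <- function(conv_kernels = c(220L, 20L, 10L, 5L),
                             conv_filters = c(24L, 24L, 24L, 8L),
                             pool_windows = c(11L, 2L, 2L),
                             dropout_rate = 0.1, input_channels = 1L) {
  if (length(conv_kernels) != length(conv_filters))
    stop("`conv_kernels` and `conv_filters` must have the same length")
  if (length(pool_windows) > length(conv_kernels))
    stop("more pool windows than conv layers")
  if (any(conv_kernels < 1) || any(conv_filters < 1) || any(pool_windows < 1))
    stop("kernels, filters and pools must be positive integers")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)")
  n <- length(conv_kernels)
  structure(list(conv_kernels = as.integer(conv_kernels),
                 conv_filters = as.integer(conv_filters),
                 pool_windows = as.integer(pool_windows),
                 dropout_rate = dropout_rate,
                 input_channels = as.integer(input_channels),
                 cin = as.integer(c(input_channels, conv_filters[-n])),
                 pool_full = as.integer(c(pool_windows,
                                          rep(1L, n - length(pool_windows))))),
            class = "cnn_arch")
}

#' Trainable parameter count of an architecture
#'
#' Per conv layer: `kernel * channels_in * channels_out + channels_out`
#' (weights plus biases). The default architecture totals 23,600.
#'
#' @param arch A [cnn_architecture()].
#' @return Named list with `per_layer` counts and the `total`.
#' @export
count_params <- function(arch) {
  per <- arch$conv_kernels * arch$cin * arch$conv_filters + arch$conv_filters
  list(per_layer = per, total = sum(per))
}

#' Audio-to-ECG downsampling factor
#' @param arch A [cnn_architecture()].
#' @return Product of the pool windows (44 by default).
#' @export
downsample_factor <- function(arch) as.integer(prod(arch$pool_windows))

arch_for_cpp <- function(arch) {
  list(kernel = arch$conv_kernels, cin = arch$cin,
       cout = arch$conv_filters, pool = arch$pool_full)
}

#' Build an untrained CNN demodulator
#'
#' Weights are Glorot-uniform, biases zero; initialization is reproducible
#' from `seed`. Weight matrices are stored as `(kernel * channels_in) x
#' channels_out`, rows ordered channel-major (channel block of `kernel`
#' positions).
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `cnn_model`.
#' @export
build_model <- function(arch = cnn_architecture(), seed = 42L) {
  with_seed(seed, {
    weights <- lapply(seq_along(arch$conv_kernels), function(l) {
      k <- arch$conv_kernels[l]; cin <- arch$cin[l]; cout <- arch$conv_filters[l]
      limit <- sqrt(6 / (k * cin + k * cout))
      list(W = matrix(runif(k * cin * cout, -limit, limit), k * cin, cout),
           b = numeric(cout))
    })
    structure(list(arch = arch, weights = weights, trained = FALSE,
                   history = NULL, init_seed = as.integer(seed)),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  p <- count_params(x$arch)
  cat(sprintf("<cnn_model> %d conv layers, %s trainable parameters (%s)\n",
              length(x$arch$conv_kernels), format(p$total, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  for (l in seq_along(x$arch$conv_kernels))
    cat(sprintf("  conv%d: %d@%d, pool %d, params %d\n", l,
                x$arch$conv_kernels[l], x$arch$conv_filters[l],
                x$arch$pool_full[l], p$per_layer[l]))
  invisible(x)
}

#' Training protocol configuration
#'
#' Defaults follow the full-scale protocol: Adam at learning rate 0.001,
#' batches of 256, a 70/30 record-level train/validation split, at most
#' 1000 epochs with early stopping after 150 epochs without validation
#' improvement, and restoration of the minimum-validation-loss weights.
#' The loss optimized is MSE; history is reported as RMSE.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param val_fraction Fraction of records held out for validation.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (set `>= max_epochs` to disable).
#' @param shuffle Shuffle the training records each epoch.
#' @param seed Integer seed covering the split, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 256L,
                         val_fraction = 0.30, max_epochs = 1000L,
                         early_stop_patience = 150L, shuffle = TRUE,
                         seed = 1L) {
  if (val_fraction < 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in [0, 1)")
  if (early_stop_patience > max_epochs)
    stop("`early_stop_patience` must not exceed `max_epochs`")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "train_config")
}

as_pair_matrices <- function(dataset, arch) {
  xs <- lapply(dataset, function(p) {
    x <- if (inherits(p$audio, "audio_stream")) p$audio$samples else p$audio
    matrix(as.numeric(x), ncol = arch$input_channels)
  })
  ys <- lapply(dataset, function(p) {
    y <- if (inherits(p$ecg, "ecg_record")) p$ecg$samples else p$ecg
    matrix(as.numeric(y), nrow = nrow(y))
  })
  list(x = xs, y = ys)
}

#' Train the CNN demodulator
#'
#' Unsupervised regression: the model learns to reproduce the original ECG
#' from its sonified audio, minimizing the mean squared error between
#' transformed and original samples. The dataset is split at record level
#' into training and validation subsets; the returned model carries the
#' weights of the epoch with minimal validation loss and the per-epoch
#' RMSE history.
#'
#' @param model A [build_model()] result.
#' @param dataset List of pairs, each `list(audio = , ecg = )`, where audio
#'   is an [audio_stream()] (or numeric vector at 11 kHz) and ecg the target
#'   [ecg_record()] (or matrix, time x leads, in mV) at the output rate.
#'   Audio length must be `downsample_factor(arch)` times the target length.
#' @param config A [train_config()].
#' @return The trained `cnn_model`, with `history` (data frame of per-epoch
#'   train/validation RMSE in mV and uV), `best_epoch` and `epochs_run`.
#' @export
train_cnn <- function(model, dataset, config = train_config()) {
  if (!inherits(model, "cnn_model")) stop("`model` must be a cnn_model")
  if (length(dataset) == 0) stop("empty dataset")
  pm <- as_pair_matrices(dataset, model$arch)
  fac <- prod(model$arch$pool_full)
  for (i in seq_along(pm$x)) {
    if (nrow(pm$x[[i]]) != fac * nrow(pm$y[[i]]))
      stop("pair ", i, ": audio length must be ", fac,
           " times the target ECG length")
    if (ncol(pm$y[[i]]) != tail(model$arch$conv_filters, 1))
      stop("pair ", i, ": target has ", ncol(pm$y[[i]]),
           " leads, architecture emits ", tail(model$arch$conv_filters, 1))
  }
  n <- length(dataset)
  groups <- attr(dataset, "records")
  if (is.null(groups)) groups <- seq_len(n)   # each pair its own record
  # record-level split so segments of one record never straddle train/val
  recs <- unique(groups)
  val_recs <- with_seed(config$seed, {
    k <- floor(config$val_fraction * length(recs))
    if (k > 0) sample(recs, k) else c()
  })
  val_idx <- which(groups %in% val_recs)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) stop("training split is empty")
  res <- cnn_train_cpp(model$weights, arch_for_cpp(model$arch),
                       pm$x[tr_idx], pm$y[tr_idx],
                       pm$x[val_idx], pm$y[val_idx],
                       config$max_epochs, config$batch_size,
                       config$learning_rate, model$arch$dropout_rate,
                       config$early_stop_patience, config$seed,
                       config$shuffle)
  model$weights <- lapply(res$weights, function(w)
    list(W = w$W, b = as.numeric(w$b)))
  model$trained <- TRUE
  ep <- seq_along(res$train_rmse)
  model$history <- data.frame(
    epoch = ep,
    train_rmse_mv = res$train_rmse,
    val_rmse_mv = if (length(res$val_rmse)) res$val_rmse else NA_real_,
    train_rmse_uv = res$train_rmse * 1000,
    val_rmse_uv = (if (length(res$val_rmse)) res$val_rmse else NA_real_) * 1000)
  model$best_epoch <- res$best_epoch
  model$epochs_run <- res$epochs_run
  model
}

#' RMSE of a model over a paired dataset
#'
#' Deterministic forward passes (no dropout); the pooled RMSE over all
#' samples, leads and pairs, in the target units (mV).
#'
#' @param model A `cnn_model`.
#' @param dataset Pair list as accepted by [train_cnn()].
#' @return Scalar RMSE.
#' @export
model_rmse <- function(model, dataset) {
  pm <- as_pair_matrices(dataset, model$arch)
  sse <- 0; n <- 0
  for (i in seq_along(pm$x)) {
    pred <- cnn_predict_cpp(model$weights, arch_for_cpp(model$arch), pm$x[[i]])
    sse <- sse + sum((pred - pm$y[[i]])^2)
    n <- n + length(pm$y[[i]])
  }
  sqrt(sse / n)
}

#' Apply the CNN demodulator to an audio stream
#'
#' @param model A `cnn_model` (trained or not).
#' @param audio An [audio_stream()] at 11 kHz. The nominal input is 10 s
#'   (110,000 samples); shorter inputs are zero-padded to the next multiple
#'   of the downsampling factor with a warning. A grossly different sampling
#'   rate (beyond 1%) is rejected.
#' @param expected_fs Sampling rate the model was trained at.
#' @return An [ecg_record()] in mV at `expected_fs / downsample_factor`
#'   (250 Hz by default), with canonical lead names when 8 leads are
#'   emitted.
#' @export
predict_ecg <- function(model, audio, expected_fs = 11000) {
  if (!inherits(model, "cnn_model")) stop("`model` must be a cnn_model")
  if (inherits(audio, "audio_stream")) {
    if (abs(audio$fs - expected_fs) / expected_fs > 0.01)
      stop("audio sampled at ", audio$fs, " Hz; the model expects ",
           expected_fs, " Hz")
    x <- audio$samples
  } else {
    x <- as.numeric(audio)
  }
  fac <- prod(model$arch$pool_full)
  if (length(x) %% fac != 0) {
    pad <- fac - length(x) %% fac
    warning("audio length ", length(x), " zero-padded by ", pad,
            " samples to a multiple of ", fac)
    x <- c(x, numeric(pad))
  }
  out <- cnn_predict_cpp(model$weights, arch_for_cpp(model$arch),
                         matrix(x, ncol = model$arch$input_channels))
  n_lead <- ncol(out)
  nm <- if (n_lead == 8) LEADS8 else paste0("ch", seq_len(n_lead))
  ecg_record(out, fs = expected_fs / fac, units = "mV", lead_names = nm)
}

#' Save / load a CNN demodulator
#'
#' The checkpoint is a self-describing JSON file: it records the full
#' architecture together with the weights (full double precision), so
#' [load_cnn()] needs no separate architecture specification and
#' `load_cnn(save_cnn(m))` reproduces predictions bit-identically.
#'
#' @param model A `cnn_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_cnn <- function(model, path) {
  chk <- list(
    format = "ecgsonify-cnn",
    version = 1L,
    arch = list(conv_kernels = model$arch$conv_kernels,
                conv_filters = model$arch$conv_filters,
                pool_windows = model$arch$pool_windows,
                dropout_rate = model$arch$dropout_rate,
                input_channels = model$arch$input_channels),
    trained = model$trained,
    init_seed = model$init_seed,
    weights = lapply(model$weights, function(w)
      list(W = as.vector(w$W), dim = dim(w$W), b = w$b)))
  json <- jsonlite::serializeJSON(chk, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  chk <- tryCatch(jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                                  collapse = "\n")),
                  error = function(e) stop("corrupt CNN checkpoint: ", path,
                                           " (", conditionMessage(e), ")"))
  if (!identical(chk$format, "ecgsonify-cnn"))
    stop("not an ecgsonify CNN checkpoint: ", path)
  arch <- cnn_architecture(chk$arch$conv_kernels, chk$arch$conv_filters,
                           chk$arch$pool_windows, chk$arch$dropout_rate,
                           chk$arch$input_channels)
  weights <- lapply(chk$weights, function(w)
    list(W = matrix(w$W, w$dim[1], w$dim[2]), b = as.numeric(w$b)))
  structure(list(arch = arch, weights = weights, trained = isTRUE(chk$trained),
                 history = NULL, init_seed = chk$init_seed),
            class = "cnn_model")
}
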