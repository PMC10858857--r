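# Window/stride parameter sweep: how the framing grid drives feature
# volume (and with it training cost) and accuracy.

#' Window/stride sweep grid
#'
#' Pairs must satisfy `s <= w`. The default is the 23-pair grid spanning
#' windows 0.1-3 s and strides 0.05-1 s used for the staging parameter
#' study; the winning pair there was `w = 0.5`, `s = 0.25`.
#'
#' @param pairs Data frame with columns `w` and `s` (seconds), or `NULL`
#'   for the default grid.
#' @param repetitions Training repetitions per pair, at least 1.
#' @return Object of class `sweep_grid`.
#' @export
sweep_grid <- function(pairs = NULL, repetitions = 1) {
  if (is.null(pairs)) {
    pairs <- rbind(
      data.frame(w = 0.1, s = 0.05),
      data.frame(w = 0.25, s = 0.1),
      expand.grid(w = 0.5, s = c(0.1, 0.25)),
      expand.grid(w = 1, s = c(0.1, 0.25, 0.5)),
      expand.grid(w = c(1.5, 2, 2.5, 3), s = c(0.1, 0.25, 0.5, 1))
    )
    pairs <- pairs[order(pairs$w, pairs$s), ]
  }
  stopifnot(is.data.frame(pairs), all(c("w", "s") %in% names(pairs)),
            repetitions >= 1)
  bad <- pairs$s > pairs$w | pairs$s <= 0 | pairs$w <= 0
  if (any(bad)) {
    stop("invalid (w, s) pair(s): ",
         paste(sprintf("(%g, %g)", pairs$w[bad], pairs$s[bad]), collapse = ", "),
         "; stride must satisfy 0 < s <= w", call. = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, repetitions = repetitions),
            class = "sweep_grid")
}

#' Frames per 30-s epoch for a framing choice
#'
#' The closed-form frame count `floor((N - round(w*fs)) / round(s*fs)) + 1`
#' for an epoch of `N = 30 * fs` samples (0 when the epoch is shorter than
#' one frame).
#'
#' @param w,s Window and stride, seconds.
#' @param fs Sampling rate, Hz.
#' @param epoch_len_s Epoch length, seconds.
#' @return Integer frame count.
#' @export
frames_per_epoch <- function(w, s, fs, epoch_len_s = 30) {
  n <- as.integer(round(epoch_len_s * fs))
  flen <- as.integer(round(w * fs))
  hop <- as.integer(round(s * fs))
  ifelse(n >= flen, (n - flen) %/% hop + 1L, 0L)
}

#' Run a window/stride sweep
#'
#' For every grid pair (and repetition) this re-extracts features with that
#' framing, rebuilds streams, and reports the feature geometry; with
#' `train = TRUE` it also trains and evaluates the classifier on a
#' subject-wise split. Frames per epoch is reported as the
#' hardware-independent proxy for training cost, which scales with the
#' input volume.
#'
#' @param grid A [sweep_grid()].
#' @param dataset A [make_dataset()] result.
#' @param params Base [mfcc_params()] (its `w`/`s` are overridden per pair).
#' @param cfg A [stream_config()].
#' @param model_cfg A [model_config()]; its seed is offset per repetition.
#' @param train If `FALSE`, skip training and report geometry only.
#' @param split_seed Seed for the subject split.
#' @return Data frame: one row per (w, s, repetition) with stream height and
#'   width, frames per epoch, and (if trained) held-out accuracy.
#' @export
run_sweep <- function(grid, dataset, params = mfcc_params(),
                      cfg = stream_config(), model_cfg = model_config(),
                      train = TRUE, split_seed = 1) {
  stopifnot(inherits(grid, "sweep_grid"))
  fs <- max(vapply(dataset$recordings[[1]]$channels, `[[`, numeric(1), "fs"))
  rows <- list()
  for (r in seq_len(nrow(grid$pairs))) {
    w <- grid$pairs$w[r]; s <- grid$pairs$s[r]
    p <- params; p$w <- w; p$s <- s
    streams <- dataset_streams(dataset, p, cfg)
    d <- dim(streams[[1]]$tensor)
    fpe <- frames_per_epoch(w, s, fs)
    for (rep in seq_len(grid$repetitions)) {
      acc <- NA_real_
      if (train) {
        sp <- split_subjects(streams, seed = split_seed)
        mc <- model_cfg; mc$seed <- model_cfg$seed + rep - 1L
        model <- build_model(mc, d)
        model <- train_model(model, sp$train, sp$val)
        pred <- predict_stages(model, sp$test)
        truth <- vapply(sp$test, `[[`, character(1), "label")
        acc <- basic_metrics(confusion(truth, pred$labels))$accuracy
      }
      rows[[length(rows) + 1]] <- data.frame(
        w = w, s = s, repetition = rep, frames_per_epoch = fpe,
        stream_height = d[1], stream_width = d[2], accuracy = acc)
    }
  }
  do.call(rbind, rows)
}
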