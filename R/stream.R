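# Composition of per-channel MFCC maps into the 2-D multi-channel,
# multi-epoch input stream: channels stack along the coefficient (height)
# axis, context epochs concatenate along the frame (time) axis, and the
# stream carries its center epoch's stage label.

#' Stream composition configuration
#'
#' @param context_epochs Number of epochs per stream; odd, default 3 (the
#'   center epoch provides the label).
#' @param channel_order Channel labels in stacking order, or `NULL` to use
#'   the recording's order.
#' @param boundary `"replicate"` duplicates the first/last epoch to fill
#'   missing context (stream count then equals hypnogram length);
#'   `"drop"` omits boundary epochs.
#' @param normalize If `TRUE`, standardize each stream tensor to zero mean
#'   and unit variance. Off by default: the literal pipeline feeds raw
#'   cepstra to the model.
#' @return Object of class `stream_config`.
#' @export
stream_config <- function(context_epochs = 3, channel_order = NULL,
                          boundary = c("replicate", "drop"),
                          normalize = FALSE) {
  boundary <- match.arg(boundary)
  if (context_epochs < 1 || context_epochs %% 2 != 1) {
    stop("context_epochs must be odd and >= 1", call. = FALSE)
  }
  structure(list(context_epochs = context_epochs, channel_order = channel_order,
                 boundary = boundary, normalize = normalize),
            class = "stream_config")
}

#' Resample all channels of a recording to a common rate
#'
#' Polyphase FIR resampling (via the signal package). Channels already at
#' the target rate are returned sample-identical. Needed because EMG is
#' commonly archived at half the EEG rate; a shared rate gives every channel
#' the same frame grid before feature fusion.
#'
#' @param rec A [psg_recording()].
#' @param target_fs Target rate in Hz, or `NULL` for the maximum channel
#'   rate in `rec`.
#' @return A [psg_recording()] with every channel at `target_fs`.
#' @export
unify_rates <- function(rec, target_fs = NULL) {
  stopifnot(inherits(rec, "psg_recording"))
  if (is.null(target_fs)) {
    target_fs <- max(vapply(rec$channels, `[[`, numeric(1), "fs"))
  }
  stopifnot(target_fs > 0)
  channels <- lapply(rec$channels, function(ch) {
    if (abs(ch$fs - target_fs) < 1e-9) return(ch)
    ratio <- target_fs / ch$fs
    # smallest integer p/q for the rate ratio
    q <- 1L
    while (abs(ratio * q - round(ratio * q)) > 1e-9 && q < 10000L) q <- q + 1L
    p <- as.integer(round(ratio * q))
    y <- signal::resample(ch$samples, p, q)
    n_out <- as.integer(round(length(ch$samples) * ratio))
    if (length(y) < n_out) y <- c(y, rep(0, n_out - length(y)))
    list(label = ch$label, samples = y[seq_len(n_out)], fs = target_fs)
  })
  psg_recording(channels, subject_id = rec$subject_id)
}

#' Per-epoch, per-channel MFCC maps for a recording
#'
#' Unifies channel rates, cuts the recording into labelled 30-s epochs, and
#' extracts an MFCC map per channel within each epoch (framing restarts at
#' every epoch boundary, so no frame straddles two stages).
#'
#' @param rec A [psg_recording()].
#' @param hyp A [hypnogram()].
#' @param params An [mfcc_params()].
#' @param target_fs Common rate passed to [unify_rates()].
#' @return List over epochs; each element has `maps` (named list of
#'   `L x n_frames` coefficient matrices, channels in recording order),
#'   `stage` and `epoch_index`.
#' @export
epoch_features <- function(rec, hyp, params = mfcc_params(), target_fs = NULL) {
  rec <- unify_rates(rec, target_fs)
  eps <- segment_epochs(rec, hyp)
  fs <- rec$channels[[1]]$fs
  lapply(eps, function(ep) {
    maps <- lapply(ep$signals, function(x) t(extract_mfcc(x, fs, params)$coef))
    list(maps = maps, stage = ep$stage, epoch_index = ep$epoch_index)
  })
}

#' Assemble multi-epoch feature streams
#'
#' For epoch `k` with context 3, the stream stacks every channel's `L`
#' coefficient rows (height `L * n_channels`) and concatenates the frames of
#' epochs `k-1, k, k+1` (width `n_frames_per_epoch * context_epochs`); the
#' label is epoch `k`'s stage. Epochs with a masked (`NA`) stage yield no
#' stream but still serve as context.
#'
#' @param feats Result of [epoch_features()].
#' @param hyp The matching [hypnogram()] (supplies subject id).
#' @param cfg A [stream_config()].
#' @return List of `feature_stream` objects: `tensor`
#'   (height x width matrix), `label`, `subject_id`, `epoch_index`.
#' @export
build_streams <- function(feats, hyp, cfg = stream_config()) {
  stopifnot(inherits(cfg, "stream_config"), inherits(hyp, "hypnogram"))
  n <- length(feats)
  if (n == 0) return(list())
  ord <- cfg$channel_order
  if (is.null(ord)) ord <- names(feats[[1]]$maps)
  shapes <- unique(do.call(rbind, lapply(feats, function(f) {
    do.call(rbind, lapply(f$maps[ord], dim))
  })))
  if (nrow(shapes) != 1) {
    stop("inconsistent per-channel map shapes across epochs/channels: ",
         paste(apply(shapes, 1, paste, collapse = "x"), collapse = ", "),
         call. = FALSE)
  }
  stacked <- lapply(feats, function(f) do.call(rbind, f$maps[ord]))
  half <- (cfg$context_epochs - 1) %/% 2
  out <- list()
  for (k in seq_len(n)) {
    if (is.na(feats[[k]]$stage)) next
    ctx <- (k - half):(k + half)
    if (cfg$boundary == "drop" && (ctx[1] < 1 || ctx[length(ctx)] > n)) next
    ctx <- pmin(pmax(ctx, 1), n)  # replicate edges
    tensor <- do.call(cbind, stacked[ctx])
    if (cfg$normalize) {
      mu <- mean(tensor); sdv <- stats::sd(as.vector(tensor))
      tensor <- (tensor - mu) / if (sdv > 0) sdv else 1
    }
    out[[length(out) + 1]] <- structure(
      list(tensor = tensor, label = feats[[k]]$stage,
           subject_id = hyp$subject_id, epoch_index = feats[[k]]$epoch_index),
      class = "feature_stream")
  }
  out
}

#' @export
print.feature_stream <- function(x, ...) {
  cat("<feature_stream>", nrow(x$tensor), "x", ncol(x$tensor),
      " label", x$label, " subject", x$subject_id,
      " epoch", x$epoch_index, "\n")
  invisible(x)
}

#' Subject-wise train/validation/test split
#'
#' Splits at the subject level so no subject's epochs leak across
#' partitions. Subject counts follow the fractions by largest remainder
#' (ties favour train, then validation). Deterministic given the seed.
#'
#' @param streams List of `feature_stream` objects.
#' @param fractions Length-3 non-negative vector summing to 1
#'   (train, validation, test).
#' @param seed Integer seed for the subject shuffle.
#' @return List with `train`, `val`, `test` (stream lists) and `assignment`
#'   (data frame subject -> partition).
#' @export
split_subjects <- function(streams, fractions = c(0.7, 0.2, 0.1), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  subj <- vapply(streams, `[[`, character(1), "subject_id")
  ids <- sort(unique(subj))
  if (length(ids) < 3) {
    stop("need at least 3 subjects for a 3-way subject-wise split, got ",
         length(ids), call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  ids <- sample(ids)
  quota <- fractions * length(ids)
  n <- floor(quota)
  rem <- quota - n
  while (sum(n) < length(ids)) {
    pick <- which.max(rem)          # ties resolve to the earliest partition
    n[pick] <- n[pick] + 1
    rem[pick] <- -1
  }
  # every partition with a positive fraction gets at least one subject
  for (p in which(fractions > 0 & n == 0)) {
    donor <- which.max(n)
    n[donor] <- n[donor] - 1
    n[p] <- n[p] + 1
  }
  part <- rep(c("train", "val", "test"), times = n)
  assignment <- data.frame(subject_id = ids, partition = part)
  pick_streams <- function(p) {
    streams[subj %in% assignment$subject_id[assignment$partition == p]]
  }
  list(train = pick_streams("train"), val = pick_streams("val"),
       test = pick_streams("test"), assignment = assignment)
}

#' Streams for a whole dataset
#'
#' Convenience wrapper: [epoch_features()] then [build_streams()] for every
#' (recording, hypnogram) pair of a [make_dataset()] result.
#'
#' @param dataset List with `recordings` and `hypnograms`.
#' @param params An [mfcc_params()].
#' @param cfg A [stream_config()].
#' @return Flat list of `feature_stream` objects across all subjects.
#' @export
dataset_streams <- function(dataset, params = mfcc_params(),
                            cfg = stream_config()) {
  out <- mapply(function(rec, hyp) {
    build_streams(epoch_features(rec, hyp, params), hyp, cfg)
  }, dataset$recordings, dataset$hypnograms, SIMPLIFY = FALSE)
  do.call(c, out)
}
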