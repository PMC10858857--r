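# Hypnograms: per-30-s-epoch stage labels aligned to a recording.

#' Construct a hypnogram
#'
#' @param stages_vec Character vector of canonical stage labels (`NA` marks a
#'   masked epoch, e.g. an artifact code dropped by the stage map).
#' @param epoch_len_s Epoch length in seconds (scoring standard is 30).
#' @param subject_id Subject identifier.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages_vec, epoch_len_s = 30, subject_id = "anon") {
  ok <- is.na(stages_vec) | stages_vec %in% stages()
  if (!all(ok)) {
    stop("non-canonical stage label(s): ",
         paste(unique(stages_vec[!ok]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(stages = as.character(stages_vec), epoch_len_s = epoch_len_s,
         subject_id = subject_id),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> subject", x$subject_id, "-", length(x$stages), "epochs of",
      x$epoch_len_s, "s\n")
  print(table(factor(x$stages, levels = stages()), useNA = "ifany"))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Read a hypnogram file
#'
#' Two dialects are supported: plain text with one stage label per line, and
#' CSV with `onset`, `duration` and `stage` columns (seconds; rows are
#' expanded into consecutive epochs). Raw labels go through `stage_map`;
#' under the default drop policy, unknown labels (movement/artifact codes)
#' become masked (`NA`) epochs.
#'
#' @param path File path.
#' @param sm A [stage_map()].
#' @param epoch_len_s Epoch length in seconds.
#' @param subject_id Subject identifier attached to the result.
#' @param format `"auto"` (detect CSV by header), `"lines"` or `"csv"`.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, sm = stage_map(), epoch_len_s = 30,
                           subject_id = "anon", format = c("auto", "lines", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("hypnogram file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty hypnogram file: ", path, call. = FALSE)
    return(hypnogram(character(0), epoch_len_s, subject_id))
  }
  if (format == "auto") {
    format <- if (grepl("onset", lines[1], ignore.case = TRUE)) "csv" else "lines"
  }
  if (format == "lines") {
    raw <- trimws(lines)
  } else {
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("onset", "duration", "stage")
    if (!all(need %in% names(df))) {
      stop("CSV hypnogram needs onset/duration/stage columns, got: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
    n_total <- round((max(df$onset + df$duration)) / epoch_len_s)
    raw <- rep(NA_character_, n_total)
    for (r in seq_len(nrow(df))) {
      k0 <- round(df$onset[r] / epoch_len_s)
      nk <- round(df$duration[r] / epoch_len_s)
      if (nk > 0) raw[(k0 + 1):(k0 + nk)] <- as.character(df$stage[r])
    }
  }
  hypnogram(map_stages(raw, sm), epoch_len_s, subject_id)
}

#' Write a hypnogram as one label per line
#'
#' Masked epochs are written as `"?"` (which the default stage map does not
#' recognize, so they stay masked on re-read under the drop policy).
#'
#' @param hyp A [hypnogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  out <- hyp$stages
  out[is.na(out)] <- "?"
  writeLines(out, path)
  invisible(path)
}

#' Cut a recording into labelled 30-s epochs
#'
#' Epoch `k` holds samples `[k*epoch_len*fs, (k+1)*epoch_len*fs)` of every
#' channel. A trailing partial epoch is dropped, never padded. The recording
#' and hypnogram must cover the same span within one epoch.
#'
#' @param rec A [psg_recording()].
#' @param hyp A [hypnogram()].
#' @return List of epochs; each has `signals` (named list of per-channel
#'   sample vectors), `stage` (canonical label or `NA`) and `epoch_index`
#'   (1-based).
#' @export
segment_epochs <- function(rec, hyp) {
  stopifnot(inherits(rec, "psg_recording"), inherits(hyp, "hypnogram"))
  el <- hyp$epoch_len_s
  n_rec_ep <- floor(rec$duration_s / el)
  n_hyp_ep <- length(hyp$stages)
  if (abs(n_rec_ep - n_hyp_ep) > 1) {
    stop("recording covers ", n_rec_ep, " epochs but hypnogram has ", n_hyp_ep,
         "; misalignment exceeds one epoch", call. = FALSE)
  }
  n <- min(n_rec_ep, n_hyp_ep)
  labs <- channel_labels(rec)
  lapply(seq_len(n), function(k) {
    sig <- lapply(rec$channels, function(ch) {
      spe <- as.integer(round(ch$fs * el))
      ch$samples[((k - 1) * spe + 1):(k * spe)]
    })
    names(sig) <- labs
    list(signals = sig, stage = hyp$stages[k], epoch_index = k)
  })
}
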