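# European Data Format (EDF), 16-bit standard flavour.
# Header: 256-byte fixed block + 256 bytes per signal; samples are stored as
# little-endian int16, record-interleaved, scaled between the declared
# physical and digital ranges.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'", call. = FALSE)
  formatC(x, width = width, flag = "-")
}

# Format a number into at most `width` ASCII chars, keeping as much
# precision as fits.
edf_num <- function(x, width) {
  for (d in seq(10, 1)) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("cannot format ", x, " in ", width, " chars", call. = FALSE)
}

#' Construct a PSG recording object
#'
#' @param channels List of channels, each a list with fields `label`
#'   (character), `samples` (numeric vector) and `fs` (sampling rate, Hz).
#' @param subject_id Subject identifier.
#' @return An object of class `psg_recording` with fields `channels`,
#'   `duration_s` and `subject_id`.
#' @export
psg_recording <- function(channels, subject_id = "anon") {
  stopifnot(is.list(channels), length(channels) >= 1)
  dur <- vapply(channels, function(ch) {
    stopifnot(is.character(ch$label), is.numeric(ch$samples), ch$fs > 0)
    length(ch$samples) / ch$fs
  }, numeric(1))
  # channels may disagree by under one sample at the slowest rate
  if (diff(range(dur)) > 1 / min(vapply(channels, `[[`, numeric(1), "fs"))) {
    stop("channel durations disagree by more than one sample: ",
         paste(signif(dur, 6), collapse = ", "), call. = FALSE)
  }
  structure(
    list(channels = channels, duration_s = min(dur), subject_id = subject_id),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> subject", x$subject_id, "-",
      sprintf("%.0f s\n", x$duration_s))
  for (ch in x$channels) {
    cat(sprintf("  %-10s %6g Hz  %d samples\n", ch$label, ch$fs,
                length(ch$samples)))
  }
  invisible(x)
}

channel_labels <- function(rec) vapply(rec$channels, `[[`, character(1), "label")

#' Write a recording to an EDF file
#'
#' Standard 16-bit EDF with one-second data records; every channel therefore
#' needs an integer sampling rate. The physical range is set symmetrically
#' from the channel's absolute maximum, so the round-trip error is bounded by
#' `range / 65535` per sample. A trailing partial second is dropped.
#'
#' @param rec A [psg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- vapply(rec$channels, `[[`, numeric(1), "fs")
  if (any(abs(fs - round(fs)) > 1e-9)) {
    stop("EDF writer uses 1-s records; channel rates must be integer Hz",
         call. = FALSE)
  }
  fs <- as.integer(round(fs))
  ns <- length(rec$channels)
  n_rec <- floor(min(vapply(rec$channels, function(ch) length(ch$samples),
                            numeric(1)) / fs))
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)", call. = FALSE)

  dig_min <- -32768L; dig_max <- 32767L
  phys_max <- vapply(rec$channels, function(ch) {
    m <- max(abs(ch$samples), na.rm = TRUE)
    if (!is.finite(m) || m == 0) 1 else m
  }, numeric(1))
  phys_min <- -phys_max

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad("mfccsleep recording", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  for (ch in rec$channels) wr(edf_pad(ch$label, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))            # transducer
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))           # physical dimension
  for (i in seq_len(ns)) wr(edf_num(phys_min[i], 8))
  for (i in seq_len(ns)) wr(edf_num(phys_max[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_min, 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))            # prefiltering
  for (i in seq_len(ns)) wr(edf_pad(fs[i], 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]$samples[seq_len(n_rec * fs[i])]
    d <- as.integer(round((x - phys_min[i]) / scale[i]) + dig_min)
    dig[[i]] <- pmin(pmax(d, dig_min), dig_max)
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs[i] + 1):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read selected channels from an EDF file
#'
#' Channel name matching is case-insensitive and ignores separators, so
#' `"C4A1"` resolves a channel stored as `"C4-A1"`. Native per-channel
#' sampling rates and physical units are preserved; rate unification is done
#' later by [unify_rates()].
#'
#' @param path EDF file path.
#' @param wanted_channels Character vector of channel labels to load, or
#'   `NULL` for all channels.
#' @return A [psg_recording()].
#' @export
read_edf <- function(path, wanted_channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) stop("corrupt EDF header (truncated): ", path, call. = FALSE)
    trimws(rawToChar(raw))
  }
  rd(8)                                   # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1 || rec_dur <= 0) {
    stop("corrupt EDF header: ", path, call. = FALSE)
  }
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  sel <- seq_len(ns)
  if (!is.null(wanted_channels)) {
    have <- normalize_label(labels)
    sel <- vapply(unname(wanted_channels), function(wc) {
      hit <- which(have == normalize_label(wc))
      if (length(hit) == 0) {
        stop("channel '", wc, "' not found; available: ",
             paste(labels, collapse = ", "), call. = FALSE)
      }
      hit[1]
    }, integer(1), USE.NAMES = FALSE)
  }

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr)) {
    stop("corrupt EDF data section (truncated): ", path, call. = FALSE)
  }
  offs <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  channels <- lapply(sel, function(i) {
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]),
                           (0:(n_rec - 1)) * per_rec, `+`))
    d <- raw[idx]
    g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    list(label = labels[i],
         samples = phys_min[i] + (d - dig_min[i]) * g,
         fs = spr[i] / rec_dur)
  })
  psg_recording(channels, subject_id = if (nzchar(patient)) patient else "anon")
}
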