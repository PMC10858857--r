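# Synthetic polysomnography with stage-dependent spectral structure.
# Emulates the discriminable electrophysiology of the five stages (alpha in
# wake, theta in S1, spindle bursts in S2, high-amplitude delta in S3,
# theta with atonia in REM) without attempting realistic waveform
# morphology.

#' Stage-dependent spectrum specification
#'
#' Per stage: oscillatory EEG components (center frequency, bandwidth used
#' as amplitude-modulation rate, relative amplitude), an EMG tone level that
#' scales the EMG channel, and a broadband Gaussian noise level per channel
#' role. Defaults: Wake = 10 Hz alpha with the highest EMG tone; S1 = 5 Hz
#' theta, medium tone; S2 = 13 Hz amplitude-modulated spindle bursts over
#' low theta; S3 = 1 Hz high-amplitude delta; REM = mixed theta with the
#' lowest EMG tone (atonia).
#'
#' @param components Named list (one entry per stage) of data frames with
#'   columns `freq`, `bw`, `amp` describing EEG oscillations.
#' @param emg_tone Named numeric vector: EMG amplitude multiplier per stage.
#' @param eeg_noise,emg_noise Broadband noise standard deviations.
#' @return Object of class `stage_spectrum_spec`.
#' @export
stage_spectrum_spec <- function(components = NULL, emg_tone = NULL,
                                eeg_noise = 0.25, emg_noise = 1) {
  if (is.null(components)) {
    components <- list(
      W   = data.frame(freq = 10, bw = 0,   amp = 1.0),
      S1  = data.frame(freq = 5,  bw = 0,   amp = 0.9),
      S2  = data.frame(freq = c(13, 5), bw = c(0.5, 0), amp = c(1.2, 0.4)),
      S3  = data.frame(freq = 1,  bw = 0,   amp = 2.5),
      REM = data.frame(freq = c(5, 2), bw = c(0, 0), amp = c(0.7, 0.5))
    )
  }
  if (is.null(emg_tone)) {
    emg_tone <- c(W = 1.0, S1 = 0.6, S2 = 0.5, S3 = 0.4, REM = 0.2)
  }
  stopifnot(setequal(names(components), stages()),
            setequal(names(emg_tone), stages()),
            eeg_noise >= 0, emg_noise >= 0)
  for (st in stages()) {
    cmp <- components[[st]]
    stopifnot(all(c("freq", "bw", "amp") %in% names(cmp)), all(cmp$amp > 0),
              all(cmp$freq > 0))
  }
  structure(list(components = components, emg_tone = emg_tone,
                 eeg_noise = eeg_noise, emg_noise = emg_noise),
            class = "stage_spectrum_spec")
}

#' Per-epoch stage transition model
#'
#' A first-order Markov chain over the five stages at 30-s resolution. The
#' default matrix keeps mean dwell times of about 4-6 epochs with a bias
#' toward S2 (the dominant stage of real nights): every stage stays with
#' probability 0.75-0.80 and transitions route preferentially through S2.
#'
#' @param P 5x5 row-stochastic transition matrix (rows/cols in stage order),
#'   or `NULL` for the default.
#' @param init Initial stage distribution, or `NULL` for the default
#'   (start mostly awake).
#' @return Object of class `transition_model`.
#' @export
transition_model <- function(P = NULL, init = NULL) {
  if (is.null(P)) {
    P <- rbind(
      W   = c(0.75, 0.13, 0.08, 0.02, 0.02),
      S1  = c(0.05, 0.72, 0.17, 0.03, 0.03),
      S2  = c(0.02, 0.04, 0.80, 0.08, 0.06),
      S3  = c(0.02, 0.02, 0.16, 0.78, 0.02),
      REM = c(0.05, 0.05, 0.12, 0.02, 0.76)
    )
    colnames(P) <- stages()
  }
  if (is.null(init)) init <- c(W = 0.6, S1 = 0.2, S2 = 0.1, S3 = 0.05, REM = 0.05)
  P <- as.matrix(P)
  stopifnot(nrow(P) == 5, ncol(P) == 5, all(P >= 0), length(init) == 5,
            all(init >= 0))
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  if (abs(sum(init) - 1) > 1e-9) stop("init must sum to 1", call. = FALSE)
  dimnames(P) <- list(stages(), stages())
  structure(list(P = P, init = stats::setNames(init, stages())),
            class = "transition_model")
}

#' Sample a hypnogram from a transition model
#'
#' @param tm A [transition_model()].
#' @param n_epochs Number of 30-s epochs, at least 1.
#' @param seed Integer seed; the sequence is fully determined by it.
#' @param subject_id Subject identifier.
#' @return A [hypnogram()].
#' @export
sample_hypnogram <- function(tm, n_epochs, seed = 1, subject_id = "anon") {
  stopifnot(inherits(tm, "transition_model"), n_epochs >= 1)
  st <- integer(n_epochs)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  st[1] <- sample.int(5, 1, prob = tm$init)
  for (k in seq_len(n_epochs - 1)) {
    st[k + 1] <- sample.int(5, 1, prob = tm$P[st[k], ])
  }
  hypnogram(stages()[st], 30, subject_id)
}

# Run code under a private RNG stream; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

synth_epoch_channel <- function(stage, role, fs, epoch_len_s, spec) {
  n <- as.integer(round(fs * epoch_len_s))
  t <- (0:(n - 1)) / fs
  if (role == "emg") {
    # broadband muscle activity whose amplitude tracks stage tone
    return(spec$emg_tone[[stage]] * stats::rnorm(n, sd = spec$emg_noise))
  }
  x <- stats::rnorm(n, sd = spec$eeg_noise)
  cmp <- spec$components[[stage]]
  for (i in seq_len(nrow(cmp))) {
    if (cmp$freq[i] >= fs / 2) {
      stop("component at ", cmp$freq[i], " Hz is at/above Nyquist for fs ",
           fs, call. = FALSE)
    }
    phase <- stats::runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * cmp$freq[i] * t + phase)
    env <- if (cmp$bw[i] > 0) {
      # raised-cosine amplitude modulation -> burst structure (spindles)
      0.5 * (1 + sin(2 * pi * cmp$bw[i] * t + stats::runif(1, 0, 2 * pi)))
    } else 1
    x <- x + cmp$amp[i] * env * carrier
  }
  x
}

#' Synthesize a multi-channel recording for a hypnogram
#'
#' Each 30-s epoch is the sum of the stage's oscillatory components (random
#' phases per epoch) plus broadband Gaussian noise; the EMG channel is
#' broadband noise scaled by the stage's tone level. Signals are not
#' continuous at epoch joins, matching the discontinuity of staged data.
#'
#' @param hyp A [hypnogram()]; masked (`NA`) epochs get Wake-like filler.
#' @param spec A [stage_spectrum_spec()].
#' @param rates Named numeric vector of channel sampling rates; names are
#'   channel labels, and labels containing "EMG" take the EMG role.
#' @param seed Integer seed.
#' @return A [psg_recording()].
#' @export
synth_recording <- function(hyp, spec = stage_spectrum_spec(),
                            rates = c(C3A2 = 128, C4A1 = 128, EMG = 64),
                            seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(spec, "stage_spectrum_spec"))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  channels <- lapply(seq_along(rates), function(i) {
    role <- if (grepl("EMG", toupper(names(rates)[i]))) "emg" else "eeg"
    eps <- lapply(hyp$stages, function(st) {
      if (is.na(st)) st <- "W"
      synth_epoch_channel(st, role, rates[[i]], hyp$epoch_len_s, spec)
    })
    list(label = names(rates)[i], samples = unlist(eps), fs = rates[[i]])
  })
  psg_recording(channels, subject_id = hyp$subject_id)
}

#' UCDDB-like and SHHS-like channel-rate presets
#'
#' `"ucddb"`: EEG at 128 Hz, EMG at 64 Hz (heterogeneous rates exercise the
#' resampling path). `"shhs"`: all channels at 125 Hz.
#'
#' @param preset `"ucddb"` or `"shhs"`.
#' @return Named numeric vector of channel rates.
#' @export
rate_preset <- function(preset = c("ucddb", "shhs")) {
  preset <- match.arg(preset)
  switch(preset,
         ucddb = c(C3A2 = 128, C4A1 = 128, EMG = 64),
         shhs = c(C3A2 = 125, C4A1 = 125, EMG = 125))
}

#' Generate a synthetic multi-subject dataset
#'
#' Per-subject seeds are derived from the master seed, so the whole dataset
#' is reproducible from one integer. Optionally writes one EDF and one
#' plain-text hypnogram per subject (round-trippable through [read_edf()]
#' and [read_hypnogram()]) plus a `manifest.csv`.
#'
#' @param n_subjects Number of subjects, at least 1.
#' @param epochs_per_subject Number of 30-s epochs per subject.
#' @param spec A [stage_spectrum_spec()].
#' @param tm A [transition_model()].
#' @param rates Channel rates (see [synth_recording()]).
#' @param seed Master seed.
#' @param dir Output directory for fixture files, or `NULL` to skip writing.
#' @return List with `recordings`, `hypnograms` (parallel lists) and
#'   `manifest` (data frame; has `edf`/`hypnogram` paths when `dir` is set).
#' @export
make_dataset <- function(n_subjects, epochs_per_subject,
                         spec = stage_spectrum_spec(),
                         tm = transition_model(),
                         rates = rate_preset("ucddb"),
                         seed = 1, dir = NULL) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1)
  ids <- sprintf("subj%02d", seq_len(n_subjects))
  recs <- vector("list", n_subjects)
  hyps <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    hseed <- (seed * 1000L + 2L * i) %% .Machine$integer.max
    rseed <- (seed * 1000L + 2L * i + 1L) %% .Machine$integer.max
    hyps[[i]] <- sample_hypnogram(tm, epochs_per_subject, seed = hseed,
                                  subject_id = ids[i])
    recs[[i]] <- synth_recording(hyps[[i]], spec, rates, seed = rseed)
    rows[[i]] <- data.frame(subject_id = ids[i],
                            n_epochs = epochs_per_subject,
                            duration_s = epochs_per_subject * 30)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      edf_path <- file.path(dir, paste0(ids[i], ".edf"))
      hyp_path <- file.path(dir, paste0(ids[i], "_hypnogram.txt"))
      write_edf(recs[[i]], edf_path)
      write_hypnogram(hyps[[i]], hyp_path)
      rows[[i]]$edf <- edf_path
      rows[[i]]$hypnogram <- hyp_path
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(recordings = recs, hypnograms = hyps, manifest = manifest)
}
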