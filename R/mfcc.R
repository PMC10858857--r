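# MFCC chain: pre-emphasis -> framing -> Hamming window -> FFT power
# spectrum -> Mel filter-bank log energies -> DCT cepstrum.

next_pow2 <- function(n) 2^ceiling(log2(n))

#' MFCC extraction parameters
#'
#' Defaults follow the staging pipeline: 0.97 pre-emphasis, 0.5-s frames with
#' 0.25-s stride, a 40-filter Mel bank over the full band, and the first 13
#' cepstral coefficients (the conventional pick inside the 12-20 range).
#'
#' `nfft = NULL` resolves, once the sampling rate is known, to the next power
#' of two at or above `max(frame_len, 2 * (M + 1))`: the second term
#' guarantees the integer-bin triangle bank has at least `M + 2` distinct
#' edges, which a bare frame-length FFT (33 bins at these rates) cannot host
#' for `M = 40`.
#'
#' @param a Pre-emphasis coefficient in `[0, 1)`.
#' @param w Frame length, seconds.
#' @param s Frame stride, seconds, `0 < s <= w`.
#' @param M Number of triangular Mel filters.
#' @param L Number of cepstral coefficients kept, `1 <= L <= M`.
#' @param nfft FFT length in samples, or `NULL` for the rule above.
#' @param fmin,fmax Filter-bank band edges, Hz; `fmax = NULL` means the
#'   Nyquist frequency.
#' @param floor_eps Floor added inside the log of the filter energies.
#' @return An object of class `mfcc_params`.
#' @export
mfcc_params <- function(a = 0.97, w = 0.5, s = 0.25, M = 40, L = 13,
                        nfft = NULL, fmin = 0, fmax = NULL, floor_eps = 1e-10) {
  stopifnot(a >= 0, a < 1, s > 0, s <= w, M >= 2, L >= 1, L <= M,
            fmin >= 0, floor_eps > 0)
  if (!is.null(fmax) && fmax <= fmin) stop("fmax must exceed fmin", call. = FALSE)
  structure(list(a = a, w = w, s = s, M = M, L = L, nfft = nfft,
                 fmin = fmin, fmax = fmax, floor_eps = floor_eps),
            class = "mfcc_params")
}

resolve_nfft <- function(p, frame_len) {
  if (!is.null(p$nfft)) {
    if (p$nfft < frame_len) {
      stop("nfft (", p$nfft, ") smaller than frame length (", frame_len, ")",
           call. = FALSE)
    }
    return(as.integer(p$nfft))
  }
  as.integer(next_pow2(max(frame_len, 2 * (p$M + 1))))
}

#' Hertz to Mel
#'
#' `mel = 2595 * log10(1 + f / 700)`; strictly increasing on `f >= 0`.
#'
#' @param f Frequency in Hz, non-negative.
#' @return Pitch in Mels.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' Mel to Hertz (inverse of [hz_to_mel()])
#'
#' @param mel Pitch in Mels, non-negative.
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(mel) {
  if (any(mel < 0)) stop("mel must be non-negative", call. = FALSE)
  700 * (10^(mel / 2595) - 1)
}

#' First-order pre-emphasis filter
#'
#' `y(n) = x(n) - a * x(n-1)` with `y(1) = x(1)` (identity at the boundary).
#' Boosts high-frequency content before spectral analysis.
#'
#' @param x Sample vector, non-empty.
#' @param a Pre-emphasis coefficient.
#' @return Filtered vector, same length as `x`.
#' @export
pre_emphasis <- function(x, a = 0.97) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  c(x[1], x[-1] - a * x[-length(x)])
}

#' Slice a signal into overlapping fixed-length frames
#'
#' Frame length is `round(w * fs)` samples and the hop `round(s * fs)`;
#' frame `k` (0-based) starts at sample `k * hop`, and frames that would
#' overrun the signal end are not emitted. A signal shorter than one frame
#' yields zero frames (flagged via the `"empty"` attribute, not an error).
#'
#' @param x Sample vector.
#' @param fs Sampling rate, Hz.
#' @param w Frame length, seconds.
#' @param s Frame stride, seconds.
#' @return Object of class `frame_matrix`: an `n_frames x frame_len` matrix
#'   with attributes `fs`, `frame_len`, `hop` and `starts` (0-based).
#' @export
frame_signal <- function(x, fs, w, s) {
  frame_len <- as.integer(round(w * fs))
  hop <- as.integer(round(s * fs))
  if (frame_len < 1 || hop < 1) {
    stop("w*fs and s*fs must round to positive integers", call. = FALSE)
  }
  n <- length(x)
  nf <- if (n >= frame_len) (n - frame_len) %/% hop + 1L else 0L
  if (nf == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = frame_len)
  } else {
    starts <- (seq_len(nf) - 1L) * hop
    m <- matrix(x[outer(starts, seq_len(frame_len), `+`)],
                nrow = nf, ncol = frame_len)
  }
  structure(m, fs = fs, frame_len = frame_len, hop = hop,
            starts = if (nf) (seq_len(nf) - 1L) * hop else integer(0),
            empty = nf == 0L, class = c("frame_matrix", "matrix"))
}

#' Hamming window weights
#'
#' `w(n) = 0.54 - 0.46 * cos(2 pi n / (T - 1))`, `n = 0..T-1`: symmetric,
#' endpoints 0.08, center 1 for odd `T`.
#'
#' @param T_len Window length in samples, at least 2.
#' @return Numeric weight vector of length `T_len`.
#' @export
hamming_window <- function(T_len) {
  if (T_len < 2) stop("window length must be >= 2", call. = FALSE)
  n <- 0:(T_len - 1)
  0.54 - 0.46 * cos(2 * pi * n / (T_len - 1))
}

#' Power spectrum of windowed frames
#'
#' Zero-pads each (already windowed) frame to `nfft` samples and returns
#' `|X(k)|^2` for the one-sided bins `k = 0..nfft/2`.
#'
#' @param frames Numeric matrix, `n_frames x frame_len` (e.g. a
#'   [frame_signal()] result with the window applied).
#' @param nfft FFT length; positive even integer, at least the frame length.
#' @return Non-negative matrix, `n_frames x (nfft/2 + 1)`.
#' @export
power_spectrum <- function(frames, nfft) {
  if (length(nfft) != 1 || nfft < 2 || nfft %% 2 != 0) {
    stop("nfft must be a positive even integer", call. = FALSE)
  }
  if (ncol(frames) > nfft) stop("nfft smaller than frame length", call. = FALSE)
  nf <- nrow(frames)
  if (nf == 0) return(matrix(numeric(0), 0, nfft / 2 + 1))
  padded <- matrix(0, nrow = nfft, ncol = nf)
  padded[seq_len(ncol(frames)), ] <- t(frames)
  X <- stats::mvfft(padded)
  t(Mod(X[seq_len(nfft / 2 + 1), , drop = FALSE])^2)
}

#' Triangular Mel filter bank
#'
#' `M` triangles with Mel-uniform edge frequencies between `fmin` and `fmax`,
#' snapped to FFT bin indices: filter `m` rises linearly from edge bin
#' `f(m-1)` to 1 at its center bin `f(m)` and falls to 0 at `f(m+1)`.
#' Adjacent triangles share edges, so interior spectrum bins sum to exactly 1
#' across the bank.
#'
#' @param M Number of filters.
#' @param nfft FFT length.
#' @param fs Sampling rate, Hz.
#' @param fmin,fmax Band edges, Hz (`fmax <= fs/2`).
#' @return Matrix `M x (nfft/2 + 1)`; row maxima are 1 at the center bins.
#' @export
mel_filterbank <- function(M, nfft, fs, fmin = 0, fmax = fs / 2) {
  stopifnot(M >= 2, fmin >= 0, fmax > fmin, fmax <= fs / 2 + 1e-9)
  edges_hz <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = M + 2))
  bins <- floor((nfft + 1) * edges_hz / fs)
  if (any(diff(bins) < 1)) {
    stop("band [", fmin, ", ", fmax, "] Hz too narrow for ", M,
         " filters at nfft ", nfft, " (duplicate bin edges)", call. = FALSE)
  }
  n_bins <- nfft / 2 + 1
  H <- matrix(0, nrow = M, ncol = n_bins)
  k <- 0:(nfft / 2)
  for (m in seq_len(M)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    rise <- k >= lo & k < ce
    fall <- k > ce & k <= hi
    H[m, rise] <- (k[rise] - lo) / (ce - lo)
    H[m, k == ce] <- 1
    H[m, fall] <- (hi - k[fall]) / (hi - ce)
  }
  structure(H, centers = bins[2:(M + 1)], edges = bins)
}

#' Log energies of the filter-bank outputs
#'
#' `s(m) = ln(sum_k |X(k)|^2 H_m(k) + eps)`; the floor keeps silent frames
#' finite at `ln(eps)`.
#'
#' @param power Power-spectrum matrix, `n_frames x n_bins`.
#' @param H Filter bank from [mel_filterbank()], `M x n_bins`.
#' @param floor_eps Floor inside the log.
#' @return Matrix `n_frames x M`.
#' @export
log_energies <- function(power, H, floor_eps = 1e-10) {
  if (ncol(power) != ncol(H)) {
    stop("spectrum has ", ncol(power), " bins but filter bank expects ",
         ncol(H), call. = FALSE)
  }
  log(power %*% t(H) + floor_eps)
}

#' DCT cepstrum of the log energies
#'
#' `C(n) = sum_{m=1..M} s(m) * cos(pi * n * (m - 0.5) / M)` for
#' `n = 1..L` (DCT-II over the half-integer grid; the zeroth coefficient,
#' overall log energy, is excluded).
#'
#' @param s Log-energy matrix (`n_frames x M`) or a single length-`M` row.
#' @param L Number of coefficients to keep, `1 <= L <= M`.
#' @return Matrix `n_frames x L` (or a length-`L` vector for vector input).
#' @export
dct_cepstrum <- function(s, L) {
  vec_in <- is.null(dim(s))
  if (vec_in) s <- matrix(s, nrow = 1)
  M <- ncol(s)
  if (L > M) stop("L (", L, ") exceeds filter count M (", M, ")", call. = FALSE)
  m <- seq_len(M)
  D <- vapply(seq_len(L), function(n) cos(pi * n * (m - 0.5) / M), numeric(M))
  out <- s %*% D
  if (vec_in) drop(out) else out
}

#' Extract an MFCC map from a signal
#'
#' Runs the full chain: pre-emphasis, framing, Hamming windowing, FFT power
#' spectrum, Mel filter-bank log energies, DCT cepstrum. Deterministic.
#'
#' @param x Sample vector spanning at least one frame.
#' @param fs Sampling rate, Hz.
#' @param p An [mfcc_params()].
#' @return Object of class `mfcc_map`: list with `coef`
#'   (`n_frames x L` matrix), `frame_times` (frame centers, s), `fs` and
#'   `params` (with `nfft`/`fmax` resolved).
#' @export
extract_mfcc <- function(x, fs, p = mfcc_params()) {
  stopifnot(inherits(p, "mfcc_params"))
  frame_len <- as.integer(round(p$w * fs))
  if (length(x) < frame_len) {
    stop("signal (", length(x), " samples) spans less than one frame (",
         frame_len, " samples)", call. = FALSE)
  }
  nfft <- resolve_nfft(p, frame_len)
  fmax <- if (is.null(p$fmax)) fs / 2 else p$fmax
  y <- pre_emphasis(x, p$a)
  fr <- frame_signal(y, fs, p$w, p$s)
  win <- sweep(unclass(fr), 2, hamming_window(attr(fr, "frame_len")), `*`)
  ps <- power_spectrum(win, nfft)
  H <- mel_filterbank(p$M, nfft, fs, p$fmin, fmax)
  S <- log_energies(ps, H, p$floor_eps)
  C <- dct_cepstrum(S, p$L)
  p_res <- p; p_res$nfft <- nfft; p_res$fmax <- fmax
  structure(
    list(coef = C,
         frame_times = (attr(fr, "starts") + attr(fr, "frame_len") / 2) / fs,
         fs = fs, params = p_res),
    class = "mfcc_map"
  )
}

#' @export
print.mfcc_map <- function(x, ...) {
  cat("<mfcc_map>", nrow(x$coef), "frames x", ncol(x$coef),
      "coefficients at fs", x$fs, "Hz\n")
  invisible(x)
}
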