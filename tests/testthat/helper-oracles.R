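# Independent oracles used by the tests. Everything here is written as
# direct, literal evaluation (explicit loops, O(N^2) DFT sums, the
# five-case triangle formula) so it shares no code path with the package.

# Brute-force framing: enumerate every start index that fits.
oracle_frame_count <- function(n, fs, w, s) {
  flen <- as.integer(round(w * fs))
  hop <- as.integer(round(s * fs))
  count <- 0L
  k <- 0L
  repeat {
    if (k * hop + flen > n) break
    count <- count + 1L
    k <- k + 1L
  }
  count
}

# Direct DFT of one real frame: X(k) = sum_n x(n) exp(-2*pi*i*k*n/N).
oracle_dft_power <- function(x, nfft) {
  xp <- c(x, rep(0, nfft - length(x)))
  n <- 0:(nfft - 1)
  vapply(0:(nfft / 2), function(k) {
    Mod(sum(xp * exp(-2i * pi * k * n / nfft)))^2
  }, numeric(1))
}

# Literal five-case triangle response on integer bin edges.
oracle_filterbank <- function(M, nfft, fs, fmin, fmax) {
  m2h <- function(m) 700 * (10^(m / 2595) - 1)
  h2m <- function(f) 2595 * log10(1 + f / 700)
  edges <- floor((nfft + 1) * m2h(seq(h2m(fmin), h2m(fmax),
                                      length.out = M + 2)) / fs)
  H <- matrix(0, M, nfft / 2 + 1)
  for (m in 1:M) {
    fl <- edges[m]; fc <- edges[m + 1]; fh <- edges[m + 2]
    for (k in 0:(nfft / 2)) {
      H[m, k + 1] <-
        if (k < fl) 0
        else if (k < fc) (k - fl) / (fc - fl)
        else if (k == fc) 1
        else if (k <= fh) (fh - k) / (fh - fc)
        else 0
    }
  }
  H
}

# Full MFCC chain by direct summation; mirrors the published six steps
# with explicit loops.
oracle_mfcc <- function(x, fs, a = 0.97, w = 0.5, s = 0.25, M = 40, L = 13,
                        nfft = NULL, fmin = 0, fmax = fs / 2,
                        floor_eps = 1e-10) {
  y <- numeric(length(x))
  y[1] <- x[1]
  for (n in 2:length(x)) y[n] <- x[n] - a * x[n - 1]
  flen <- as.integer(round(w * fs))
  hop <- as.integer(round(s * fs))
  if (is.null(nfft)) nfft <- 2^ceiling(log2(max(flen, 2 * (M + 1))))
  nf <- oracle_frame_count(length(x), fs, w, s)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  H <- oracle_filterbank(M, nfft, fs, fmin, fmax)
  C <- matrix(0, nf, L)
  for (k in seq_len(nf)) {
    frame <- y[((k - 1) * hop + 1):((k - 1) * hop + flen)] * win
    p <- oracle_dft_power(frame, nfft)
    sm <- numeric(M)
    for (m in 1:M) sm[m] <- log(sum(p * H[m, ]) + floor_eps)
    for (n in 1:L) {
      C[k, n] <- sum(sm * cos(pi * n * ((1:M) - 0.5) / M))
    }
  }
  C
}

# Hand-built 2-unit peephole LSTM fixture. The expected state was computed
# by literal step-by-step arithmetic of the gate equations (sigmoid input
# and forget gates peeking at C_prev, output gate at the new C) before the
# kernel was written, and is frozen here.
lstm_fixture <- function() {
  list(
    x = 0.5,
    h_prev = c(0.1, -0.2),
    C_prev = c(0.3, -0.1),
    wts = list(
      Wxi = matrix(c(0.5, -0.25), 2, 1),
      Whi = matrix(c(0.1, -0.1, 0.2, 0.3), 2, 2),
      wci = c(0.25, -0.5),
      bi = c(0.1, -0.1),
      Wxf = matrix(c(0.3, 0.2), 2, 1),
      Whf = matrix(c(0.2, 0.1, -0.1, 0.1), 2, 2),
      wcf = c(0.5, 0.25),
      bf = c(0.2, 0.1),
      Wxo = matrix(c(-0.5, 0.5), 2, 1),
      Who = matrix(c(0.3, -0.2, 0.1, 0.2), 2, 2),
      wco = c(0.5, -0.25),
      bo = c(0.0, 0.2),
      Wxc = matrix(c(1.0, -0.5), 2, 1),
      Whc = matrix(c(0.2, 0.1, 0.2, -0.3), 2, 2),
      bc = c(0.1, 0.0)
    ),
    expected_C = c(0.501828879847970, -0.132302882172061),
    expected_h = c(0.233041975968662, -0.079476734807265)
  )
}

# Small labelled synthetic dataset shared by slower tests (built once per
# test run).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(4, 30, seed = 424)
    }
    cache
  }
})
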