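test_that("Mel scale evaluates the closed form and inverts exactly", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2), tolerance = 1e-12)
  for (f in c(50, 500, 4000)) {
    expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  }
  expect_true(all(diff(hz_to_mel(seq(0, 64, by = 0.5))) > 0))
  expect_error(hz_to_mel(-1), "non-negative")
})

test_that("pre-emphasis follows the first-order difference with identity boundary", {
  expect_equal(pre_emphasis(rep(2, 5), 0.97), c(2, rep(0.06, 4)))
  x <- rnorm(20)
  expect_equal(pre_emphasis(x, 0), x)
  expect_equal(pre_emphasis(c(1, -1, 1, -1), 0.97), c(1, -1.97, 1.97, -1.97))
  expect_error(pre_emphasis(numeric(0)), "empty")
})

test_that("framing emits the closed-form frame count and exact sample blocks", {
  x <- rnorm(30 * 125)
  fr <- frame_signal(x, 125, 0.5, 0.25)
  expect_equal(nrow(fr), 119)
  expect_equal(attr(fr, "frame_len"), 62L)
  # no-overlap framing concatenates back to the signal prefix
  fr2 <- frame_signal(x, 125, 0.5, 0.5)
  k <- 10
  expect_equal(as.vector(t(unclass(fr2)[1:k, ])), x[1:(k * 62)])
  # exactly one frame when the signal equals one frame length
  expect_equal(nrow(frame_signal(x[1:62], 125, 0.5, 0.25)), 1)
  # shorter than a frame: zero frames, flagged, not an error
  short <- frame_signal(x[1:10], 125, 0.5, 0.25)
  expect_equal(nrow(short), 0)
  expect_true(attr(short, "empty"))
})

test_that("frame count matches brute-force start enumeration over random setups", {
  set.seed(41)
  for (rep in 1:300) {
    fs <- sample(c(64, 100, 125, 128), 1)
    w <- sample(c(0.1, 0.25, 0.5, 1, 1.5, 2, 3), 1)
    s <- sample(c(0.05, 0.1, 0.25, 0.5, 1), 1)
    if (s > w) next
    n <- sample(10:(30 * fs), 1)
    fr <- frame_signal(numeric(n), fs, w, s)
    expect_equal(nrow(fr), oracle_frame_count(n, fs, w, s),
                 info = sprintf("n=%d fs=%d w=%g s=%g", n, fs, w, s))
  }
})

test_that("Hamming window has the printed endpoints, center and symmetry", {
  w <- hamming_window(63)
  expect_equal(w[1], 0.08)
  expect_equal(w[63], 0.08)
  expect_equal(w[32], 1.0)               # center of odd-length window
  expect_equal(w, rev(w))
  expect_error(hamming_window(1), ">= 2")
})

test_that("power spectrum matches a direct DFT and satisfies Parseval", {
  # pure cosine on a bin: energy concentrates there
  nfft <- 64
  k0 <- 6
  x <- cos(2 * pi * k0 * (0:63) / 64)
  ps <- power_spectrum(matrix(x, 1), nfft)
  expect_equal(which.max(ps[1, ]), k0 + 1)
  expect_equal(ps[1, ], oracle_dft_power(x, nfft), tolerance = 1e-9)
  # off-bin frame vs the naive DFT oracle
  set.seed(5)
  fr <- matrix(rnorm(3 * 50), 3)
  ps <- power_spectrum(fr, nfft)
  for (i in 1:3) expect_equal(ps[i, ], oracle_dft_power(fr[i, ], nfft),
                              tolerance = 1e-9)
  # Parseval: two-sided |X|^2 / nfft equals the windowed-sample energy
  two_sided <- ps[, c(1:(nfft / 2 + 1), (nfft / 2):2)]
  expect_equal(rowSums(two_sided) / nfft, rowSums(fr^2), tolerance = 1e-9)
  expect_equal(unname(power_spectrum(matrix(0, 1, 10), 16)[1, ]), rep(0, 9))
  expect_error(power_spectrum(fr, 63), "even")
})

test_that("Mel filter bank peaks at 1 and tiles interior bins", {
  H <- mel_filterbank(40, 128, 125, 0, 62.5)
  expect_true(all(H >= 0))
  expect_equal(unname(apply(H, 1, max)), rep(1, 40))
  centers <- attr(H, "centers")
  for (m in 1:40) expect_equal(H[m, centers[m] + 1], 1)
  # partition of unity strictly between the first and last centers
  interior <- (centers[1] + 1):(centers[40] - 1)
  expect_equal(unname(colSums(H)[interior + 1]), rep(1, length(interior)),
               tolerance = 1e-12)
  # compact support: each row is a single contiguous triangle
  for (m in c(1, 10, 40)) {
    nz <- which(H[m, ] > 0)
    expect_true(all(diff(nz) == 1))
  }
  expect_equal(unclass(H), oracle_filterbank(40, 128, 125, 0, 62.5),
               ignore_attr = TRUE)
  expect_error(mel_filterbank(40, 64, 128, 0, 64), "duplicate bin edges")
})

test_that("log energies floor at ln(eps) and follow the single-bin form", {
  H <- mel_filterbank(10, 64, 128, 0, 64)
  z <- log_energies(matrix(0, 2, 33), H, 1e-10)
  expect_equal(unname(z), matrix(log(1e-10), 2, 10))
  # single-bin spectrum of value v at bin k
  v <- 3.7; k <- 12
  p <- matrix(0, 1, 33); p[1, k + 1] <- v
  expect_equal(unname(log_energies(p, H, 1e-10)[1, ]),
               log(v * H[, k + 1] + 1e-10))
  # white noise: all energies finite
  set.seed(2)
  wn <- power_spectrum(matrix(rnorm(5 * 64), 5), 64)
  expect_true(all(is.finite(log_energies(wn, H))))
})

test_that("DCT cepstrum follows the half-integer cosine sum", {
  M <- 40
  # constant log energies: every kept coefficient is ~0
  expect_equal(dct_cepstrum(rep(3.2, M), 13), rep(0, 13), tolerance = 1e-12)
  # orthogonality: s = cos(pi*(m-0.5)/M) picks out C(1) = M/2
  s1 <- cos(pi * 1 * ((1:M) - 0.5) / M)
  cc <- dct_cepstrum(s1, 5)
  expect_equal(cc[1], M / 2, tolerance = 1e-9)
  expect_equal(cc[2:5], rep(0, 4), tolerance = 1e-9)
  # random rows against the direct sum
  set.seed(9)
  s <- matrix(rnorm(3 * M), 3)
  direct <- t(apply(s, 1, function(row) {
    vapply(1:13, function(n) sum(row * cos(pi * n * ((1:M) - 0.5) / M)),
           numeric(1))
  }))
  expect_equal(dct_cepstrum(s, 13), direct, tolerance = 1e-10)
  expect_error(dct_cepstrum(s, 41), "exceeds")
})

test_that("full chain is deterministic, shaped by the framing law, and scale-invariant", {
  set.seed(31)
  x <- rnorm(30 * 128)
  m1 <- extract_mfcc(x, 128)
  m2 <- extract_mfcc(x, 128)
  expect_identical(m1$coef, m2$coef)
  expect_equal(nrow(m1$coef), 119)
  expect_equal(ncol(m1$coef), 13)
  # doubling the signal shifts log energies by ln 4, which the n>=1 DCT
  # cancels (floor effects are negligible for non-silent signals)
  m4 <- extract_mfcc(2 * x, 128)
  expect_equal(m4$coef, m1$coef, tolerance = 1e-6)
  expect_error(extract_mfcc(x[1:10], 128), "less than one frame")
})

test_that("full chain matches the naive direct-sum oracle", {
  set.seed(77)
  for (fs in c(64, 125, 128)) {
    x <- rnorm(3 * fs) + sin(2 * pi * 7 * (1:(3 * fs)) / fs)
    got <- extract_mfcc(x, fs)$coef
    want <- oracle_mfcc(x, fs)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})
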