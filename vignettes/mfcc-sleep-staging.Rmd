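---
title: "Sleep staging with Mel-cepstral features and a CNN-LSTM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging with Mel-cepstral features and a CNN-LSTM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical sleep scoring assigns one of five stages — Wake, S1, S2, S3
(slow-wave sleep, merging the older R&K stages 3 and 4), and REM — to every
30-second epoch of an overnight polysomnogram (PSG). The stages differ
mainly in their spectral signatures: alpha rhythm (~10 Hz) and high muscle
tone in wake, theta (4–7 Hz) in S1, sigma-band spindle bursts (12–15 Hz) in
S2, high-amplitude delta (< 2 Hz) in S3, and theta with near-complete
muscle atonia in REM. `mfccsleep` implements an automatic scorer that reads
two central EEG channels and one EMG channel, converts each epoch into a
compact time–frequency representation — Mel-frequency cepstral coefficients
(MFCCs) — and classifies a three-epoch context window with a small
convolutional network followed by a peephole LSTM layer.

## The MFCC chain

MFCCs summarize a short-time power spectrum through a bank of triangular
filters spaced uniformly on the Mel scale,
$f_{mel} = 2595\,\log_{10}(1 + f/700)$, followed by a log and a discrete
cosine transform. The chain, applied independently to every 30-s epoch of
every channel:

1. **Pre-emphasis** $y(n) = x(n) - a\,x(n-1)$ with $a = 0.97$, boosting
   high frequencies. The first output sample is passed through unchanged
   ($y(1) = x(1)$); the recursion leaves it undefined and the identity is
   the usual convention.
2. **Framing** into windows of $w = 0.5$ s with stride $s = 0.25$ s.
   Frame length and hop are `round(w*fs)` and `round(s*fs)` samples; frame
   $k$ starts at sample $k \cdot \text{hop}$ and frames that would overrun
   the epoch are dropped, giving exactly
   $\lfloor (N - \text{len})/\text{hop} \rfloor + 1$ frames — 119 per
   30-s epoch at 125 or 128 Hz.
3. **Hamming window** $0.54 - 0.46\cos(2\pi n/(T-1))$.
4. **FFT power spectrum** $|X(k)|^2$ on the one-sided bins of a
   zero-padded transform.
5. **Mel filter bank**: $M = 40$ triangles whose edge frequencies are
   Mel-uniform between 0 and the Nyquist frequency, snapped to FFT bin
   indices. Each filter rises linearly to 1 at its center bin and falls to
   0 at the next center; adjacent triangles share edges, so the bank sums
   to exactly 1 on every interior bin (a property the tests assert). Log
   energies are floored as $\ln(E + \varepsilon)$ with
   $\varepsilon = 10^{-10}$ so silent frames stay finite.
6. **DCT cepstrum**
   $C(n) = \sum_{m=1}^{M} s(m) \cos\!\big(\pi n (m - 0.5)/M\big)$ for
   $n = 1 \ldots L$, with $L = 13$ kept coefficients — the conventional
   choice inside the commonly used 12–20 range. Starting at $n = 1$
   excludes the overall log-energy term, which makes the cepstra invariant
   to global amplitude scaling.

**FFT length.** The 0.5-s frames span 62–64 samples at these rates, but a
64-point FFT has only 33 one-sided bins — fewer than the 42 distinct bin
edges a 40-filter bank needs, so the bank would degenerate. The package
therefore resolves `nfft` to the next power of two at or above
`max(frame_len, 2*(M+1))`, i.e. 128 for the default configuration: fine
enough to host the bank, still cheap, and stable across the 125/128-Hz
recording families.

## Stream composition

UCDDB-style recordings store EMG at 64 Hz against 128-Hz EEG. All channels
are first resampled (polyphase FIR) to the fastest channel rate so that
every channel shares one frame grid; resampling is the only place rates are
touched, and channels already at the target rate pass through untouched.

For epoch $k$, the input tensor stacks the three channels' $L$ coefficient
rows vertically (height $13 \times 3 = 39$) and concatenates the frames of
epochs $k-1, k, k+1$ horizontally (width $119 \times 3 = 357$); the label
is epoch $k$'s stage. Framing restarts at each epoch boundary so no frame
straddles two stages. At the edges of a recording the first/last epoch is
replicated into the missing context slot, which keeps exactly one stream
per scored epoch (a drop policy is available). Channels-on-height /
time-on-width is an interpretation — the geometry is isolated behind
`stream_config()` — chosen so the convolution sees time as a contiguous
axis. Per-stream standardization exists as an off-by-default toggle; the
literal pipeline feeds raw cepstra to the model.

## The classifier

Four convolutional units (kernels 6×6, 5×5, 5×5, 2×2, each with leaky-ReLU
activations of negative slope 0.1) feed one peephole LSTM layer of 128
units, a fully connected layer, and a 5-way softmax. The LSTM cell:

$$i_t = \sigma(W_{xi}x_t + W_{hi}h_{t-1} + w_{ci}\odot C_{t-1} + b_i)$$
$$f_t = \sigma(W_{xf}x_t + W_{hf}h_{t-1} + w_{cf}\odot C_{t-1} + b_f)$$
$$c_t = \tanh(W_{xc}x_t + W_{hc}h_{t-1} + b_c)$$
$$C_t = f_t \odot C_{t-1} + i_t \odot c_t$$
$$o_t = \sigma(W_{xo}x_t + W_{ho}h_{t-1} + w_{co}\odot C_t + b_o)$$
$$h_t = o_t \odot \tanh(C_t)$$

The peephole weights act diagonally (one scalar per unit), the standard
peephole formulation; note the output gate peeks at the *current* cell
state while the input and forget gates see the previous one, and the
hidden output is driven by the accumulated cell state $C_t$, not the
candidate $c_t$. The conv output is collapsed by treating its width (time)
axis as the LSTM sequence and flattening height × filters into the
per-step feature vector; the last hidden state feeds the output layer.

Choices the architecture leaves open were fixed for single-CPU training at
package scale: filter counts 8/8/8/16, a (2, 3) stride on the first
convolution (an early map reduction in the tested 2–4 stride range)
with 2×2 max-pooling after the second and third units, same-padding
everywhere so the 2×2 fourth kernel is always shape-valid, Adam at
learning rate $10^{-3}$, batch size 128, unweighted cross-entropy (class
imbalance is reported, not corrected), at most 14 epochs with early
stopping (patience 4) on validation accuracy, and the best-validation
parameters retained. All of these sit in `model_config()`. Initialization,
shuffling, and everything downstream derive from one integer seed; two
runs with the same configuration are identical. The forward/backward
passes are hand-written (im2col convolutions, BPTT through the peephole
cell) with compiled kernels, and every analytic gradient is checked
against numerical differentiation in the test suite.

## Evaluation metrics

`eval_report()` produces the confusion matrix over the fixed class order
(W, S1, S2, S3, REM), per-class one-vs-rest precision/recall/F1 and
accuracy (as percentages), overall accuracy, Cohen's
$\kappa = (p_0 - p_e)/(1 - p_e)$, and the Test Cost Index

$$\mathrm{TCI} = \frac{1}{N}\sum_{i=1}^{N} (y_i - \hat y_i)^3,$$

the mean *cubed signed* difference between true and predicted stage codes
(W = 0 … REM = 4). The cube keeps the sign and weights distant confusions
heavily, so a negative TCI indicates predictions biased toward
higher-coded stages. Because its value depends on the encoding, the code
order is fixed package-wide. A class absent from the truth or the
predictions scores 0 for the affected rate, with a warning, so macro
averages stay defined on imbalanced runs.

## The synthetic generator

Real reference recordings are access-restricted and far larger than a test
suite should carry, so the package ships a generator that emulates exactly
the structure the classifier must exploit: per-stage EEG oscillations
(alpha in wake, theta in S1, amplitude-modulated sigma bursts over theta
in S2, high-amplitude delta in S3, mixed theta in REM), an EMG channel
whose amplitude follows stage-dependent muscle tone (1.0 in wake down to
0.2 in REM), broadband Gaussian noise, random phases per epoch, and
heterogeneous channel rates (EEG 128 Hz / EMG 64 Hz by default, with an
all-125-Hz preset). Hypnograms come from a first-order Markov chain with
mean dwell times around 4–6 epochs and an S2 bias, echoing the S2
dominance of real nights. Everything derives from one master seed;
per-subject seeds are derived deterministically.

What the generator does *not* emulate: waveform morphology (K-complexes,
sawtooth waves, vertex waves), artifacts, arousals, apnea events,
inter-subject variability of spectra, or scorer disagreement. Passing the
end-to-end test therefore shows that the implementation can learn
stage-dependent spectral structure through the full pipeline — not that it
reaches any particular accuracy on clinical data. A linear discriminant on
raw band powers already separates these synthetic stages above 80%
accuracy (asserted in the tests), which is deliberate: the synthetic task
is a correctness floor, not a difficulty benchmark.

## Problem sizes and reproducibility

The shipped end-to-end experiment uses 12 subjects × 120 epochs (one hour
each) at UCDDB-like rates, split subject-wise 70/20/10 — no subject
contributes to two partitions — and reports the median held-out accuracy
and macro-F1 over three model seeds. These sizes keep the whole experiment
in a few CPU-minutes while leaving every component at its production
configuration. `scripts/acceptance.R` re-runs exactly this experiment from
one command-line seed.

## Known limitations

* The EDF writer emits the plain 16-bit flavour with 1-s records and
  therefore requires integer channel rates; EDF+ annotation channels are
  not parsed beyond what the hypnogram readers cover.
* The window/stride sweep reports frames-per-epoch as a
  hardware-independent proxy for training cost rather than wall-clock
  time.
* No liftering, delta features, or cepstral mean normalization are
  applied; the pipeline is deliberately the minimal six-step chain.
* Training is plain Adam without class weighting; heavily imbalanced
  hypnograms will favour the majority stage.
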