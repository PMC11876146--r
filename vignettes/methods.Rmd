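---
title: "Reconstructing stimulation-blanked iEEG by masked-token modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing stimulation-blanked iEEG by masked-token modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Responsive neurostimulation implants for epilepsy record intracranial EEG
(iEEG) and deliver electrical stimulation when they detect abnormal
activity. While a stimulation burst is delivered, the recording amplifier
is *blanked*: the stored signal is exactly flat for the duration of the
burst (10 ms to 5 s, typically around 100 ms) and is followed by an
amplifier-recovery artifact — a sharp spike with a rapid, roughly
exponential decay lasting a few hundred milliseconds. A large fraction of
chronic records contain at least one such gap, which frustrates any
analysis of the acute effects of stimulation.

stimfill implements a reconstruction approach borrowed from masked
language modelling: reduce each second of each channel to one integer
*token* summarizing its spectral content, train a bidirectional
transformer encoder to predict tokens hidden behind a mask from the
surrounding context, and use that model to fill in the seconds lost to
blanking. Interpolation and random-token baselines and a tolerance-based
evaluation harness complete the pipeline.

## Tokenization

Records are 250 Hz, up to 4 channels, nominally 90 s. After artifact
excision and per-channel z-scoring (population-SD convention; the formula
leaves the denominator convention open, so it is configurable), band power
is computed per non-overlapping 250-sample (1 s) window as a Hann-tapered
one-sided periodogram summed over the frequency bins of each band and
expressed in dB. Two band schemes are supported:

* **3band** — 0–13 Hz (delta/theta/alpha), 13–35 Hz (beta),
  35–125 Hz (gamma);
* **4band** — 0–8 Hz (delta/theta), 8–13 Hz (alpha), 13–35 Hz (beta),
  35–125 Hz (gamma), trading vocabulary size for low-frequency resolution
  given the 1/f shape of neural spectra.

Raw band power is strongly long-tailed, so fixed-width bins would leave
most bins nearly empty. Instead, per-band bin boundaries are the 10th–90th
percentiles (linear-interpolation estimator) of a pooled calibration
sample; each band's dB value quantizes to a decile digit 0–9, making every
digit uniform on the calibration distribution by construction. Digits are
concatenated with the lowest-frequency band as the most significant digit
(the digit-order convention only affects token spelling, not accuracy):
3 bands give tokens 000–999, 4 bands 0000–9999. A sequence is padded with
token 0 to 90 tokens or truncated to the first 90; because padding
collides with the real token 000, the true `signal_length` is carried
alongside and evaluation never touches padding. Ties at a bin boundary go
to the upper bin (left-closed binning); any consistent rule would do, this
one is documented and tested.

Whether binning happens on linear or dB power is a genuine open choice;
dB was chosen because quantization boundaries of long-tailed spectral
power are conventionally displayed and reasoned about in dB, and the
quantile boundaries are then better spread. Quantiles are pooled across
the calibration corpus rather than computed per record, so that a token
means the same thing in every channel.

## The masked-token model

The encoder is a standard bidirectional transformer: token embedding plus
learned positional embedding, `num_hidden_layers` pre-norm self-attention
blocks (layer norm, multi-head attention, residual; layer norm,
position-wise feed-forward with configurable activation, residual), a
final layer norm, and a softmax head over the vocabulary evaluated only at
masked positions. The pre-norm arrangement is used because it trains
stably with Adam at desk-scale learning rates without a warmup schedule,
which the post-norm original needs; attention projections carry no bias
terms (the layer-norm affine parameters make them redundant).
The vocabulary is the `10^B` real tokens plus one mask token (`10^B`
itself). For the 4-band scheme the mask token is 10,000 — a mask value
inside the real range (such as 1,000, which is a legitimate 4-band token)
would be ambiguous.

Training masks a fixed 16 of the 90 positions (18%) per channel per
epoch, drawn uniformly over *all* positions including padding — the
masking rate is raised from the conventional 15% precisely because some
masks land on trivially predictable padding. Masked positions are replaced
by the mask token only (no random-token/keep split); cross-entropy loss is
computed at masked positions only; Adam optimizes with global
gradient-norm clipping at 1.0. Validation loss is measured each epoch on
masks that are fixed across epochs, so successive values are comparable;
training stops at `max_epochs` or after `early_stop_patience` epochs
without improvement, and the best-validation weights are kept.

No deep-learning framework is used: forward pass, analytic
backpropagation and Adam are implemented directly on matrix operations,
with gradients verified against numerical differentiation in the test
suite. Two consequences follow. First, the default configuration is
desk-scale — hidden dimension 64, 2 layers, 4 heads, learning rate 1e-3,
batch 32 — sized to train on one CPU in minutes; the full-scale
configuration (dimension 496, 6 layers, 8 heads, learning rate 1e-6) is
expressible through the same `model_config()` fields. Second, the default
feed-forward activation is ReLU rather than GELU: elementwise normal CDF
evaluations dominate the step time in this implementation, and at these
model sizes the two train comparably (`activation = "gelu"` is available).

Inference is deterministic: predictions are the argmax over the real
vocabulary (the mask token is excluded), ties broken toward the lower
token id.

## Synthetic data: what it emulates, what it does not

No clinical recordings ship with the package; the generator produces
records with the statistical features the method actually relies on:

* each channel is a sum of four band-limited Gaussian components (0.5–8,
  8–13, 13–35, 35–125 Hz) on top of a 1/f broadband background;
* each component's log-amplitude follows a first-order autoregressive
  state updated once per second (default half-life 5 s, stationary SD 0.5
  natural-log units) and linearly interpolated between window centres, so
  per-second band powers are smooth and autocorrelated across seconds —
  the property that makes context-based reconstruction learnable at all,
  and one the package verifies (lag-1 autocorrelation of per-second band
  power exceeds 0.5 at the default half-life);
* injected blanking replaces a span on every channel with the value at
  its onset (hardware blanking is exactly flat) and adds a recovery spike
  `A e^{-t/tau}` (default tau 100 ms, truncated at 500 ms, amplitudes
  5–15 signal units) after the blank; spikes are applied before fills so
  blanks are exactly constant even inside an earlier blank's recovery
  tail;
* in a generated corpus, 35% of records (configurable) receive 1–5 blanks
  with log-normal durations (median ~100 ms, clipped to the 10 ms–5 s
  hardware range), placed in disjoint chunks so they never overlap.

Real iEEG differs in ways the generator does not attempt: no epileptiform
transients, line noise, electrode drift, state changes (sleep/wake),
cross-channel coherence structure, or patient heterogeneity; amplitudes
are arbitrary units with no claim of realism, since z-scoring removes
scale. Consequently, passing benchmarks here demonstrate that the
implementation is correct and that the model learns temporal context when
it exists — not that clinical-scale accuracies are reproduced. Reported
clinical accuracies (~30% for 3 bands) depend on millions of channels and
full-scale training and are out of scope by design.

Blank detection assumes *exact* flatness (first difference exactly zero,
minimum run 3 samples = 12 ms, just above the shortest 10 ms burst);
this matches both hardware blanking and the generator's constant fills,
and makes the generator/detector round trip exact — a property tested in
integration. The 125 samples (500 ms) following each blank are excised to
cover the recovery artifact; deletions that run into each other are
merged (the behaviour of two blanks closer than the recovery window is
unspecified upstream; merging is the conservative choice).

## Evaluation

A prediction is counted correct when every band digit is within ±1 of the
truth (no wraparound between 0 and 9 — bins are ordered, not circular):
for truth 456, prediction 345 is correct and 256 is not. Per-channel
accuracy is the percentage of *masked* positions predicted within
tolerance; the harness reports mean and SEM (sample SD over sqrt of the
number of channels) across channels. The denominator is the number of
masked tokens, not the 90 tokens of the file: with one masked token the
alternative reading would cap accuracy at 1.1%, inconsistent with any
reported accuracy above that, so the masked-token denominator is the only
coherent interpretation.

The benchmark protocol masks k = 1..10 tokens per channel, either as
individually scattered positions or as one consecutive run (emulating one
long blank), always inside the real signal length; channels shorter than
k are skipped with a warning. Methods: the trained model; digit-wise
interpolation — up to `context` (default 1) nearest unmasked, non-padding
tokens per side, decoded to digits, averaged per band, rounded half-up,
re-encoded; and uniform random tokens. Digit-wise rather than raw-integer
averaging is the default because token integers are positional encodings:
averaging 190 and 210 as integers gives 200, which corresponds to no
sensible per-band average (raw-integer mode is available for comparison).
The rounding rule (half-up) is a documented convention. A context sweep
(1–5 tokens per side, at 7 consecutive masked tokens) mirrors the
standard comparison table layout.

For the random baseline a closed form exists: with uniform digits, a
uniform prediction lands within ±1 of the truth with probability 28/100
per band (interior digits accept 3 of 10, the two edge digits 2 of 10),
so expected accuracy is `100 * 0.28^B` — 2.1952% for 3 bands and 0.6147%
for 4. The package exposes this via `expected_random_accuracy()` and the
test suite verifies both the enumeration and the Monte-Carlo convergence
of the simulated baseline to it.

## Numerical and design choices

* Percentile estimator: linear interpolation (type 7); calibration uses
  pooled windows from the training split only, so no test information
  leaks into the tokenizer.
* Degenerate inputs: constant signals fail z-scoring (zero SD) and are
  skipped with a warning; calibration requires at least 10 distinct
  values per band; out-of-range dB values clip into the end bins.
* Power floor: all-constant excised windows would give zero band power;
  dB conversion floors at the smallest positive double instead of
  returning -Inf.
* Splits are grouped by record id (all channels of a record stay in one
  set; a `group` key supports patient-level grouping for real data),
  80/10/10 by default.
* Determinism: every stochastic step (generation, masking, draws,
  initialization, shuffling) derives its seed from a caller-provided
  master seed via a fixed integer mixing function; identical seeds give
  bit-identical corpora, token files and training runs (single-threaded
  BLAS).
* EDF support is a minimal 16-bit implementation sufficient for
  round-tripping 4-channel 250 Hz records with standard EEG tooling;
  16-bit digitization makes the round trip approximate by one
  quantization step.

## Problem sizes

The package's own benchmarks run at desk scale, chosen once: the
end-to-end study uses 520 records x 4 channels = 2,080 channels
(80/10/10 split), quantile calibration pools up to 250 training records
(~90,000 windows), and the desk model trains for up to 30 epochs with
early stopping. The reference-quantity script uses 500 records (2,000
channels) and repeats random-baseline trials per channel (3 sweeps of the
k = 1..10 protocol; 250 single-token trials per channel for the 4-band
case) to shrink Monte-Carlo error well below the comparison bands.

## Known limitations

* Absolute clinical accuracies are not reproducible without a clinical
  corpus; the package's benchmarks are directional. Both context-using
  methods beat the random baseline by an order of magnitude, and
  interpolation accuracy declines steeply as consecutive-mask length
  grows while the random baseline stays flat.
* On this generator the trained model *matches* rather than beats
  digit-wise interpolation. The reason is decision-theoretic, not a
  training failure: predictions are the argmax (posterior mode) over
  tokens, but the ±1-digit metric rewards putting the prediction at the
  posterior's centre of mass over a 3-digit window. On symmetric,
  unimodal (Gaussian autoregressive) conditionals the rounded digit
  average that interpolation computes approximates that centre, so even a
  Bayes-optimal mode decoder cannot out-score it by a wide margin. Real
  iEEG conditionals are not Gaussian-symmetric, and richer long-range
  structure favours a learned model there. A tolerance-aware decoder
  (argmax of window-summed posterior mass) would change this, but argmax
  decoding is the documented prediction contract.
* Equally, growing the interpolation context (1 to 5 tokens per side)
  *reduces* accuracy on this generator: with a 5 s amplitude half-life,
  tokens beyond the nearest neighbour decorrelate quickly, so equal-weight
  averaging over wider context adds bias faster than it averages out
  noise. On clinical data, where band power carries slowly decaying
  long-range correlation relative to its measurement noise, wider context
  helps slightly; this is a known divergence between the synthetic
  conditions and real recordings, documented rather than tuned away.
* The amplifier-recovery tail beyond the fixed 500 ms excision window is
  not modelled or removed.
* Tokens discard within-second temporal structure and phase entirely;
  reconstruction is of per-second band-power summaries, not waveforms.
* The interpolation baseline operates in token space, as specified; it is
  not a waveform interpolator.
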