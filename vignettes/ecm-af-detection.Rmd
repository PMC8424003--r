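---
title: "Detecting brief AF episodes with electrocardiomatrix images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brief AF episodes with electrocardiomatrix images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmaf)
```

## The problem and the representation

Paroxysmal atrial fibrillation (AF) often surfaces as brief episodes — tens of
seconds — buried in long-term ECG recordings. The two clinical cues that
separate AF from normal sinus rhythm (NSR) are *rhythm* (irregular RR
intervals) and *morphology* (absence of the P wave, replaced by low-amplitude
fibrillatory oscillations). `ecmaf` detects such episodes by transforming the
ECG into **electrocardiomatrix (ECM) images** and classifying them with a
small convolutional network.

An ECM-image is built from a segment containing 10 consecutive beats plus
0.5 s before the first and 2.5 s after the last R peak. For each beat *i*, a
3.0 s subsegment starting 0.5 s before its R peak is extracted at 500 Hz
(1500 samples) and stacked as row *i*, so the R peaks of all rows are
vertically aligned. Each row is then downsampled in two sections:

* **left section** — the 0.5 s before the R peak at 125 Hz (decimate-by-4,
  63 columns): high time resolution where the P wave lives;
* **right section** — the remaining 2.496 s at 62.5 Hz (decimate-by-8,
  156 columns): coarse resolution that still encodes where the *following*
  beats fall in each row, i.e. the local rhythm pattern.

The result is a 10 × 219 intensity image (2,190 pixels). In NSR the
subsequent QRS complexes form regular vertical stripes; in AF the stripes
smear out and the left section loses its P-wave band.

### The 219-column geometry

A literal reading of "125 Hz over [0, 0.5] s and 50 Hz over [0.5, 3.0] s"
yields 63 + 125 = 188 columns, which contradicts the 10 × 219 image that the
network input layer and the relevance-map sides require. We honor the printed
matrix dimensions: the left section takes every 4th of the first 252 samples
(63 columns) and the right section every 8th of the remaining 1248
(156 columns, 62.5 Hz — "50 Hz" is treated as a rounding of the description,
not of the geometry). The boundary sits at subsegment offset 252, so column
64 is the first sample strictly after the aligned R peak region.

Before decimation each section is lowpass filtered at 0.8 × its output
Nyquist (4th-order Butterworth applied forward-backward, i.e. 8th-order
magnitude). `build_ecm_dataset()` applies each section's filter once to the
whole record rather than per row — in-band equivalent, free of per-window
edge transients, and much cheaper. A raw index-map mode
(`anti_alias_filter = FALSE`) exists so tests can check the pixel-to-sample
mapping exactly and invert it.

## Preprocessing

Records are (1) resampled to 500 Hz, (2) highpass filtered at 0.5 Hz with a
4th-order Butterworth to remove baseline wander, (3) clipped to ±1 mV.
"Linear-phase Butterworth" is contradictory for a single-pass IIR filter; we
apply the filter forward and backward (zero phase — peaks do not move, the
magnitude response is squared). Edge transients are suppressed by
odd-reflection padding of 10 s, long enough that a 0.5 Hz highpass transient
decays below 1e-6.

Resampling is a delay-compensated windowed-sinc rational resampler
(`p/q` up/down factors from a rational approximation of the rate ratio;
Blackman window, 10 sinc zero-crossings per side). Exact linear-phase
compensation matters here because beat indices are rescaled arithmetically:
any residual group delay would misalign annotations with the waveform.
Annotation bounds and beats are rounded to the nearest output sample, ties
to even. All sample indices in the package are 0-based and all intervals
half-open `[onset, offset)`.

Beat positions come from annotations (or the synthetic generator's ground
truth) whenever available. For raw records without annotations,
`detect_beats()` provides a classical stand-in: 5–25 Hz bandpass, squared
energy envelope, adaptive threshold at 15% of the 99th percentile, 200 ms
refractory period. It is deliberately simple — the method is tolerant of
imperfect beat detection because windows are defined by beat count rather
than by fixed time, and every pipeline entry point accepts externally
supplied beat lists that bypass it.

## The classifier

The network (built by `build_network()`) is fixed:

| layer | kernel (H, L, W) | stride | activations |
|---|---|---|---|
| input | – | – | 10 × 219 × 1 |
| conv 1 + BN + ReLU | (3, 9, 10) | (1, 1) | 10 × 219 × 10 |
| max pool 1 | (3, 3) | (1, 2) | 10 × 110 × 10 |
| conv 2 + BN + ReLU | (3, 9, 15) | (1, 1) | 10 × 110 × 15 |
| max pool 2 | (3, 3) | (2, 2) | 5 × 55 × 15 |
| conv 3 + BN + ReLU | (2, 4, 20) | (2, 2) | 3 × 28 × 20 |
| fully connected + softmax | – | – | 2 |

for a total of 10,217 trainable parameters (batch-norm running statistics
are not trainable and are excluded from the count). Two structural choices
deserve a note:

* **Conv-2 stride.** The published stride entry for the second convolution,
  (1, 2), is inconsistent with its own output shape (10 × 110, equal to its
  input). We use stride (1, 1), the only reading under which the activation
  chain composes and the fully-connected input is 3·28·20 = 1680 features —
  which is what fixes the 10,217 total.
* **Padding.** Convolutions and pools use "same"-style zero-padding with
  `out = ceiling(in / stride)` and the excess padded asymmetrically (more at
  the bottom/right). The published shapes, not a padding formula, are the
  contract; this rule reproduces them exactly. Pooling pads with −∞ so
  padding never wins the max.

Training is stochastic gradient descent with momentum 0.9, learning rate
0.01, L2 1e-4 on convolution and fully-connected weight matrices, binary
cross-entropy on the 2-class softmax, 3 epochs with seeded per-epoch
reshuffling. Classes are balanced beforehand by randomly excluding the
surplus of the majority class (seeded, order-preserving). The original batch
size of 3000 suits multi-million-image corpora; the desk default is 256
(configurable). Weight initialization is seeded scaled-uniform with fan-in
variance 1/fan-in; the original toolbox's scheme is unpublished, so only
structural quantities (shapes, parameter count) are treated as binding.

Because a desk-scale run performs only tens of SGD steps, the
momentum-tracked batch-norm running statistics would lag far behind the
learned parameters and inference-mode outputs would not match training
behavior. `train()` therefore ends with an exact recalibration pass
(`calibrate_batchnorm()`): each batch-norm layer's running mean/variance is
replaced by the statistics of its inputs over the full training set under
the final parameters. This is deterministic and changes no trainable
parameter.

`train_three_splits()` makes three seeded patient-wise 80/20 splits (the
original split composition was manual and is not reproducible); no patient
ever contributes to both sides of a split. The final decision for an image
is the majority of the three networks' argmax votes (`mov_classify()`).

## Explaining decisions: LRP-ε

`lrp_epsilon()` propagates the winning class's softmax score backwards.
Linear and convolutional layers redistribute relevance proportionally to
`a_k · w_{n,k}` over the stabilized pre-activation
`z_n + ε·sign(z_n)`; the bias participates in `z_n`, and the relevance
share it would receive is absorbed (with ε = 0 and zero biases the total is
conserved exactly — this is tested to 1e-6). Choices where the method
description is silent:

* the denominator is **sign-stabilized** (`ε·sign(z)`), the standard way to
  avoid cancellation for negative pre-activations; a literal bare-ε mode is
  available (`sign_stabilized = FALSE`);
* batch-norm has no native LRP rule and is **folded** into the adjacent
  convolution as an inference-time affine before redistribution;
* max-pooling routes relevance **winner-take-all** to its argmax input,
  which is conservative by construction;
* ReLU passes relevance unchanged;
* relevance can alternatively start at the winning **logit**
  (`start = "logit"`), a common variant, but the softmax score is the
  default; ε defaults to 1, the value that suppresses noise contributions
  while keeping the dominant features.

`collapse_sides()` folds the 10 × 219 relevance map into two traces. The
left sections of all rows are beat-aligned by construction, so the
leftside-LRP is the plain column mean over the 10 rows on the beat-relative
axis [−0.5, 0) s. Right-section pixels are mapped through the downsample map
and each row's beat time back to record time; where spans from different
rows overlap, contributions are averaged per sample (coverage-weighted, with
the coverage count reported). Signed averaging is the default — negative
relevance (evidence against the decision) is informative; an absolute-value
mode exists.

## Evaluation

Window-level decisions are scored with the confusion metrics Acc, Se, Sp,
PPV, F1 and the Matthews correlation coefficient rescaled to [0, 1] as
`(Mcc + 1)/2`. Any metric whose denominator vanishes is reported `NA`,
never silently 0 — one-class toy data would otherwise inflate summaries.

For episode scoring, each classified window's label is painted onto its
samples (`remap_to_samples()`; where training-style overlapping windows
disagree, AF wins — testing uses non-overlapping windows, so this rule is
inert there), maximal AF runs become detected episodes, and
`ec57_metrics()` computes episode sensitivity/PPV and duration
sensitivity/PPV. Episode matching is **any-overlap** — one detected sample
inside an annotated episode counts it as found — the permissive reading of
the EC57 convention; detected episodes are not gap-merged before scoring
(a merge flag can be added without changing the interfaces, but merging
would hide the short-false-episode behavior the duration metrics are meant
to expose). `brief_episode_sensitivity()` recomputes episode sensitivity
restricted to annotated episodes shorter than each threshold
(10/15/20/30/60/90/120/∞ s), with cumulative bin counts.

## The synthetic generator

`generate_record()` emulates exactly the statistical structure the detector
exploits, nothing more:

* **RR intervals**: log-normal draws, NSR mean 0.8 s with CV 0.03, AF mean
  0.6 s with CV 0.20, i.i.d. (serially uncorrelated) — an
  atrioventricular-node model would add realism the classifier does not
  need and would be harder to seed and reason about;
* **morphology**: each beat renders a sum of Gaussian bumps (P, Q, R, S, T).
  During AF the P bump is omitted entirely (zero P-template energy by
  construction) and a fibrillatory sinusoid (6 Hz, 0.08 mV, frequency- and
  amplitude-jittered, cosine-tapered at rhythm boundaries) is added.
  T-wave latency scales with the preceding RR interval (Bazett-style √RR),
  so at AF rates the previous T wave realistically encroaches on the pre-R
  window;
* **noise**: baseline wander (0.03 mV at 0.25 Hz, below the highpass cutoff)
  and white noise (SD 0.01 mV).

`generate_cohort()` jitters amplitudes, RR means and f-wave frequency per
patient (seeded) so patient-wise splits are meaningful;
`generate_brief_af_plan()` builds NSR backgrounds with AF insertions of
exact durations for episode-sensitivity studies. Ground-truth beats and
rhythm intervals are returned with every record and revalidated on
construction.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: ectopy and bigeminy (the classic AF confounder),
noise bursts and electrode artifacts, atrial flutter, multi-lead projection
geometry, and genuine inter-patient morphology diversity beyond scaling
jitter. The end-to-end accuracy bar on synthetic cohorts is an engineering
check of the pipeline's learning machinery, not a claim about clinical
performance; published real-data figures require the public PhysioNet
databases, which this package can read (WFDB format 16 + MIT annotations)
but does not ship.

## Problem sizes and numerical choices

The bundled experiments use desk-scale sizes chosen once: 20 training
patients × 200 s for the end-to-end check (≈1,000 training images after
balancing, three networks, 3 epochs at batch 256), 5 held-out test patients
(two mixed-rhythm, three with brief-AF plans of 8/20/35/60/90 s episodes).
On these conditions the ensemble reaches ≈0.99 held-out window accuracy and
detects all synthetic episodes ≥ 15 s; the acceptance suite asserts the
engineering bars (≥ 0.90 and ≥ 80%).

Numerical details fixed by design: zero-phase filtering pads 10 s by odd
reflection; the batch-norm variance floor is 1e-5; softmax is computed with
max-shift stabilization; the LRP denominator substitutes the machine epsilon
when it would be exactly zero; rounding of rescaled annotation indices is
nearest-ties-to-even (R's `round()`); seeded streams derive child seeds per
patient/split/epoch so results are invariant to evaluation order and all
seeds stay below 2³¹.

## Limitations

The stand-in beat detector is a deliberately simple energy detector — on
heavily artifacted real records a production detector should be substituted
via the external beat-list entry points. The CNN training loop is plain R +
BLAS with C++ gather/scatter kernels; it is sized for desk-scale
experiments, not for the multi-million-image corpora of the original
training regime. Episode scoring implements the permissive any-overlap
matching only. The WFDB reader covers format 16 with standard beat and
rhythm annotations — the subset the AF databases use — not the full format
zoo.
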