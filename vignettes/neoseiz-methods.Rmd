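---
title: "Detecting neonatal seizures with fully convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neonatal seizures with fully convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seizures in newborns are mostly subclinical: without continuous EEG
monitoring the majority go unnoticed, and continuous review requires an
expert who is rarely available around the clock in a neonatal intensive
care unit. An automated detector watches the multichannel EEG and raises
per-second seizure probabilities and discrete seizure alarms.

Clinical annotations of neonatal EEG are *weak labels*: a reviewer marks
seizure intervals in time but not the channels on which the discharge is
visible. `neoseiz` is built around that constraint end to end — every
channel of a window becomes an independent single-channel training example
carrying the window's time label, and channel fusion happens only at
inference.

## Pipeline

1. **Montage and band-limiting.** The standard eight bipolar derivations
   (F4-C4, C4-O2, F3-C3, C3-O1, T4-C4, C4-Cz, Cz-C3, C3-T3) are formed
   from referential electrodes. Rhythmic seizure activity in neonates is
   concentrated between roughly 0.5 and 12 Hz, so the signal is
   band-passed 0.5–12.8 Hz (zero-phase order-4 Butterworth high- and
   low-pass applied forward–backward) and resampled to 32 Hz. Zero-phase
   filtering is a deliberate choice: a causal filter would shift the
   signal relative to the 1 s label grid. Integer ratios (256 to 32 Hz)
   decimate by sample picking, since the low-pass already bounds the
   bandwidth; non-integer ratios (200 to 32 Hz = 4/25) use a polyphase
   zero-stuffing resampler with a zero-phase windowed-sinc FIR.
2. **Windowing.** 16 s windows slide with a 1 s shift; a window is
   labelled seizure when at least 8 of its 16 seconds are seizure
   (majority rule — the tie at exactly 8 counts as seizure, erring toward
   sensitivity for boundary windows). The raw amplitudes are *not*
   normalized: amplitude is diagnostic in neonatal EEG, and scale
   diversity is instead supplied by augmentation.
3. **Model.** A fully convolutional 1-D network maps a window of any
   length (at least its receptive field) to one probability through a
   global average pool and sigmoid. Two architectures are provided:
   a compact **baseline** (3 feature-extraction blocks of three
   32-filter kernel-3 convolutions with batch norm, ReLU, and stride-2
   average pooling, then a one-map classification convolution), and the
   **enhanced** network: 4 residual feature-extraction blocks with
   bottleneck pointwise convolutions, a depthwise convolution (64
   filters, kernel 5) opening block 2, kernel-9 spatial convolutions,
   stride-2 average pooling per block, and a kernel-12 classification
   convolution. The enhanced layer table is pinned by three published
   constraints, re-verified at build time: 45,121 trainable parameters
   (rounding to 45 K), an analytic receptive field of 320 samples (10 s
   at 32 Hz), and the residual/depthwise/bottleneck structure itself.
4. **Training.** Weighted binary cross-entropy (inverse class
   frequencies, renormalized to mean example weight 1) under RAdam
   (learning rate 1e-3, moment decays 0.9/0.999), batch size 128, with
   two on-the-fly augmentations in fixed order: dynamic amplitude
   rescaling (per-example gain, uniform on 0.5–2 by default) and then
   Mixup (one Beta(0.2, 0.2) coefficient per batch, unrestricted pairing
   across patients). There is no held-out validation split — all data
   trains; training stops when the epoch loss has failed to improve by
   `plateau_delta` for `plateau_patience` consecutive epochs, and the
   checkpoint is the epoch with the highest training AUC (estimated on a
   fixed subsample of un-augmented training examples to bound the
   per-epoch cost). Three seeds are trained and their probabilities
   averaged at inference. The baseline regime is batch 300 with
   SGD-Nesterov (lr 0.001, momentum 0.9) and Glorot uniform
   initialization.
5. **Postprocessing.** Window probabilities are assigned to window-center
   seconds, smoothed by a centered 61-tap (60 s) moving average with
   truncated-renormalized edges, contrasted against the trailing
   10-minute mean of the sequence (subtraction with clipping to [0, 1] —
   division was rejected as unstable when the background probability is
   near zero), thresholded, and every detected event is extended by a
   30 s collar on both sides with overlapping events merged. The stage
   order — smooth, adapt, threshold+collar — is fixed.
6. **Metrics.** Per-second epoch metrics: AUC (Mann–Whitney form, ties
   half), AUC90 (trapezoidal partial area over specificity 0.9–1.0 with
   boundary interpolation, normalized by 0.1 so chance is 5% and
   perfection 100%), and AUC-PR by average precision (trapezoidal PR
   interpolation is biased upward; a trapezoid variant is selectable).
   Event metrics: good detection rate (any-overlap) and false detections
   per hour, averaged unweighted across patients with seizures; the
   GDR–FD/h curve sweeps the threshold. AUC differences are tested with
   the Hanley–McNeil standard error, treating the two models'
   errors as independent. Note that when both class counts scale by `k`
   this SE falls as `1/sqrt(k)` — slower than the inverse square root of
   the class-count product, because its numerator also grows with the
   counts.
7. **Site adaptation.** A model trained at site A is adapted to site B
   from *unlabelled* site-B recordings: the trained ensemble scores the
   site-B windows, the 1.5% most seizure-like are discarded as uncertain
   (ties at the cut are discarded too, never labelled), the rest become
   background-class pseudo-labels, and the network is retrained from
   random initialization on the merged corpus with freshly derived class
   weights. Only the background class is ever pseudo-labelled, so a full
   retrain is used rather than fine-tuning; soft labels are never used as
   targets (a model fine-tuned against its own probabilities receives no
   gradient). The quantile is computed corpus-wide over the per-channel
   window examples — the same unit that enters training.

## The synthetic data generator

No clinical recordings ship with the package; the simulator in
`synth_config()` / `synthesize_record()` emulates the *structure* of
neonatal corpora so the pipeline can be exercised and tested end to end:

* 8 channels at 256 Hz (200 Hz selectable) in microvolts;
* background: per-channel Gaussian noise shaped to a `1/f` power law over
  0.1–64 Hz, 30 µV RMS — an amplitude and spectral envelope typical of
  normal-voltage neonatal background;
* seizures: amplitude-modulated harmonic-rich sawtooth discharges whose
  instantaneous frequency ramps linearly (default 2 to 1 Hz, a slowing
  rhythmic discharge inside the 0.5–12 Hz band), active on a random
  channel subset of at least one channel, at a discharge-to-background
  RMS ratio of 2 by default. The harmonic-rich waveform is deliberate:
  the 12.8 Hz low-pass visibly attenuates its harmonics, so preprocessing
  is exercised rather than bypassed;
* weak labels: every injected second is marked seizure on the time axis
  regardless of the active channel subset — mirroring clinical practice;
* events: durations uniform on 30–90 s, separated by at least 60 s so
  that the 60 s smoothing filter cannot merge distinct events, at a
  target prevalence of 10% of seconds (the regime of curated training
  corpora; long unedited monitoring runs closer to 1%). On records too
  short to honor both the duration draw and the separation rule the
  generator degrades gracefully (clamping or dropping events), so very
  short fixtures may miss the prevalence target;
* site shift: a global gain and added white sensor noise emulate
  hardware and procedural differences between units. The event plan is
  drawn before the background, so site-shifted copies of a record have
  identical label structure.
* Event counts respect the prevalence budget in expectation even when it
  is below one event's worth of seconds: the last event is capped at the
  remaining budget, and a sub-minimum remainder becomes a minimum-length
  event with matching probability. A 1% record therefore usually
  contains no seizure at all — which is what makes it a faithful
  stand-in for unannotated sample corpora. The packaged adaptation study
  uses exactly that: the unlabelled target-site sample is generated at
  1% prevalence, because background-only pseudo-labelling with a 1.5%
  discard budget presumes the unlabelled data is nearly seizure-free;
  feeding it a 10%-prevalence corpus instead poisons the pseudo-labels
  (about one window in ten would be a mislabelled seizure) and
  measurably hurts the adapted model.

What the simulator does **not** model: artefacts (ECG, respiration,
electrode pops, movement), inter-patient background variability,
state cycling, or realistic seizure morphology evolution. Passing
end-to-end tests on this data therefore demonstrates that the pipeline
is wired correctly and can learn band-limited rhythmic structure from
weak labels under amplitude shift — not that it reaches clinical
performance; the published clinical figures come from corpora three
orders of magnitude larger.

## Numerical and design choices

* **Window-label rule** for boundary windows (majority, ties to
  seizure) is a repo decision; published descriptions leave it open.
* **Channel fusion** at inference is the arithmetic mean (maximum
  selectable); the mean matches the ensembling philosophy and damps
  single-channel artefacts.
* **Ensemble averaging precedes postprocessing**: member probabilities
  are averaged first and smoothing runs once on the average.
* **Dense inference.** Scoring a record window-by-window recomputes each
  convolution 16 times. `predict_windows_dense()` instead runs the
  convolutional body once over the whole record and averages the
  classification map over each window span; interior windows then see
  real context instead of zero padding at window edges. The two paths
  agree closely away from record borders (the difference is the padding
  of the outermost ~5 s of context) and dense scoring is the default in
  `detect_record()`.
* **Training thinning.** Windows shifted by 1 s overlap in 15 of 16
  seconds, and all channels of a window share one label; `window_stride`
  and `channels_per_window` subsample this redundancy for training
  (inference always uses every position and channel). The packaged
  end-to-end experiments train on every 5th window and 2 random channels
  per window for 2–3 epochs — these problem sizes (20 + 5 records of
  10 min for detection; 6 + 6 + 3 records for the two-site adaptation
  study) are the package's scaled-down study conditions.
* **Optimizer details.** RAdam implements the variance-rectification
  warm-up exactly (momentum-SGD fallback while the rectification term is
  undefined, rho <= 4). Batch-norm counts scale and shift as trainable
  parameters; running statistics are state and excluded from the 45 K
  parameter count.
* **EDF I/O** is a minimal 16-bit implementation (one sampling rate, 1 s
  records, ±2000 µV physical range by default — a typical neonatal
  head-box range). Round-trips are exact to the quantization step of
  about 0.061 µV. EDF+ discontinuous records are out of scope.
* **Degenerate inputs.** Single-class training sets, empty probability
  sequences, thresholds outside (0, 1), empty channel sets and
  overlapping annotation events are rejected with errors; overlapping
  events can be merged explicitly with `merge_events()`.

## Limitations

The networks are trained on CPU in double precision; training throughput
(~1 s per 128-example batch) bounds practical experiments to the
synthetic scale above. The adaptive background stage assumes prolonged
non-seizure stretches — on recordings dominated by status epilepticus it
would subtract away genuine activity (a known property of this family of
postprocessors). The AUC-difference test ignores the correlation between
two models scored on the same data and is therefore conservative when the
models are similar.
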