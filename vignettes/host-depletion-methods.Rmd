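---
title: "Raw-signal host depletion: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raw-signal host depletion: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nanosieve)
```

## The problem

Clinical and environmental sequencing libraries are dominated by host
DNA: a mock community mixed at equal molar amounts per microbial species
(six species at 6 fmol, one at 3 fmol) against 250 fmol of host DNA is
86.51% host by moles. On a nanopore flow cell every host molecule that
is sequenced to completion costs pore time that could have gone to a
microbial molecule. Adaptive sampling (Read-Until) lets software eject a
molecule mid-read by reversing the pore voltage — but the keep/eject
decision must be made from the first ~4000 raw current samples (about
one second of acquisition, ~450 bases at ~450 nt/s and 4 kHz), before
basecalling.

The decision is learnable because genomes differ in 6-mer composition
and roughly six bases reside in the pore at measurement time: each 6-mer
has its own characteristic current level, so compositional differences
between host and microbial DNA are visible directly in the raw signal.
nanosieve implements that chain of reasoning end to end on simulated
data: a 6-mer pore-model squiggle simulator, a convolutional classifier
over normalized signal chunks, cross-validation harnesses, a simulated
Read-Until loop, and the 6-mer composition/signal analysis that
motivates the classifier.

## The squiggle simulator

The simulator is deliberately the simplest model that preserves the
premise that 6-mer identity determines the expected current.

**Sequences.** A reference pool is sampled by a 5th-order Markov chain
whose conditional distribution `P(base | previous 5 bases)` is derived
from a 4096-long 6-mer weight vector, so the stationary 6-mer
composition of long sequences approximates the requested bias.
Divergence between two pools is controlled by a single dial:
`blend_kmer_bias(bias, mix)` interpolates between uniform composition
(`mix = 0`) and a Dirichlet-like random bias (`mix = 1`). Two
independent random biases at the default concentration (0.3) are
typically ~0.7 apart in total-variation distance, comfortably above the
0.5 used for the package's reference experiment.

**Signals.** For each 6-mer window the dwell is
`round(N(dwell_mean, dwell_sd))` clipped to at least one sample, and
each sample is `N(level_mean[kmer], level_sd[kmer])` picoamps,
converted to 16-bit DAC units via
`pA = (dac + offset) * range / digitisation`. Defaults: levels drawn
without ties from 60–120 pA (the working range of a MinION-like
device), `level_sd` 1.5 pA, `dwell_mean` 4000/450 ≈ 8.89 samples/base
(4 kHz at 450 nt/s), `dwell_sd` 1.5, digitisation 8192, range 1400,
offset 0. The window-to-sample map is recorded as ground truth, which
is what makes the zero-noise reconstruction test and the per-6-mer
signal analysis possible without event segmentation.

**Libraries.** Read lengths are log-normal (median 3 kb, sigma 0.5 on
the log scale, truncated to 500 b–50 kb) — a long-read regime in which
a 4000-sample decision window truncates most of a host read. Each
read's component is drawn with probability equal to its molar fraction;
channels are uniform over 1–512.

**What the simulator does not model.** Adapter/stall artifacts at read
starts, base modifications (the compositional signal, not the
modification signal, is what separates host from microbe), pore-to-pore
level drift, and event-boundary autocorrelation. Passing tests on this
generator therefore demonstrate that the architecture can exploit
composition-driven signal differences; they do not certify performance
on real flow-cell data, whose headline numbers depend on deposited
sequencing runs and device pore-time economics.

## Preprocessing

Each read contributes one chunk: samples
`[skip_samples, skip_samples + 4000)` after picoamp conversion,
normalized per chunk. The normalization the original workflow used is
not documented anywhere we could follow, so both robust median/MAD
(default; insensitive to current spikes) and z-score are provided, and
idempotence and centering are tested for both. `skip_samples` defaults
to 0 because simulated reads have no adapter; 1000–1500 is a sensible
value for real device output. Reads shorter than the window are skipped
and counted, never padded: the adaptive-sampling use case only ever
sees read starts, so multi-chunk augmentation is deliberately out of
scope.

## The classifier

Topology: a 1D convolutional stem (32 channels, kernel 19, stride 3) →
squeeze-and-excitation (SE) channel attention → three residual blocks
(32, 64, 128 channels, each two kernel-3 convolutions with batch
normalization and ReLU, stride-2 downsampling, 1×1 projection
shortcut) → a second SE block → global average pooling → a fully
connected softmax bi-classifier. The SE block squeezes each channel to
its temporal mean, passes the vector through a two-layer bottleneck
(reduction 4) with sigmoid output, and rescales the channels — cheap
channel-wise attention that emphasizes informative feature maps.

Only the topology is fixed; the layer sizes are config-overridable
(`classifier_spec()`) because common 1D-ResNet practice, not a
published table, sets them. The default network has 121,450 parameters
(regression-tested).

Two numerical choices deserve explanation:

* **All convolutions are valid (no zero padding).** Global average
  pooling makes the output defined for any admissible input length; with
  zero padding, edge effects would make even a constant input give
  slightly different probabilities at different lengths. With valid
  convolutions the length-invariance contract is exact, and it is tested
  at 4000 vs 8000 samples. The price — a few samples of context at each
  end — is negligible at 4000 samples. The projection shortcut's output
  is cropped to the main path's length (both are constant-preserving).
* **Ties classify as target.** The expensive error in host depletion is
  ejecting a rare microbial molecule; an exactly ambiguous chunk is
  therefore never rejected. The same convention is used by
  `classify_batch()` and by the Read-Until threshold (reject only when
  `p(host)` strictly exceeds the threshold, so `threshold = 1` disables
  rejection).

Training is Adam (default 1e-3) on cross-entropy, implemented with a
hand-derived backward pass verified against finite differences.
Everything — initialization, shuffling — flows from one seed, so
`squiggle_classifier()` is bit-reproducible. Batch normalization uses
batch statistics during training and running statistics at inference.

## Evaluation

AUC is computed as the Mann–Whitney probability that a random positive
outranks a random negative, ties counted one half, via average ranks;
the test suite checks it against exhaustive pair enumeration, the
trapezoid area under `roc_points()`, and an established ROC package.
K-fold cross-validation uses stratified folds (fold sizes differ by at
most one overall and per class) — plain random folds could produce a
single-class validation fold at small n. Leave-one-species-out
evaluation mixes the held-out species with an equal-sized host sample
withheld from training, because AUC needs both classes; precision takes
target (microbial) as the positive class.

## The simulated Read-Until loop

Channels 1–255 form the adaptive arm, 256–512 the untouched control
arm. An adaptive-arm read shorter than the decision window passes
through undecided. Otherwise its first 4000 samples are chunked and
classified; a rejected read emits
`min(full_length, round((decision_samples + latency_samples) / samples_per_base))`
bases. `latency_samples` (default 1000) stands for the signal acquired
between decision and pore reversal; the default puts rejected reads
near 562 bases, in the few-hundred-base regime a real device leaves
behind. Reads are independent events per channel: pore re-capture,
queuing and mux scans are not modelled, so real-device throughput gains
(read-count inflation from freed pore time) are outside what this
simulator can reproduce — the loop reports yield ratios, it does not
model pore economics.

`time_budget_check()` verifies the architectural constraint that
classification keeps up with acquisition (per-read latency below
`decision_samples / sample_rate` = 1 s at the defaults). The measured
latency is hardware-dependent and is reported, never asserted.

## 6-mer analysis

`kmer_profile()` counts forward-strand windows (reverse-complement
counting is a flag; strand treatment is a convention, not a given),
with ambiguous-base windows tallied separately.
`top_enriched()` scores `log2((freq_a * 4096 + 1) / (freq_b * 4096 + 1))` —
frequencies scaled to "counts per uniform k-mer" with pseudocount 1 so
absent k-mers never divide by zero — with lexicographic tie-breaks.
`extract_kmer_signals()` uses the simulator's ground-truth map (real-read
segmentation is a non-goal) and summarizes each 6-mer by mean current,
SD, mean dwell and a `w = 8`-point linearly resampled level trace; the
exact per-k-mer feature vector behind such analyses is a free choice,
and the resampled trace is this package's. `pca_project()` centers
(optionally scales), drops constant columns with a warning, and is
tested against a covariance eigendecomposition.

## The reference experiment

`host_depletion_experiment()` is the package's end-to-end check, sized
for a desktop CPU:

* two pools at total-variation distance ≥ 0.5 (reported, not forced);
* 2000 chunks per class at 4000 samples, 80/20 train/validation,
  5 epochs — on this generator loss saturates within a handful of
  epochs, so the 30-epoch regime appropriate for real data is not
  needed;
* training-library reads use a log-normal median of 1000 bases rather
  than the 3 kb default, since only the first chunk of each read is
  used — a compute choice that does not change what is being tested;
* a 90%-host (by moles) library of 2000 full-length reads over all 512
  channels for the adaptive phase.

Expected behavior, asserted in the test suite: held-out AUC ≥ 0.95, and
the microbial fraction of emitted bases strictly higher in the adaptive
arm than in the control arm. Typical runs give AUC ≈ 0.99 and a
three-to-five-fold increase in microbial base fraction, with rejected
reads at 562 emitted bases and a large host:microbial ratio among
rejected reads (the ratio is ∞ when no microbial read is rejected; it
is serialized as null with a flag).

## Known limitations

* The simulator's i.i.d. Gaussian event model understates the
  autocorrelation and heavy tails of real squiggles; real-data AUCs are
  lower than simulated ones.
* Absolute throughput and read-count gains of adaptive sampling depend
  on pore-time economics the loop does not model.
* The classifier is a bi-classifier; per-species identification is out
  of scope.
* Live device integration is specified only as an interface contract
  (`read_until_contract()`).
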