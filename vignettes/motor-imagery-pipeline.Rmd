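---
title: "Sorted blind source separation, wavelet scalograms, and a CNN for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorted blind source separation, wavelet scalograms, and a CNN for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipipe)
```

## The problem

Motor imagery (MI) — imagining a hand or foot movement without executing it
— modulates the sensorimotor mu (8–13 Hz) and beta (14–26 Hz) rhythms
recorded over the motor cortex. A two-class MI brain–computer interface
must decide, from a few seconds of multichannel EEG, which movement was
imagined. Two obstacles dominate: EEG channels observe unknown linear
mixtures of cortical sources and artifacts, and the discriminative rhythms
are weak relative to broadband noise.

`mipipe` implements a classification pipeline that addresses both:

1. **Blind source separation (BSS)** per trial and per hemisphere cluster
   recovers estimated sources $s'(t) = B\,x(t)$ from the observed mixture
   $x(t) = A\,s(t)$.
2. **Spectral-template sorting** repairs the one thing BSS cannot provide:
   a stable ordering. Separation matrices are only identified up to
   permutation and scale, so the same physiological source lands in a
   different row on every trial. Each estimated source is scored by the
   Pearson correlation between its normalized power spectrum and a fixed
   movement-related independent component (MRIC) template concentrated in
   the mu and beta bands; sources are stacked in descending score order, so
   rhythm-rich components occupy stable top positions and artifacts sink.
3. **Time–frequency imaging**: each sorted source is transformed with an
   analytic generalized Morse wavelet over 1.0-s windows advanced in
   0.25-s steps; per window, the per-source scalograms are stacked
   vertically (left cluster above right) and resized to a 128×256 image.
   The vertical axis therefore carries frequency-by-source (spatial)
   information and the horizontal axis carries time.
4. **A small CNN** classifies the images; a k-fold harness summarizes
   accuracy.

## Source separation

Both separation back ends first whiten the data (eigendecomposition of the
channel covariance; rank deficiency is an error, since a duplicated channel
makes separation ill-posed).

* `fastica()` is the fixed-point algorithm that maximizes the sum of
  marginal negentropy approximations — equivalently, minimizes mutual
  information after whitening. The default contrast is `tanh` in symmetric
  mode (all rows updated then re-orthonormalized each step), tolerance
  `1e-4` on row directions, at most 200 iterations, with a seeded random
  orthonormal initialization. Non-convergence is reported in the result
  (`converged = FALSE`), never thrown: a hard trial must not abort a
  session. A deflation mode (one component at a time, Gram–Schmidt) is
  available for comparison.
* `sobi()` uses only second-order statistics: it jointly diagonalizes
  symmetrized time-lagged covariance matrices of the whitened data with
  Jacobi rotations. It identifies sources with distinct spectra (even
  Gaussian ones), but is blind to temporally white sources. The operation
  default uses lags `1..min(100, n/3)`; the pipeline passes
  `1..min(30, n/3)` (0.3 s at 100 Hz), which covers mu/beta
  autocorrelation at a third of the cost. The robust-orthogonalization
  SOBI variant is not implemented; plain SOBI stands in for the
  second-order family.

Separation quality is always judged with the permutation- and
scale-invariant Amari index (`amari_index()`), never by raw matrix
comparison, because of the inherent permutation/scale indeterminacy. The
test suite confirms the textbook dichotomy: the negentropy-based method
wins on i.i.d. non-Gaussian sources, the second-order method on Gaussian
sources with distinct spectra.

The number of estimated components always equals the number of input
channels (9 per cluster with the default montage), and BSS runs per trial
and per cluster. Running the 18 channels jointly is possible by passing a
single-cluster montage, but the default mirrors the per-hemisphere layout
of the stacked images.

## The MRIC template and the sort

No standard numerical definition of the MRIC spectrum exists, so the
package defines a concrete, overridable template: the sum of two Gaussian
bumps, one at 10.5 Hz (sd 1.5 Hz, the mu peak) and one at 20 Hz (sd
3.5 Hz, amplitude ratio 0.6, the broader beta peak), normalized to unit
area on a 0.5–45 Hz grid with 0.5 Hz spacing. Frequencies above 45 Hz are
excluded on purpose: broadband muscle activity would otherwise dominate
the correlation. A custom template can be supplied as a two-column text
file (`read_template()`).

```{r template, fig.width = 6, fig.height = 3, eval = requireNamespace("ggplot2", quietly = TRUE)}
ggplot2::autoplot(default_template())
```

Source spectra are estimated with Welch's method (Hann taper, one-second
segments, 50% overlap — stable for 3.5-s trials), interpolated onto the
template grid, and normalized to unit area. Scores are Pearson
correlations of *linear* power with the template; log-power is a
conceivable alternative, but linear power weighs the band peaks more
heavily, which is what the sort is for. Sorting is stable (ties keep their
original order), and a constant (dead) source scores `-Inf` and sinks to
the bottom rather than raising an error. Sorting happens per cluster; the
left cluster's sorted block is stacked above the right cluster's.

## Wavelet images

The continuous wavelet transform uses generalized Morse wavelets — the
analytic family supported on positive frequencies only — with shape
parameters $\gamma = 3$, $\beta = 20$ (the standard symmetric choice) and
12 voices per octave, implemented in the frequency domain with
zero-padding to a power of two. The frequency axis spans 1 Hz to
$0.45\,f_s$ logarithmically. For a pure tone, the time-averaged magnitude
ridge falls within one voice of the tone frequency (a property the test
suite sweeps over 5/10/20/40 Hz).

Windows of 1.0 s advance in 0.25-s steps, giving
$\lfloor (T - 1)/0.25 \rfloor + 1 = 11$ windows for a 3.5-s trial. Every
window of every trial becomes one training sample, inheriting the trial's
class label — an 11-fold data amplification that keeps desk-scale training
sets usable. Each stacked map is bilinearly resized to 128 rows × 256
columns and min–max normalized to $[0,1]$ (a constant map maps to zeros).
Magnitude (not squared or log power) is imaged.

## The classifier

The reference architecture (`architecture_spec()` defaults) is, for a
128×256×1 input:

| stage | operation | output |
|---|---|---|
| conv 1 | 250 filters, kernel (3,1), stride (2,1), ReLU | (63, 256, 250) |
| pool 1 | max-pool (4,4) | (15, 64, 250) |
| conv 2 | 150 filters, kernel (1,2), stride (1,1), ReLU | (15, 63, 150) |
| pool 2 | max-pool (3,3) | (5, 21, 150) |
| flatten | | 15750 |
| dense | 2048, ReLU, dropout 0.4 | 2048 |
| output | dense 2, softmax | 2 |

All convolutions use valid padding and pooling uses floor division; this
is the only arithmetic under which the chain above is self-consistent, and
it requires conv 1 to downsample the vertical (frequency × source) axis
only — horizontal stride 1 preserves temporal resolution. The first
kernel (3,1) looks across neighbouring frequency/source rows; the second
(1,2) across neighbouring time steps. `shape_propagation()` computes the
chain analytically and refuses architectures that collapse a dimension.

Convolution and pooling forward/backward passes are compiled (C++), the
rest is plain R linear algebra. Training is minibatch softmax
cross-entropy with Adam (default) or SGD; weights are He-initialized from
a seed, dropout masks and any shuffling are drawn from the training seed,
and a fixed data order makes runs bit-reproducible. `train()` records
per-epoch train/validation accuracy and loss, and stores per-epoch
parameter snapshots.

At full scale this network has ~33 M parameters — far more than a
desk-scale synthetic experiment needs or can train in reasonable time, so
`reduced_architecture_spec()` keeps the exact layer structure, kernels,
strides and pools but uses 8 + 8 filters and a 32-unit dense layer. All
synthetic experiments in the tests and the worked examples use the reduced
network; the full specification is retained as the default and for shape
analysis.

## Evaluation protocol

`evaluate_kfold()` splits the *test* set into k contiguous, nearly equal
parts (remainder to the first parts). In `"max"` mode each part reports
its best accuracy over the stored per-epoch checkpoints — an optimistic
protocol (picking the best epoch per fold inflates scores), which is why a
`"plain"` mode (final parameters only) is also provided; in plain mode the
pooled correct count over folds equals the overall correct count exactly.
Fold dispersion uses the sample standard deviation. `summarize_report()`
pools reports: the overall mean averages all fold accuracies, the overall
standard deviation averages the per-report standard deviations. Values are
kept at full precision and displayed to two decimals.

The train/test split in `run_pipeline()` is 50/50, stratified by class
and made at the *trial* level, so the 11 windows of one trial never
straddle the split (that would leak near-duplicate images across it).

## The synthetic generator

Real MI recordings cannot ship with a package; the generator produces
datasets with the statistical structure the method assumes, plus ground
truth for oracle testing:

* Per hemisphere cluster, nine sources: one mu burst (10.5 ± 2.5 Hz), one
  beta burst (20 ± 6 Hz), line interference, blink-like transients, and
  five 1/f-noise sources. Band-limited sources are white noise,
  amplitude-modulated by 1–3 Hann burst envelopes (0.5–1.5 s) over a 0.2
  baseline, then band-pass filtered — filtering after modulation keeps
  spectral confinement governed by the filter (an 8th-order Butterworth,
  chosen so at least 80% of output power falls inside the declared band).
  Blinks are asymmetric double-exponential pulses (rise 40 ms, decay
  180 ms) at ~0.3 Hz; pink noise is spectrally shaped white noise.
* Class structure is event-related desynchronization: imagining the
  movement contralateral to a hemisphere attenuates that hemisphere's mu
  source (gain 0.5) and, more mildly, its beta source (gain 0.7); gains
  are mirrored between clusters. The waveform draw is label-independent,
  so the two classes of a given seed differ exactly by these amplitude
  factors.
* Each cluster is mixed by its own random Gaussian matrix,
  rejection-sampled until its condition number is below the configured cap
  (default 20); ground-truth sources and mixing matrices are retained, so
  tests can verify that the true inverse recovers sources to numerical
  precision.
* Defaults: 100 Hz sampling, 3.5-s trials, 9 channels per cluster named
  after the sensorimotor electrode clusters (FC5…CP1 left, FC2…CP6
  right). The line-interference source sits at 40 Hz — a sub-Nyquist
  stand-in for mains interference, since 50/60 Hz is not representable at
  the desk-scale sampling rate.

What the generator does *not* emulate: volume conduction with a head
model, nonstationary mixing, inter-subject variability, electrode drift,
or real artifact morphologies. Mu/beta bursts here are filtered Gaussian
noise — mildly super-Gaussian through their envelopes but far tamer than
real EEG artifacts. Consequences for interpretation: a passing test suite
shows the pipeline's machinery is correct and that sorting restores
order-stability under the assumed mixture model; it does not certify
real-data accuracy. One visible consequence: on these Gaussian-dominated
mixtures the second-order back end separates about as well as the
negentropy-based one, whereas on real EEG (with strongly non-Gaussian
artifacts) higher-order methods typically lead.

## Desk-scale experiment sizes

The packaged experiments (tests and the ablation comparison) use 10
trials per class, the reduced architecture, 12 training epochs, batch 16,
learning rate 2e-3, and 5 dataset seeds, with the mean validation accuracy
over the second half of training as the arm statistic; a three-arm
comparison at this scale takes on the order of ten minutes on one core. These sizes are the
package's desk-scale reference configuration: large enough that the
sorted arm separates from the unsorted one in the median over seeds,
small enough to re-run routinely.

## Determinism

Every stochastic step (source draws, mixing, ICA initialization, weight
initialization, dropout, shuffling) derives its seed from a configured
seed via a stable hash; RNG state is restored after use. Identical
configurations therefore reproduce identical datasets, identical models,
and byte-identical report files.

## Known limitations

* Per-trial ICA at 100 Hz sees 350 samples for a 9×9 unmixing problem —
  near the identifiability floor; estimates are noisy and some trials do
  not converge (they are still used, flagged).
* The MRIC template is a stylized two-bump construction, not an estimate
  from data; `read_template()` exists precisely so users can replace it.
* The max-over-epochs evaluation mode reproduces an optimistic published
  protocol; plain mode should be preferred for honest comparisons.
* `write_edf()`/`read_edf()` implement the 16-bit continuous-recording
  core of EDF only (no EDF+ annotations, uniform sampling rate).

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synthetic = synthetic_config(n_trials_per_class = 10, seed = 501),
  filter_band = c(0.5, 45),            # high edge below Nyquist at 100 Hz
  bss = "fastica", sorting = "mric",
  architecture = reduced_architecture_spec(),
  training = train_config(epochs = 16, batch_size = 16, learning_rate = 2e-3),
  k = 10, seed = 201)
run <- run_pipeline(cfg, "runs/sorted")
run$report          # per-fold accuracies, mean, std
tidy(run$report)    # tibble: fold, accuracy
```
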