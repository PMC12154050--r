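---
title: "Connectogram-COH: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectogram-COH: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical and design choices made where more
than one reasonable option existed.

## The representation

An EEG recording is a multivariate time series on $c$ electrodes. The
package turns it into a sequence of functional connectivity graphs and
renders that sequence as a grayscale image:

1. **Segmentation.** Recordings are cut into fixed-length, non-overlapping
   segments (10, 20 or 30 s). Each segment is an independent
   classification sample carrying its subject's label. Trailing remainders
   are dropped: segment counts are `floor(duration / length)`, and a
   recording shorter than one segment yields an empty list with a warning
   rather than an error, so cohort-level loops keep going.
2. **Sliding windows.** Within a segment, a 0.4 s window advances in 0.2 s
   steps (50 % overlap). Window starts form an arithmetic sequence in
   samples; the count is $\lfloor (L - w)/s \rfloor + 1$, which at 500 Hz
   gives 149, 99 and 49 windows for 30, 20 and 10 s segments.
3. **Per-window graph.** Every unordered channel pair gets the
   band-averaged magnitude-squared coherence (MSC) of that window,
   producing a symmetric $c \times c$ adjacency with unit diagonal and
   entries in $[0,1]$.
4. **Flattening and tiling.** The strictly-upper triangle
   ($c(c-1)/2$ values; 171 for the 19-channel 10–20 montage) becomes one
   pixel column; columns are tiled left to right in window order.

The image is therefore a *dynamic* connectivity portrait: rows index
channel pairs, columns index time, intensity is synchrony strength.

### Assumptions

* Coherence is a linear, stationary-within-window measure. The 0.4 s
  window length assumes synchrony is roughly stationary at that scale.
* Channel order is fixed and canonical (`eeg_channels_1020`): pixel-row
  identity depends on it, so `select_channels()` defines the order for
  everything downstream.
* No re-referencing, filtering or artifact rejection happens at read time;
  an optional 0.5–45 Hz order-4 zero-phase Butterworth band-pass
  (`bandpass_recording()`) exists but is off by default. Preprocessing is
  the caller's responsibility.

## Spectral estimation choices

MSC is estimated per window by Welch averaging. The transform definition
fixes the window (0.4 s) and overlap (50 %) but not the estimator inside
the window, so the estimator settings are the package's own choices, all exposed in
`spectral_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `subwin_samples` | 100 | samples | a 0.4 s window at 500 Hz is 200 samples; 100-sample sub-segments at 50 % overlap give $M = 3$ averaged periodograms and 5 Hz resolution |
| `subwin_overlap` | 0.5 | fraction | standard Welch compromise between variance and leakage |
| `taper` | Hann (periodic) | — | sidelobe suppression for short segments |
| `band` | (0.5, 45) | Hz | the conventional delta-to-gamma EEG range; DC bin always excluded |
| `detrend` | constant | — | removes per-sub-segment DC offsets that would inflate low-frequency coherence |

Three numerical rules are enforced rather than configurable:

* **$M \ge 2$ is mandatory.** With a single averaged sub-segment the MSC
  estimator is identically 1 regardless of the data; requesting it is an
  estimation error, not a value.
* **Zero-variance inputs are errors** (the denominator $P_{xx}P_{yy}$
  vanishes), reported with the offending channel name.
* **Values are clamped to $[0,1]$** after the ratio; by Cauchy–Schwarz the
  exact quantity is already in range, so this only absorbs last-bit
  rounding.

**Scalar reduction.** The per-frequency MSC must be collapsed to one
number per pair; the reduction is not specified by the transform itself.
The package uses the unweighted mean over the inclusive analysis band,
excluding DC. A band mean (rather than, say, the peak) is stable under the
coarse 5 Hz grid of a 0.4 s window and keeps the estimator linear in the
spectrum; sub-band variants (e.g. alpha-only images) are a one-argument
change.

**Estimator bias, quantified.** For independent Gaussian channels the
Welch MSC estimator has the known small-sample expectation $\approx 1/M$;
with the default $M = 3$ the background of an image of uncoupled channels
sits near 0.33, not 0. For a pair sharing one source with per-frequency
signal-to-noise ratio $\rho$, the large-$M$ limit is
$(\rho/(1+\rho))^2$. Both facts are used as analytic oracles in the test
suite: the first checked by Monte-Carlo over windows, the second with a
wide-band source so that $\rho$ is flat across the analysis band. A
brute-force MSC implementation (`oracle_msc()`, explicit loops and direct
Fourier sums, no shared code) pins the fast path to $10^{-10}$.

**Sources are filtered noise, not sinusoids.** The synthetic latent
sources are white Gaussian noise band-limited by a zero-phase FFT brick
wall. Sinusoidal sources would concentrate power in single bins and make
band-averaged MSC degenerate at line frequencies; band-limited noise keeps
the estimate stable across the averaging band.

## Image conventions

* Row order is the row-major strictly-upper pair order
  $(1,2), (1,3), \dots, (c-1,c)$, recorded in the image's `pair_order`
  metadata. The flattening order is otherwise arbitrary but must be fixed
  and documented for pixel rows to be comparable across images.
* The float image is canonical and is what classifiers consume. The 8-bit
  PNG export quantizes with `floor(v * 255 + 0.5)` (error at most 1/510
  per pixel) and exists for inspection and interchange. Feeding float
  rather than quantized images to the classifier avoids a needless 8-bit
  floor on contrast.
* No per-image normalization: coherence is already bounded, so grayscale
  is absolute and intensities are comparable across images, subjects and
  classes.
* The lossless on-disk container is an `.rds` file holding the float
  matrix and all metadata, the natural R serialization; EDF (16-bit,
  standard physical/digital scaling) is supported for recordings.

## Classifier architectures

Both classifiers run on a small conv-net engine written in R for this
package (im2col + BLAS matrix products, Adam, batch normalization,
residual blocks). Every backward pass is verified against central finite
differences in the test suite, and the engine is seeded end to end, so
training is bit-reproducible on a single-threaded BLAS.

**Custom CNN.** The reference layer shapes (171×149 → 169×147 → 84×73 →
82×71 → 41×35 → 39×33 → 19×16 → 38 912) force unpadded 3×3 convolutions
with stride 1 and 2×2 max-pools with floor division. Activation functions
are not part of the shape listing; ReLU after each convolution and after the 128-unit dense
layer is the standard completion.

**Shallow ResNet.** The reference shapes dictate something unusual: the
input is (171, 149) with no trailing channel axis, and the first
convolution maps 171 → 86 with 64 filters. The network therefore treats
the *pair axis* as the 1-D sequence and the *window axis* as input
features. Fidelity to the reference listing wins over convention here; it also
means the ResNet is insensitive to segment length only through its feature
dimension. 171 → 86 with kernel 3, stride 2 requires "same" padding
(TensorFlow convention, extra pad on the right). The residual blocks are
the standard minimal completion of "2× Conv + Add": conv–BN–ReLU–conv–BN
on the main path, identity shortcut when shape is preserved, 1×1 strided
projection + BN when filters change or the block downsamples, ReLU after
the addition.

**Parameter count.** The two architectures differ by an order of
magnitude: the CNN's 38 912 → 128 dense layer alone is ~5 M weights,
while the ResNet as built here has ~0.47 M
(`n_parameters(build_model(model_spec("shallow_resnet", c(171, 149), 3)))`).
A compact sub-million figure sometimes quoted for models of this family
matches neither listing; parameter count is treated as informational, not
as a contract.

**Unstated training details** default to: Adam at $10^{-3}$, categorical
cross-entropy, batch size 8, 50 epochs — small-to-moderate batches, the regime in
which these images are classified most reliably. All
are configurable in `train_config()`.

## Subject-wise evaluation

Fold assignment happens at the *subject* level, before segmentation, so
segments of one subject can never straddle the train/test boundary;
non-overlapping segments remove the residual similarity leak between
neighbouring samples. The package enforces this twice: fold assignment
partitions subjects by construction, and `subject_wise_cv()` re-asserts
disjointness on every fold (`assert_disjoint_subjects()`), failing hard on
violation. Fold assignment is stratified by class label — not required by
the protocol, but it keeps class balance across folds and is standard
practice. Within each training fold, 10 % of training subjects (at least
one, and never so many that a class disappears from training) are held out
subject-wise for the per-epoch validation curve. The image transform has
no fitted parameters, so per-fold preprocessing independence holds
structurally — there is nothing to leak through a shared normalizer.

## The synthetic cohort: what it shows and what it does not

`default_cohort_spec()` defines the study conditions used by the test
suite and the acceptance script: two classes on the 19-channel, 500 Hz
montage, six subjects per class, 60 s per recording. Class `frontal`
couples the seven frontal electrodes through one shared 4–30 Hz source;
class `occipital` couples the seven posterior electrodes; independent unit
noise everywhere. These sizes keep the full study — 72 images of 171 × 49,
five training runs of 20 epochs at batch size 8 — at about a minute of
desktop CPU while leaving the planted contrast clearly recoverable
(coupled-pair coherence ≈ 0.8 against a ≈ 0.33 bias floor).

The generator emulates the *shape* of a real cohort (multiple subjects and
classes, montage, sampling rate, minutes-long recordings, class-specific
connectivity) and gives every stage an analytic ground truth. It does not
emulate eye-blink or muscle artifacts, volume conduction (which induces
spurious zero-lag coherence between neighbours), 1/f spectral shape, or
inter-subject variability of the coupling itself; subjects within a class
differ only through noise realizations. Consequently a perfect synthetic
cross-validation score validates the machinery — transform correctness,
leakage freedom, optimizer and architectures — and says nothing about
clinical accuracy on recorded EEG. Dataset-scale clinical accuracies
(99+ % on the open 88-subject three-class dementia cohort, OpenNeuro
ds004504) require that dataset and GPU-scale training; they are
deliberately not reproduced at this scale, and the property-based suites
above stand in for them.

## Degenerate inputs and tie-breaks

* Max-pool tails that do not fill a pool are dropped (floor semantics, as
  the reference CNN shapes require); max-pool ties take the first maximum.
* Softmax class ties in prediction take the first class in sorted label
  order.
* `flatten_upper()` rejects matrices asymmetric beyond $10^{-9}$; the
  adjacency constructor symmetrizes its own rounding ($ (A + A^T)/2 $)
  before the diagonal is set to exactly 1.
* Seconds-to-samples conversion uses round-half-up, exact at 500 Hz
  (0.4 s → 200, 0.2 s → 100) and well defined at any other rate.
* One global seed expands to per-subject, per-fold and per-stage sub-seeds
  through a fixed counter scheme, so each subject's recording is
  reproducible independently of generation order.

## Known limitations

* The conv-net engine is single-threaded R; it is sized for the package's
  validation studies, not for training on large cohorts.
* EDF support covers continuous 16-bit recordings with a uniform sampling
  rate; EDF+ annotations and per-signal rates are out of scope.
* Resampling is not provided; recordings at other rates are accepted and
  window lengths are converted via rounding, which changes the Welch
  sub-segment count unless `spectral_config()` is adjusted accordingly.
* Alternative connectivity metrics (PLV, imaginary coherence, amplitude
  envelope correlation) are not implemented; the adjacency stage is the
  single place they would plug in.
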