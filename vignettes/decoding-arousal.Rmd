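---
title: "Decoding continuous emotional arousal from alpha-band EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding continuous emotional arousal from alpha-band EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arousalpha)
```

## The scientific problem

During a naturalistic, continuously unfolding experience, the intensity of
subjective emotional arousal covaries — inversely — with the power of the
8–13 Hz alpha rhythm over parieto-occipital cortex. `arousalpha`
implements a complete analysis chain for testing that link in single
subjects: a continuous 0–100 arousal rating (sampled once per second) is
related to the amplitude dynamics of narrowband alpha sources extracted
from 30-channel scalp EEG. Three complementary decoders are provided:

* **SPoC** (source power comodulation): a supervised spatial decomposition
  whose criterion is the covariance between a component's per-second
  alpha-band variance and the continuous rating.
* **CSP** (common spatial patterns) + shrinkage LDA: binary decoding of
  the most vs least arousing seconds (tertile split, mid discarded).
* A small **LSTM** sequence classifier trained directly on 1-s epochs of
  the alpha-band component time courses.

Because the human recordings the design emulates cannot be redistributed,
the package ships a generative stand-in with known ground truth, so that
every stage — filters, spectra, decompositions, cross-validation schemes,
permutation tests — is verifiable end to end.

## The generative model

`generate_subject()` draws one subject from the following model, with the
experiment's structure fixed by `synth_config()` defaults: a 270-s
experience at 250 Hz over 30 channels, split into two "rides" (148 s and
92 s) around a 30-s low-arousal break.

1. **Rating trace.** A Gaussian random walk, smoothed with an 8-s kernel,
   scaled to an SD of 14 rating units, shifted by per-phase offsets
   (ride 52, break 20, second ride 62 — the second ride most arousing,
   the break least), clipped to [0, 100] and quantized to the 50-step
   dial grid. The offsets and SD give cross-subject rating means and
   spreads in the mid-40s with SDs near 12–14 units, matching what a
   seated rollercoaster-style experience plausibly produces. The
   smoothing bandwidth is a config knob (`rating_smooth_s`) because the
   autocorrelation of real rating traces is not pinned down by the design.
2. **Arousal-coupled alpha source.** Band-limited Gaussian noise in
   `alpha_peak_hz` ± 2 Hz whose per-second amplitude envelope is
   `1 − κ · z01(t)`, with `z01` the min–max-normalized rating and
   `κ = coupling_kappa ∈ [0, 1]`. The coupling is linear in the
   normalized rating: the hypothesis under test is a monotone inverse
   relation, not a specific functional form, so the simplest monotone
   parameterization is used. `κ = 0` is the null model.
3. **Distractor alpha sources.** Three additional narrowband sources with
   peaks jittered within ±0.5 Hz of the subject's alpha peak, each with a
   distinct scalp pattern. They make the component-selection rule and the
   four-component CSP feature set meaningful (with a single alpha source
   both would be degenerate by construction). They are
   amplitude-stationary on purpose: any slow envelope modulation would
   correlate spuriously with the (slow) rating trace over a 270-s record
   and contaminate the null model.
4. **Aperiodic background.** Eight 1/f^b noise sources (`b = 1.5`),
   mimicking the broadband background that dominates EEG spectra.
5. **Mixing and noise.** Sources project to the sensors through smoothed
   random unit-norm patterns; alpha-source patterns carry a
   parieto-occipital emphasis (no lead-field model is in scope).
   White Gaussian sensor noise (1 µV SD) is added; aperiodic structure is
   already carried by the background sources.

What the generator does **not** emulate: ocular/muscular artifacts, head
movement, volume-conduction physics, non-stationary background spectra,
or between-subject alpha-frequency variability beyond the configured
peak. Passing tests therefore certify the *analysis machinery* — correct
decompositions, leakage-free cross-validation, calibrated null models,
recovery of planted structure — not performance on real recordings.

## Preprocessing rules

* `crop_experience()` removes the first and last 2.5 s of each ride and
  centre-crops the break to 30 s (raw input), yielding the analysed 270-s
  record; `include_break = FALSE` drops the break (240 s). Cropping marks
  its output and is idempotent on already-cropped data.
* `resample_ratings()` averages non-overlapping 50-sample windows of the
  50-Hz dial signal to 1 Hz.
* `screen_epochs()` flags 1-s epochs exceeding ±100 µV on any channel
  except the frontal set (Fp1, Fp2, F7, F8); `exclude_subject()` drops a
  subject with more than 90 flagged epochs (a third of the record). The
  flags feed only the exclusion rule — decoding always uses the full
  epoch set, since artifact repair itself is out of scope.
* `tertile_labels()` is a rank-based split with stable ties (earlier
  epoch → lower tertile), guaranteeing 90/90/90 classes at 270 epochs.
  Remainders at other lengths go to the low, then the high class.

## Spectral parameterization and SSD

Per-channel spectra use Welch's method (5-s Hann segments, 50 % overlap,
density scaling). The aperiodic component is the least-squares line in
(log f, log p) over 0–40 Hz, excluding ±4 Hz around the candidate alpha
peak; natural logarithms are used throughout (the choice only rescales
thresholds consistently). The individual alpha peak is the argmax of the
detrended residual in 8–13 Hz. No minimum prominence is enforced; a
low-prominence argmax (residual below 0.05) triggers a warning rather
than an error, and boundary argmaxima are returned as-is. Because the
planted sources are band-limited with ±2 Hz flat passbands, the detrended
argmax can sit anywhere on the plateau, typically near its upper edge;
the downstream ±2/3/4 Hz bands comfortably cover the true sources either
way.

SSD contrasts the signal band (peak ± 2 Hz) against flanking noise
(± 4 Hz band-passed, ± 3 Hz band-stopped) via the generalized
eigenproblem of the two covariances, posed directly as (Cs, Cn) after
rank-truncating whitening of Cn (eigenvalue ratio 1e-10): this matches
the "maximize signal, minimize noise" reading and yields the same
eigenvectors as the (Cs, Cs+Cn) form with monotonically related
eigenvalues. All band filters are zero-phase Hamming-windowed sinc FIRs
with a 1-Hz transition band, applied to the continuous signal before
epoching.

Component selection applies two criteria to each component's detrended
log-residual spectrum: (A) the peak inside the alpha window must exceed
0.35, and (B) after z-scoring the residuals over the whole 0–40 Hz fit
range, the window peak must exceed the larger of the two adjacent 2-Hz
flank means by at least 1.45 SD. The units of the criterion-A constant
are ambiguous in the source material (it is applied after log
detrending), so the threshold is exposed as a parameter with 0.35 on the
natural-log residual scale as the default; the z-scoring range for
criterion B is likewise a parameter defaulting to the full fit range.
Decoders run only for subjects with at least four selected components.

## SPoC

With per-epoch covariances `C(e)` of the selected, signal-band-filtered
components and the z-scored rating `z`, SPoC solves the generalized
eigenproblem of `(mean_e z(e) C(e), mean_e C(e))`. Filters are
normalized to unit variance under the mean covariance, so each
eigenvalue λ equals the covariance between `w' C(e) w` and `z` — a
self-consistency contract the tests verify to 1e-6. The retained
component is the one with the smallest (most negative) λ;
`z_est(e) = w' C(e) w` and its Pearson correlation `r` with `z` are the
subject-level outcome. Significance uses phase-randomized surrogates of
`z` (identical Fourier amplitude spectrum, hence identical
autocorrelation; DC and Nyquist bins preserved): each of the `n_perm`
surrogates re-runs the *full* decomposition, and
`p = (#{r_perm < r_obs} + 1) / (n_perm + 1)` — lower-tail by hypothesis,
with the +1 correction avoiding p = 0. The group-level test is a
one-tailed one-sample t-test on per-subject differences between `r` and
the mean of that subject's own null (the difference-based form; the
alternative of a single pooled constant is less faithful to per-subject
null levels).

## CSP, cross-validation, and null models

CSP solves the eigenproblem of (C_high, C_high + C_low) on class-mean
covariances (means of per-epoch covariances — standard practice and
robust given equal epoch lengths). Features are the log-variances of the
two most "high" and two most "low" components; the classifier is LDA
with Ledoit–Wolf analytic shrinkage of the pooled covariance.

Two evaluation schemes are provided:

* **Randomized 10-fold CV** (accuracy = 1 − misclassification rate).
  Folds are stratified by class — with 90 + 90 epochs unstratified folds
  can degenerate; the stratification choice is flagged as such.
* **Sub-blocked chronological 10-fold CV** (ROC-AUC, high = positive
  class, scores = signed LDA decision values). The 180 retained epochs
  are split into three chronological sub-blocks; fold f's test set
  concatenates the f-th consecutive 6-epoch chunk from each sub-block
  (chunk = N/(10·3)); remainders at awkward N are appended to each
  sub-block's final chunk to preserve the partition property. SMOTE
  (k = 5 minority neighbours, convex combinations) balances only the
  training features; test sets stay unbalanced.

The block-permutation null shuffles ten contiguous label blocks as units,
preserving local autocorrelation, and recomputes the sub-blocked AUC per
permutation; p-values are upper-tail with the +1 correction. Because the
permutation loop re-runs the entire CV 200–1000 times, the standard
metric path is also implemented in compiled code
(`csp_block_permutation()`); the R and compiled routes are checked
against each other in the test suite on folds where SMOTE is inactive.

## LSTM decoder

The third decoder is a sequence classifier over the 270 × 250 × 10 epoch
tensor (component slots beyond those available are zero vectors;
mid-tertile rows dropped, labels −1/+1): one or two LSTM layers consume
the 250 samples of an epoch, the final hidden state passes through one
or two fully connected layers (ReLU or ELU) into a scalar tanh output,
trained with MSE loss and Adam on shuffled mini-batches of 9 for 20
passes. Layer sizes come from {10, 15, 20, 25, 30, 40, 50, 65, 80, 100}
with a bottleneck constraint, regularization is L1/L2 with strengths
{0, 0.18, 0.36, 0.72, 1.44}, and learning rates {1e-2, 1e-3, 5e-4}. A
two-step random search (`lstm_random_search()`) draws configurations on
a subject subset, pools the two best per subject and evaluates the pool
everywhere. Implementation notes:

* The network is implemented in RcppArmadillo (forward pass plus full
  backpropagation through time); the module contract is at the
  architecture/loss/optimizer level, not the framework level.
* Component slots are rescaled by their training-set SD (no centring, no
  per-epoch normalization) so amplitude information — the signal the
  decoders rely on — is preserved while gate activations stay in range.
* Gradients are clipped at global norm 5 for stability at the largest
  learning rate; forget-gate biases start at 1.
* An output of exactly 0 maps to the positive class (a measure-zero
  event that still needs a deterministic rule).
* Cross-validation reuses the same stratified 10-fold split object as
  the CSP decoder, so per-subject accuracies are directly comparable;
  the fold count for the search is a parameter since nothing in the
  design fixes it.

## Statistical evaluation

Per subject: exact binomial tests (two-sided by default, one-sided by
flag; sidedness is not fixed by the design, and two-sided is the
conservative default) on pooled CV predictions against 0.5. Per group:
upper-tail one-sample t-tests of mean accuracies against 0.5; a 2 × 2
within-subject ANOVA (model × condition) on accuracies; two-sided paired
t-tests for the break-exclusion control; pairwise Pearson correlations
between per-subject model performances with Bonferroni correction.
Degenerate inputs follow explicit rules: all-zero difference vectors
return t = 0 (p = 1 two-sided, 0.5 one-sided) rather than NaN, zero
effect sums of squares give F = 0, and constant metric vectors raise
errors rather than silently producing NaN correlations.

The break-exclusion control (`run_break_exclusion_control()`) reruns
labelling, SPoC and CSP (sub-blocked CV + block permutation) on the
240-s break-free record, refitting SSD on that record, and emits paired
with/without metrics.

## Numerical and scale choices

Cohort-level checks in the tests and the acceptance script run at desk
scale: 100 simulated null subjects with 200 permutations each for
calibration (empirical α at 0.05 must stay within [0.01, 0.10], and the
p-value distributions pass a KS test against uniformity), 20 planted
subjects (κ = 0.8, high in-band SNR) for recovery, and 10 training seeds
for the LSTM checks. Seeds fan out from a single cohort seed through a
counter-based derivation (`derive_seed()`), keeping every stream
reproducible and below R's 32-bit integer limit.

## Known limitations

* Spatial patterns are synthetic smoothed weights, not lead-field
  projections; pattern-recovery similarity is meaningful relatively, not
  as a topographic claim.
* The alpha-peak detector inherits the plateau bias described above for
  flat-passband sources; on real spectra with peaked alpha bumps the
  argmax behaves conventionally.
* The generator's null model is stationary by design; real EEG
  non-stationarities can inflate randomized-CV accuracy, which is
  precisely why the sub-blocked CV and block-permutation null are the
  stringent evaluation path.
* EDF/BrainVision/HDF5 I/O is out of scope in this implementation;
  recordings, spectra, labels and results serialize to CSV and JSON.
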