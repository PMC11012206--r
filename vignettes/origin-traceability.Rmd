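---
title: "Multi-block spectral fusion for origin traceability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block spectral fusion for origin traceability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrafuse)
```

## The problem

Geographic origin leaves a chemical fingerprint in food products: growing
region shifts the concentrations of organosulfur compounds, lipids,
carbohydrates and water, and those shifts are visible as small
class-dependent changes in absorption-peak heights in cheap, non-destructive
spectra. A single instrument often does not carry enough information — some
constituents absorb in the ultraviolet, others in the mid-infrared — so a
standard chemometric strategy is to measure each sample on two instruments
and fuse the blocks before classification.

`spectrafuse` implements that strategy end to end for a five-region
origin-authentication design with 225 samples: UV-Vis spectra on a
190–700 nm grid at 1 nm (511 variables) and mid-infrared spectra on a
400–4000 cm⁻¹ grid at 10 cm⁻¹ (361 variables), one origin label per sample.

The modeling chain is

1. **per-spectrum preprocessing** — SNV, MSC or Savitzky–Golay smoothing;
2. **a stratified 70/30 train/test split** shared by every model compared;
3. **genetic-algorithm (GA) selection of characteristic wavelengths**,
   scored by cross-validated accuracy on the training partition only;
4. **low-level data fusion (LLDF)** — column-wise concatenation of the
   preprocessed blocks, rows aligned by sample ID;
5. **four classifier families** — RBF support-vector classification,
   random forest, a single-hidden-layer feedforward network, and
   gradient-boosted trees;
6. **confusion-matrix evaluation** with per-class TP/TN/FP/FN, precision and
   recall.

## The synthetic cohort

No public spectra accompany the design the package targets, so the package
ships a first-class generator whose defaults *are* the study conditions.
Sample `i` of class `c` on axis `t` (with `t~` the axis rescaled to [0, 1])
is

```
x_ij = a_i + c_i * t~_j
     + b_i * sum_k (A_k + delta_kc + eta_ik) * exp(-(t_j - mu_k)^2 / (2 w_k^2))
     + eps_ij
```

with log-normal multiplicative scatter `b_i = exp(N(0, scatterSigma^2))`
(log-normal so gains stay positive), additive offset
`a_i ~ N(0, offsetSigma^2)`, linear baseline slope `c_i ~ N(0, slopeSigma^2)`
over the [0, 1]-rescaled axis (so slope magnitudes are comparable between a
510 nm-wide and a 3600 cm⁻¹-wide block), per-sample per-peak amplitude
jitter `eta ~ N(0, ampJitterSigma^2)` and white measurement noise
`eps ~ N(0, noiseSigma^2)`. This is deliberately the *minimal* model under
which SNV and MSC are exactly the right corrections: both remove an affine
`a + b * signal` distortion, so preprocessing behavior is analytically
checkable (SNV output has row mean 0 and sd 1; MSC recovers any
`a + b * reference` spectrum exactly).

Default parameterization and why:

* **Classes and sizes** 5 classes of 45/46/48/44/42 — the study's numbering
  ranges, totalling 225.
* **Peaks** UV {215, 250, 280} nm; MIR {1080, 1260, 1450, 2900, 3400} cm⁻¹,
  placed in the bands where such cohorts differ (organosulfur UV absorption
  near 250 nm; C–O 1000–1500, C–H ~2900, O–H ~3400 cm⁻¹). Widths and
  amplitudes are package defaults chosen to give realistic-looking smooth
  spectra, not reported values.
* **Split-signal class design** The class signal is divided between the
  blocks: the UV-informative peaks (250, 280 nm) carry the amplitude pattern
  `(0, 0, 1, 1, 2) * effect` and the MIR-informative peaks (1260,
  3400 cm⁻¹) the pattern `(0, 1, 0, 1, 2) * effect`. Each block alone
  therefore merges two class pairs ({1, 2}/{3, 4} in UV, {1, 3}/{2, 4} in
  MIR) while the fused blocks give every class a unique signature — the
  structure that makes low-level fusion genuinely necessary, and the
  package's fusion claim testable.
* **Effect and noise scale** `effect = 0.30`, `ampJitterSigma = 0.01`,
  `scatterSigma = 0.10`, `offsetSigma = slopeSigma = 0.03`,
  `noiseSigma = 0.01`. Per-peak jitter is *fully correlated* across a peak's
  grid points, so no classifier can average it away; the effect/jitter ratio
  is chosen so every class boundary is many standard deviations wide and the
  fused cohort is cleanly separable — the regime in which the reference
  comparison the package emulates reports perfect fused accuracy — while
  scatter and baseline remain large enough that raw-spectrum models visibly
  benefit from SNV/MSC. Spreading the class signal over two
  independently-jittered peaks per block avoids resting the entire decision
  on one brittle coordinate, which no real cohort does either.
* **Determinism** One seed drives everything through fixed sub-streams
  (gain, offset, slope, jitter, noise — in that order, per block), so
  identical configurations are bit-identical, and because the noise draw is
  last, raising `noiseSigma` under the same seed rescales the very same
  noise realization (which makes noise-monotonicity properties testable
  without Monte-Carlo slack).

What the generator does **not** emulate: real absorptivities or band
shapes, instrument line-shape effects, atmospheric CO₂/water artifacts,
wavelength-dependent noise, or any between-peak correlation structure
beyond the shared class pattern. Passing tests on this cohort therefore
show that the pipeline's logic is correct under the stated model — not that
any particular accuracy will be attained on real spectra.

The zero-effect control (`zeroEffectConfig()`) zeroes every class offset:
no variable is informative and downstream accuracy collapses to roughly the
majority-class share (48/225 ≈ 21 %), which the test suite uses as the
chance-level reference.

## Preprocessing choices

* **SNV** uses the sample standard deviation (divisor `p − 1`), giving the
  clean identity `snv([1, 2, 3]) = [−1, 0, 1]`; a zero-variance spectrum is
  an error naming the offending sample rather than a silent NaN row.
* **MSC** regresses each spectrum on a reference by OLS and returns
  `(x − a) / b`. The reference defaults to the column mean of the *training
  partition only*, then is frozen for the test partition
  (`applyPreprocess()`), so no test statistic ever leaks into the transform.
  A near-zero slope (|b| < 1e−12) is an error: such a spectrum is
  uncorrelated with the reference and "correcting" it would explode.
* **Savitzky–Golay** smoothing (derivative order 0) uses the standard
  central least-squares coefficients with **mirror padding** (reflection
  without repeating the edge point) so outputs keep their length; defaults
  window 11, polyorder 2, common chemometric practice. Interior points
  reproduce polynomials up to the fit degree exactly, and window 3/order 1
  is the 3-point moving mean — both serve as oracle checks in the tests.

Preprocessing is applied per block before fusion: each instrument has its
own scale, and SNV standardizes every spectrum within its block, which is
also why fusion applies no additional block weighting by default (an
autoscale flag exists for non-SNV workflows).

## GA wavelength selection

Chromosomes are boolean masks over the spectral variables. Fitness is the
mean stratified k-fold cross-validated accuracy of a base classifier on the
masked columns of the **training partition**, minus a parsimony penalty
`lambda * selectedCount / p`. Evaluating fitness on the held-out partition
would leak the test set into feature selection and inflate reported test
accuracies, so the fitness function simply never sees it — the test suite
verifies that corrupting the test rows changes neither the selected mask
nor any training accuracy.

Defaults (population 50, up to 100 generations, crossover 0.8, per-bit
mutation 1/p, tournament 3, elitism 1, initial density 0.3, lambda 0.01,
5 folds, patience 20) are standard GA wavelength-selection practice; every
one is configurable because no single convention exists. The base
classifier defaults to a 200-tree random forest: hyperparameter-robust and
cheap enough to refit k times per fitness evaluation. Determinism is taken
seriously: fold assignment and classifier seeds derive from the GA seed,
fitness values are cached per mask, and ties are broken toward smaller
masks and then lexicographically smaller bit patterns — determinism over
elegance. All-zero offspring are repaired by setting one random bit.

Whether selection should run per block before fusion or once on the fused
matrix is genuinely open in this design space; both are supported
(`gaPlacement = "per_block"` / `"post_fusion"`), with post-fusion the
default since the fused matrix is what the downstream models consume.

One subtlety worth knowing when validating GA selection on simulated data:
after SNV, *every* column of an amplitude-coded cohort carries class
information, because the per-spectrum standard deviation in SNV's
denominator depends on the class-dependent peak amplitudes — even flat
baseline regions become weakly discriminative once divided by it. In
addition, when informative columns are highly redundant (a peak spans many
grid points), any moderately dense mask reaches the accuracy ceiling and
fitness differences reduce to the parsimony term. The package's
window-recovery diagnostics therefore run on the raw blocks with sparse
initial masks (`initDensity` well below the default), the regime in which
individual informative wavelengths are actually under selection; this is
also practical advice for anyone validating wavelength selectors against
synthetic ground truth.

## Classifiers

No hyperparameters are canonical for this kind of cohort, so the defaults
are ordinary textbook settings, all exposed in `classifierSpec()`:

* `svc` — RBF kernel, cost 10, kernel width
  `1 / (p * mean feature variance)`;
* `rf` — 500 trees, `sqrt(p)` candidate variables per split (ranger
  engine, single-threaded for reproducibility);
* `ann` — one hidden layer of 100 rectified-linear units, softmax output,
  cross-entropy loss with L2 weight decay 0.03, full-batch Adam, up to 1000
  iterations, inputs standardized with training statistics. The network is
  implemented in the package in vectorized base R: at these problem sizes
  (hundreds of samples and features) a fit takes seconds, and the
  implementation keeps initialization and optimization fully seeded. The
  relatively strong decay is deliberate — with ~900 variables and ~150
  training spectra a weakly-regularized network memorizes noise columns.
* `gbt` — 300 rounds, depth 6, learning rate 0.1, with stochastic boosting
  (row subsample 0.8, per-tree column subsample 0.3; xgboost engine).
  Column subsampling matters on wide spectral matrices: deterministic
  greedy boosting otherwise splits every tree at the same coordinate and
  handles samples falling just outside the training range of their class
  erratically, while subsampling diversifies the split sites the same way
  bagging does for random forests. "Gradient-boosted trees" is a family
  contract here, not a vendor commitment.

`splitTrainTest()` is stratified by default: the training size is exactly
`floor(0.7 n)` with per-class floors and the remainder assigned by largest
fractional part. An unstratified mode exists because some published designs
of this kind appear to have split unstratified; stratification is the
statistically safer default when class sizes differ.

## Evaluation conventions

The confusion matrix is built **rows = predicted, columns = true** — the
convention of the study design this package mirrors, although the transpose
is more common elsewhere; a `transpose` flag provides interoperability.
Accuracy is `100 * trace / n`, printed to two decimals. Per class,
`FP = rowSum − TP` and `FN = colSum − TP` under this convention, and a
precision or recall with a zero denominator is reported as `NaN`, never
silently 0 or 1.

## Numerical and reproducibility choices

* Axes are stored strictly ascending; descending wavenumber exports are
  reversed together with their columns at load. Column count = axis length
  is asserted at every construction.
* Text round-trips write 12 significant digits, giving save/load agreement
  within 1e−9 per cell.
* Every stochastic stage derives its seed from one global seed through a
  small integer hash (`deriveSeed()`), keeping all derived seeds valid
  32-bit R seeds; `runPipeline()` output files are byte-identical across
  reruns of the same configuration and seed.
* One shared split underlies every cell of a comparison table: comparing
  models on different random splits would confound model and partition.

## Problem sizes used by the checks

The package's own validation runs the full-scale cohort (225 × 511 and
225 × 361) for the end-to-end pipeline checks, with a reduced GA budget
(population 30, up to 40 generations) that reliably concentrates selection
on the informative windows; property-style checks (noise monotonicity,
preprocessing benefit, GA recovery at small scale) use a down-scaled
three-class cohort (30 samples, 21-point grids) so that invariants are
exercised over many seeds in seconds. The fusion-dominance comparison uses
ten full-scale cohort replicates per classifier family.

## Known limitations

* The generator's Gaussian-peak/affine-scatter model is a validation
  harness, not a claim about real spectra; accuracies on this cohort do not
  transfer to real data.
* Only smoothing-order Savitzky–Golay is provided (no derivative filters,
  detrending or wavelet denoising), and only low-level fusion — mid-level
  (feature-level) and high-level (decision-level) fusion are out of scope.
* GA fitness assumes every class has at least as many training samples as
  CV folds.
* No probability calibration or ROC/AUC: the evaluation layer reports the
  confusion matrix, accuracy, precision and recall only.
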