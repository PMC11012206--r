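# spectrafuse

Chemometric origin traceability from fused UV-Vis and mid-infrared
spectra.

Food-authentication labs routinely ask whether a sample's geographic origin
can be read off cheap, non-destructive spectra. A single instrument often
cannot: some origin-dependent constituents absorb in the ultraviolet,
others in the mid-infrared. `spectrafuse` implements the standard
multi-block answer as a tested R pipeline:

* **Preprocessing** — standard normal variate (SNV),
  `x' = (x − mean(x)) / sd(x)` per spectrum; multiplicative scatter
  correction (MSC), `x' = (x − a) / b` from the per-spectrum OLS fit
  `x ≈ a + b·r` against a training-mean reference; Savitzky–Golay
  smoothing with mirror-padded edges.
* **Wavelength selection** — a genetic algorithm over boolean wavelength
  masks, fitness = stratified k-fold cross-validated accuracy of a base
  classifier on the training partition minus a parsimony penalty
  `λ·(selected/p)`.
* **Low-level data fusion (LLDF)** — column-wise concatenation of the
  preprocessed blocks, rows aligned by sample ID, with block-provenance
  bookkeeping.
* **Classification** — RBF support-vector classification, random forest,
  a single-hidden-layer feedforward network, gradient-boosted trees.
* **Evaluation** — confusion matrix (rows = predicted, columns = true),
  accuracy `= 100·trace/n`, per-class TP/TN/FP/FN, precision, recall.

Because cohorts of this kind are rarely deposited, the package also ships a
seeded two-block spectra generator (Gaussian class-dependent peaks +
log-normal multiplicative scatter + linear baseline + white noise) whose
defaults emulate the target study design: 5 origin classes sized
45/46/48/44/42 (225 samples), UV 190–700 nm at 1 nm, MIR 400–4000 cm⁻¹ at
10 cm⁻¹, with the class-informative peaks split between the blocks so that
neither block alone separates all five classes but their fusion does. See
`vignettes/origin-traceability.Rmd` for the model and every default.

## Worked example

```r
library(spectrafuse)

cfg <- pipelineConfig(
  data        = syntheticConfig(),                     # the 225-sample cohort
  preprocess  = preprocessSpec("snv"),
  ga          = gaConfig(populationSize = 30, generations = 40),
  blockSets   = list("uv", "mir", c("mir", "uv")),     # single blocks vs fused
  classifiers = c("svc", "rf", "ann", "gbt"),
  globalSeed  = 1
)
res <- runPipeline(cfg, verbose = TRUE)
compareTable(res)
```

For the fused arm this prints (run with `globalSeed = 1`):

```
  Model Preprocessing mir+uv.Train mir+uv.Test
1   svc        SNV-GA       100.00      100.00
2    rf        SNV-GA       100.00      100.00
3   ann        SNV-GA       100.00      100.00
4   gbt        SNV-GA       100.00      100.00
```

Reading: after per-block SNV, GA selection on the fused training matrix
(157 training spectra; 132 of 872 wavelengths kept under the reduced GA
budget) and low-level fusion, all four classifier families classify all 68
held-out samples correctly. The single-block arms top out far lower
(roughly 55–68 % test accuracy across seeds) because each block by
construction leaves
two class pairs indistinguishable — fusion is what completes the signature.

Individual stages are plain functions/S4 objects: `generatePaired()`,
`snv()`, `msc()`, `sgSmooth()`, `splitTrainTest()`, `gaSelect()`,
`llfuse()`, `trainClassifier()`, `predict()`, `evaluateLabels()`,
`reportToText()`. A thin CLI over the same functions is installed as
`exec/spectrafuse` (subcommands `simulate`, `preprocess`, `fuse`,
`evaluate`, `run`).

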