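# mmgdecode

Decoding individual finger movements from simultaneous magnetomyography
(MMG, optically pumped magnetometers) and surface electromyography (EMG).

Contactless magnetometers can record the magnetic fields of muscle ionic
currents. The scientific question this package addresses is whether such
MMG recordings support single-trial decoding of which finger moved — index
(DII) vs little finger (DV) vs no movement — and how they compare with the
EMG gold standard. The package provides the full analysis as reusable,
tested building blocks plus an `analysis/` workflow, driven by a synthetic
generator (the kind of paired recording it emulates is not publicly
deposited) with known ground-truth channel gains so that every claim the
pipeline makes can be checked against a known answer.

## What is implemented

* **Synthetic paired sessions** (`generator_config()`,
  `generate_experiment()`): 3 sessions × 30 cued trials of 5 s at
  2343.8 Hz; per-trial 25–100 Hz movement bursts under a tapered-cosine
  envelope with class-dependent spatial gains (radial channels ↔ DII,
  ulnar channels ↔ DV, magnetometer Z axis above Y); 1/f background,
  50 Hz line, white sensor noise; EMG > MMG in-band SNR.
* **Preprocessing** (`preprocess_recording()`): demean → 25–100 Hz
  zero-phase 4th-order Butterworth band-pass → 49–51 Hz band-stop →
  Hilbert envelope → 200 Hz resampling.
* **Window datasets** (`split_trials()`, `build_fold_dataset()`): 100 ms
  windows, movement class from 0–300 ms post-onset, no-movement from
  −1500–0 ms; stratified k-fold over trials (never windows); 500/100
  windows per class for train/test; z-scoring with train-only moments.
* **Classifier** (`model_config()`, `train_model()`,
  `cross_validate()`): residual 1-D convolutional network — pointwise
  conv (128 filters) → BN → GELU → kernel-3 conv back to C → BN → GELU →
  residual add → GELU → stride-2 conv (16 filters) → FC(100) → FC(100) →
  softmax(3) — trained with Adam (lr 0.01, batch 250), categorical
  cross-entropy; compiled (RcppArmadillo) training core with a pure-R
  reference implementation cross-checked in the tests.
* **Attribution** (`integrated_gradients()`, `channel_importance()`):
  integrated gradients of the per-sample loss, 6 interpolation levels from
  an all-zeros baseline, L1-normalized, averaged over time and samples per
  channel and fold.
* **Statistics** (`permutation_null()`, `perm_pvalue()`,
  `cohens_d_vs_null()`, `five_by_two_cv_ftest()`, `mcnemar_test()`,
  `percentage_agreement()`, `cohens_kappa()`): empirical chance level by
  training-label permutation; 5×2-CV pseudo-F against F(10, 5);
  continuity-corrected McNemar χ²(1) with Cohen's g; agreement and kappa
  between the two modality models' aligned predictions.
* **Orchestration** (`run_config()`, `run_full_analysis()`): one-call
  end-to-end run with provenance (seeds, config hash, MD5 checksums) and
  TSV/JSON export.

The `analysis/` directory holds the narrative workflow
(`01_simulate.R` … `04_statistics.R`), each a thin driver over the package
that writes its tables under `results/`.

## Worked example

```r
library(mmgdecode)

cfg <- run_config(
  generator = generator_config(),   # default synthetic study conditions
  model = model_config(),
  k = 5, n_train = 500, n_test = 100, epochs = 100,
  n_perm = 30,                      # reduced-scale permutation null
  perm_scale = list(k = 2L, n_train = 100L, n_test = 50L, epochs = 10L),
  seed = 1
)
report <- run_full_analysis(cfg, verbose = TRUE)
report
```

which prints (about 6 minutes on one core):

```
<run_report>
  accuracy: EMG 0.9593, MMG 0.8427
  agreement: 82.80%, kappa 0.742
  McNemar: chi2(1) = 120.622, p = 4.62e-28, g = 0.349
  5x2-CV: F(10,5) = 129.689, p = 2.12e-05
  permutation null: EMG p < 0.0333, MMG p < 0.0333
```

Reading: from 100 ms envelope windows, the EMG model classifies ~96 % of
held-out windows correctly and the MMG model ~84 % (chance is 1/3; the
permutation null sits at chance, so both are far above it — no null value
reaches the observed accuracy). The two models agree on 83 % of aligned
test windows (kappa 0.74 after chance correction); the McNemar test on
their discordant windows and the 5×2-CV F-test both show the EMG model is
reliably the stronger one. `report$importance` holds the per-channel
integrated-gradients scores, which recover the generator's ground-truth
gain structure — on the default conditions the magnetometer Z-axis
channels carry ~3.5× the mean importance of the Y-axis channels, matching
their higher simulated gain.

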