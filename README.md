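# emglrcn

Simultaneous **lower-limb movement classification** and **knee joint angle
regression** from raw multichannel surface electromyography (sEMG), built
around a transfer-learning long-term recurrent convolutional network (LRCN).

## The problem

Remote monitoring of knee rehabilitation needs two things from a wearable
sEMG sensor: *what* movement the patient is performing (walking, sitting with
knee extension, standing with knee flexion) and *how* the knee joint angle
evolves while they perform it. Classically these are solved by separate
pipelines with hand-crafted features, and the angle usually requires an extra
goniometer or inertial sensor at run time. This package implements a single
data-driven network that does both from 256 ms windows of raw 4-channel sEMG
(vastus medialis, semitendinosus, biceps femoris, rectus femoris, sampled at
1000 Hz and band-limited to 20–460 Hz):

1. a **feature extractor** — four parallel per-channel stages of
   conv(20 filters, 11×1, stride 1) → ReLU → 4×1 max-pool → dropout(0.5),
   concatenated and passed through one more such stage, leaving a 16×20
   feature map per 256-sample window;
2. an **angle head** — two stacked LSTM layers (32 and 64 units); the final
   hidden state feeds a linear dense layer with one output per window sample
   (64×256 + 256 = 16 640 parameters), trained end-to-end first with Adam
   (lr 0.001, batch 25) on mean-squared error;
3. a **classification head** — flatten → dense → softmax over the three
   movements (320×3 + 3 = 963 parameters), fitted afterwards by **transfer
   learning**: the feature extractor learned during angle regression is
   frozen bit-exactly and only the head is trained with cross-entropy.

Around the network, the package provides the full experimental pipeline:

* **segmentation** into 256 ms windows with 64 ms overlap (stride 192 ms);
* **data augmentation** `D_v = D_o + wgn(m, n, p)` with the white-noise power
  `p` solved per window so the augmented data attain a fixed signal-to-noise
  ratio (default 25, dB convention), default 10× dataset size;
* per-channel **z-score normalization** fitted on training folds only;
* **3-fold cross-validation** with fold-averaged reports;
* the **empirical iterative algorithm (EIA)** — data-driven low-pass
  smoothing of the predicted angle trace by natural cubic-spline
  interpolation through midpoints of consecutive local extrema, iterated
  (default 2 iterations);
* **metrics**: normalized mean absolute error (MAE %), per-class
  precision/recall/F1, accuracy, row-normalized confusion matrices, and the
  Pearson correlation between actual and EIA-processed angle;
* a seedable **synthetic sEMG generator** (band-limited Gaussian carriers
  amplitude-modulated by class-specific muscle recruitment of the knee angle
  and its angular velocity) so the whole pipeline runs and is tested without
  any external data, plus a delimited-text reader/writer for real recordings
  in the UCI lower-limb layout.

No deep-learning framework is used: the convolution, pooling and LSTM
forward/backward passes are implemented in RcppArmadillo inside the package
and verified against finite differences in the test suite.

## Worked example

```r
library(emglrcn)

rec <- gen_recording("walking", sim_config(duration_s = 4, seed = 42))
rec
#> <emg_recording> synthetic | walking | synthetic
#>   4000 samples x 4 channels @ 1000 Hz (4.0 s), angle 5.0-65.0 deg

segs <- segment_windows(rec)          # 256 ms windows, 64 ms overlap
segs
#> <segment_set> 20 windows of 256 samples x 4 channels @ 1000 Hz (0 virtual)

solve_noise_power(segs$x[1, , ], augment_config())   # p for SNR 25 dB
#> [1] 0.0001425

# a reduced end-to-end experiment (1 trial/class, 10 s, 8 epochs, 2x augment)
cfg <- run_config(sim = sim_config(duration_s = 10, seed = 42),
                  n_trials_per_class = 1,
                  augment = augment_config(factor = 2, seed = 42),
                  lrcn = lrcn_config(epochs = 8, seed = 42),
                  class_epochs = 20, seed = 42)
run_experiment(cfg)
#> <metrics_report>
#>   MAE: 23.58 +/- 5.07 %
#>   accuracy: 79.74 +/- 16.68 %
#>   Pearson r: 0.91 +/- 0.01
#>   confusion (row %):
#>                        walking sitting_knee_extension standing_knee_flexion
#> walking                   55.6                   30.8                  13.6
#> sitting_knee_extension    11.4                   88.6                   0.0
#> standing_knee_flexion      0.0                    0.0                 100.0
```

The aggregate report is the mean ± sample standard deviation over the three
folds: the classifier's overall accuracy, the range-normalized MAE of the
EIA-smoothed angle prediction, the Pearson correlation between actual and
smoothed predicted angle (averaged per trial), and the fold-averaged
row-normalized confusion matrix. The reduced settings above are for
illustration; at the defaults studied in the tests (2 trials/class of 30 s,
10× augmentation, 30 epochs) the same pipeline reaches ≥99% 3-fold accuracy
and post-EIA correlation above 0.9 (see `tests/testthat/test-acceptance.R`).

A thin command-line interface over the same functions is installed at
`inst/cli/emglrcn` (subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `smooth`, `run`).

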