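# coxdae

Survival prediction for glioblastoma from multimodal 3-D brain MRI, using a
convolutional denoising autoencoder (DAE) trained with a Cox
proportional-hazards loss.

## What it does

Glioblastoma survival varies enormously between patients, and much of the
prognostic signal — tumour size, necrosis, contrast enhancement, edema — is
visible in routine MRI (T1, T2, T1ce, FLAIR). `coxdae` learns a per-patient
**prognostic index** (PI) directly from the segmented lesion:

* an encoder φ (three 3×3×3 convolution stages with 16/32/64 feature maps,
  LeakyReLU, 2× max-pooling) compresses the 4-channel tumour volume of
  interest;
* a decoder ψ reconstructs the clean input from a corrupted copy (the
  denoising objective), ending in a sigmoid;
* a survival branch on the flattened hidden matrix (65,536 features at the
  default 64×64×128 input → dense 1024 → dense 128 → linear, no bias)
  outputs the log relative hazard `PI = W′φ(x)`.

Training minimizes the hybrid loss

```
L_hybrid = α·L_r + β·L_s,        α + β = 1  (default 0.7 : 0.3)
L_r  = (1/n) Σ_i ‖x_i − ψ(φ(x_i))‖²                      (reconstruction)
L_s  = −Σ_i δ_i { W′φ(x_i) − log Σ_{j∈R(t_i)} e^{W′φ(x_j)} }   (Cox NPLL)
```

with within-batch risk sets `R(t_i) = {j : t_j ≥ t_i}`, Breslow tie
handling, Adam (lr 5e-4), batch size 26 and time-sorted batches.

Around the model the package provides the full workflow: NIfTI input with
BraTS-style nested segmentation labels, percentile min–max normalization,
VOI extraction, mirror/right-angle-rotation augmentation, an HDF5 cohort
container, a synthetic tumour-cohort generator with known ground-truth
hazard, and an evaluation suite — Harrell's C-index, 300/450-day
three-class risk accuracy, Kaplan–Meier + log-rank at the median-PI split,
Schoenfeld residual diagnostics, IPCW time-dependent ROC, and a Cox
regression nomogram with calibration curves.

It is aimed at researchers in medical image analysis and radiomics who want
a self-contained, CPU-only, fully testable implementation of deep Cox
survival modelling on 3-D images. The network, backpropagation and Adam are
implemented in C++ (single-precision BLAS GEMM via im2col) — no deep
learning framework is required.

## Worked example

Train on a synthetic cohort whose images encode a known hazard, then
evaluate on held-out patients:

```r
library(coxdae)

cfg <- sim_config(n_patients = 180, vol_shape = c(24, 24, 24), seed = 101)
co  <- simulate_cohort(cfg, voi_shape = c(16, 16, 16))

model <- dae_cox_model(model_config(c(16, 16, 16), recon_reduction = "mean"),
                       seed = 101)
fit <- train_dae_cox(model, co$vois[1:120], co$vois[121:140],
                     train_config(batch_size = 26, epochs = 60, seed = 101))

p <- predict_pi(fit, co$vois[141:180])          # held-out test set
concordance_index(p$pi, p$time, p$event)
#> [1] 0.71949

km_by_median_pi(p$pi, p$time, p$event)$log_rank$p
#> [1] 1.297018e-05

p_train <- predict_pi(fit, co$vois[1:120])
risk_class_accuracy(p$pi, p$time, risk_class_scheme(p_train$pi))
#> [1] 0.425

time_dependent_roc(p$pi, p$time, p$event)
#>   horizon       auc n_cases n_controls flag
#> 1     200 0.7866347      15         22   ok
#> 2     400 0.8846745      17         14   ok
#> 3     600 0.8824235      18         12   ok
#> 4     800 0.8705045      20          9   ok
```

A held-out C-index of 0.72 (against a ceiling of 0.79 for the generator's
true log hazard on this test set) means the network recovered most of the
imaging-encoded risk; the log-rank p far below 0.01 confirms that the
median-PI split separates survivors from non-survivors; the three-class
accuracy of 0.43 beats the 1/3 chance level; and the time-dependent AUC
stays in the 0.79–0.88 band across the 200–800-day horizons, i.e. the PI's
discrimination does not decay over time.

A command-line wrapper with `simulate / preprocess / train / predict /
evaluate / nomogram` subcommands is installed at
`inst/cli/coxdae.R` (`system.file("cli", "coxdae.R", package = "coxdae")`).

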