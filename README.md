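# resunetCT

Automatic detection and quantification of ascites (free peritoneal
fluid) on axial abdominopelvic CT slices with a deep residual U-Net —
implemented natively in R, with a synthetic CT phantom generator so the
whole pipeline runs and is tested without patient data.

## Who this is for

Researchers in medical image analysis who want a self-contained,
inspectable reference implementation of segmentation-based fluid
detection: HU windowing, paired image/mask augmentation, a configurable
residual U-Net trained under a BCE + Dice loss with stratified k-fold
cross-validation, and a joint segmentation/detection evaluation scheme
with volume estimation. The network — convolution forward/backward,
fused batch-norm + ReLU, Adam — is written in the package (R with
compiled C++ kernels); there is no TensorFlow/PyTorch dependency.

## The model in brief

A U-Net encoder–bridge–decoder built from pre-activation residual units
`[BN → ReLU → conv] × 2` with identity/1×1-projection shortcuts. With the
default configuration (4 blocks per side, base 32 filters, 256×256×3
input) the encoder runs 256×32 → 128×64 → 64×128 → 32×256 with stride-2
first convolutions, the bridge sits at 16×16×512, and each decoder block
up-samples ×2 (nearest), concatenates its mirror encoder output, and
convolves back down; a 1×1 convolution + sigmoid yields the per-pixel
fluid probability p. Training minimises

    L = BCE(p, g) + 1 − (2·Σ p·g + ε) / (Σ p + Σ g + ε),   ε = 1

with Adam. Detection declares a slice positive when its predicted fluid
area fraction reaches a threshold; sweeping the threshold gives the ROC.
Per-image IoU scores fluid-free slices 1 (empty prediction) or 0 (any
spurious pixel); volume in mL is Σ area × spacing² × thickness / 1000.

## Worked example

```r
library(resunetCT)

# 300 synthetic slices (60 subjects), with bladder/cyst confounders
ds    <- generate_dataset(30, 30, 5, phantom_spec(grid_size = 128, seed = 1),
                          seed = 1)
split <- split_train_test(ds, 0.8, seed = 2)          # by subject, stratified
train <- preprocess_dataset(split$train, window_spec(), 128)
test  <- preprocess_dataset(split$test,  window_spec(), 128)

mc  <- resunet_config(n_blocks = 2, base_filters = 8, input_size = 128, seed = 7)
tc  <- train_config(learning_rate = 1e-3, batch_size = 16, seed = 11)
fit <- resunet_fit(train, mc, tc, epochs = 10, verbose = TRUE)
evaluate_model(fit, test)
```

Output from this exact run (fixed seeds, one CPU, ~5 minutes):

```
epoch 1/10  train 1.6716 (bce 0.6802, dice 0.9914)
...
epoch 10/10  train 0.2470 (bce 0.0192, dice 0.2278)

Evaluation over 60 slices
  mIoU:  0.661
  AUROC: 0.989
  sens 1.00 | spec 0.74 | acc 0.85 | bal acc 0.87 | prec 0.74 | F1 0.85
  predicted fluid volume: 332.6 mL
```

Read: on held-out phantom subjects the model recovers fluid masks with a
mean IoU of 0.66 and separates ascites from fluid-free slices with AUROC
0.99; an untrained network scores mIoU ≈ 0.01 on the same split. The
residual false positives sit on confounder slices (distended bladder,
large cysts) whose fluid is deliberately intensity-identical to ascites.

A command-line front end wraps the same functions:

```sh
inst/cli/resunetct generate --config run.yaml
inst/cli/resunetct train    --config run.yaml
inst/cli/resunetct evaluate --config run.yaml
inst/cli/resunetct model-summary
```

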