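# upunet

Background-emission removal for fluorescence confocal microscopy with an
up-convolutional U-net, plus the synthetic bead-image simulator used to
train and score it.

## The problem

Fluorescence microscopy frames of calibration beads are corrupted by PSF
blur, mixed Gaussian/Poisson noise, and — hardest of all — diffuse
*background emission* (auto-fluorescence, reflections, diffraction in
the medium).  The recorded frame follows

```
g_n = P(H x* + b) + eta
```

with `x*` the clean bead slice, `H` a Gaussian PSF, `b` the background
field, `P` Poisson photon noise and `eta` Gaussian read noise.  Particle
localisation degrades badly when `b` is strong.  This package:

* **simulates** realistic frame pairs: beads placed without overlap in a
  continuous 3D volume, rasterised at 229.5 (90% of the 8-bit maximum),
  background emission modelled as 8-octave improved Perlin gradient
  noise (persistence 0.5), Gaussian PSF blur (sigma 2 px), Gaussian read
  noise calibrated so `||g_n - g||_F = 0.03 ||g||_F` exactly, and
  Poisson shot noise;
* **restores** frames with an encoder-decoder network whose skip
  connections are *learnable 2x2 transposed convolutions* added one
  spatial level finer than their source block ("upU-net", 295,593
  learnable parameters at the default 5 blocks x 8 filters), trained
  with ADAM on an l2-penalised least-squares loss (lr 0.01, x0.2 every
  25 epochs, batch 50); a classical 3-level U-net baseline (121,385
  parameters) is included for comparison;
* **scores** particle estimation on restored frames: threshold/
  connected-component detection, greedy one-to-one matching, per-frame
  true-positive ratio `TPR = #matched / #truth` and mean false-particle
  count `phi`, and 3D bead reconstruction from restored z-stacks.

It is aimed at microscopists and method developers who need a
reproducible, fully synthetic testbed for background-removal and
particle-estimation pipelines.

## Worked example

```r
library(upunet)

# a miniature study condition: 24 scenes at 128x128, 10-15 beads each
spec <- dataset_spec(n_images = 24, split = c(0.75, 0.125, 0.125), seed = 7)
ds   <- generate_dataset(spec)
ds
#> Synthetic bead dataset: 24 pairs (18/3/3 train/val/test), 128x128 px

net <- build_upunet(upunet_spec(), seed = 7)
fit <- train_model(net, ds, train_config(batch_size = 18, max_epochs = 40,
                                         seed = 7))
fit
#> Trained restoration network: 40 epochs, final train loss 37.8372, val loss 45.9841
#> upU-net: 5 blocks, channels 8-16-32-64-128, 295,593 parameters

# restoration error vs doing nothing, on the held-out frames
residuals(fit, ds)
#>   id mse_restored mse_input
#> 1  5     49.68325  12147.46
#> 2  7     42.53140  14193.46
#> 3  9     44.95339  12993.01

# particle estimation on restored frames vs on the raw inputs
evaluate_restorations(fit$net, ds$pairs[ds$split$test])
#> Particle-estimation report over 3 frames: mean TPR 0.6607 (66.07%), phi 0.000
evaluate_restorations(identity, ds$pairs[ds$split$test])
#> Particle-estimation report over 3 frames: mean TPR 0.1667 (16.67%), phi 11.000
```

Even this two-minute training cuts the restoration error by more than
two orders of magnitude and turns particle estimation from unusable
(one bead in six found, eleven spurious detections per frame) into
clean recovery of the larger profiles with zero false particles; the
full protocol in the acceptance script pushes the true-positive ratio
into the mid-80s percent.

A command-line surface wraps the same functions
(`inst/scripts/upunet`):

```sh
Rscript inst/scripts/upunet simulate --config cfg.yaml --out data/
Rscript inst/scripts/upunet train    --config cfg.yaml --data data/ --out ckpt
Rscript inst/scripts/upunet restore  --model ckpt --input stack.tif
Rscript inst/scripts/upunet evaluate --model ckpt --data data/
Rscript inst/scripts/upunet reconstruct --model ckpt --input stack.tif
```

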