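# nucformer

Nucleus segmentation for H&E-stained pathology tiles in two stages:

1. **Guided-filter denoising.** Slide scanning and transmission leave
   Gaussian and salt-and-pepper noise on osteosarcoma pathology tiles.
   The guided (directed) filter smooths each tile as a local linear
   transform of its own grayscale: per window ω_k,
   `a_k = cov(K, q) / (σ_k² + ε)`, `b_k = mean(q) − a_k mean(K)`, and
   `p_i = ā_i K_i + b̄_i`. Flat regions are averaged, edges are kept, and
   all window statistics are O(N) running-sum box means. An optional
   bilateral post-filter is included (off by default).
2. **Dual-attention U-shaped transformer.** Tiles are tokenized by an
   overlapping patch embedding (stride 4), processed by encoder stages at
   H/4 (C), H/8 (2C) and H/16 (4C) built from dual blocks — efficient
   (spatial) attention `E(Q,K,V) = ρ_q(Q)(ρ_k(K)ᵀV)` followed by
   transposed (channel, cross-covariance) attention
   `T(Q,K,V) = V softmax(KᵀQ/τ)` with L2-normalized queries/keys, each
   with LayerNorm + Mix-FFN residual sub-blocks — a two-block bottleneck,
   and a mirrored decoder whose skip connections are fused by
   cross-attention (`E = ρ_v(V)(ρ_k(K)ᵀQ)`, encoder output as query).
   Training minimizes `0.6·Dice + 0.4·BCE` with SGD (lr 0.05, momentum
   0.9, weight decay 1e-4, batch 4). The forward and backward passes are
   implemented natively in R on a small reverse-mode tape — no external
   deep-learning framework is required.

Because the clinical slides behind this method are embargoed, the package
ships a synthetic H&E-like tile generator (elliptical purple nuclei on a
textured pink background with exact masks, Gaussian + salt-and-pepper
noise, translation augmentation) so the entire pipeline is exercisable
and testable on any machine.

## Worked example

```r
library(nucformer)

## a 64 px synthetic tile with its mask and the default noise model
spec <- syntheticSpec(tileSize = 64, nNucleiRange = c(3L, 6L),
                      axisRange = c(4, 8), seed = 7L)
tile <- generateTile(spec, noisy = TRUE)
sum(tile$mask)
#> [1] 628            # nucleus pixels out of 4096

## stage one: guided-filter denoising recovers ~4 dB of color PSNR
psnrColor(tile$noisyImage, tile$image)
#> [1] 20.56          # dB, noisy vs clean
den <- guidedFilterRGB(tile$noisyImage, denoiseParams(radius = 4,
                                                      epsilon = 0.01))
psnrColor(den, tile$image)
#> [1] 24.52          # dB, denoised vs clean

## the identity limit: self-guided filtering with epsilon = 0 is exact
q <- toGrayscale(tile$image)
max(abs(guidedFilter(q, q, denoiseParams(radius = 2, epsilon = 0)) - q))
#> [1] 3.885781e-16

## stage two: a desk-scale network
model <- buildModel(tinyModelSpec(), seed = 42)
model
#> DualAttentionUNet with 445 parameter tensors, 402,944 trainable scalars
#> ModelSpec: C = 16 | stages 2/2/2 | heads 1/2/4 | bottleneck 2 | FFN x 2

## segmentation metrics from confusion counts
segMetrics(newConfusion(tp = 1, tn = 1, fp = 1, fn = 1))
#>  accuracy precision    recall       iou       dsc        f1
#>     0.500     0.500     0.500     0.333     0.500     0.500
```

The PSNR values say the noise model costs ~20 dB of fidelity and one
guided-filter pass recovers about 4 dB; the metric row shows the Dice
coefficient equaling F1 (they coincide on binary masks) and
IoU = DSC/(2 − DSC).

A full training run at desk scale (20 tiles of 64 px, C = 16, 30 epochs,
a few minutes on one CPU):

```r
ds  <- makeDataset(25, spec, "synthetic")
fit <- trainModel(ds$train, ds$val, spec = tinyModelSpec(),
                  cfg = trainConfig(epochs = 30L, seed = 42L))
fit$bestDice      # validation Dice of the kept checkpoint, ~0.9
```

The same verbs are available from a shell via the thin CLI at
`inst/cli/nucformer.R` (`simulate`, `denoise`, `train`, `predict`,
`evaluate`), with YAML configuration via `readPipelineConfig()`.

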