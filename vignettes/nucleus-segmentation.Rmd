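---
title: "Guided-filter denoising and dual-attention transformer segmentation of nuclei"
author: "nucformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided-filter denoising and dual-attention transformer segmentation of nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucformer)
```

# The problem

Hematoxylin-and-eosin (H&E) stained pathology tiles of osteosarcoma tissue
carry two obstacles to automated nucleus segmentation: acquisition noise
(mostly Gaussian and salt-and-pepper) introduced during slide scanning and
transmission, and the sheer density of nuclei per tile. `nucformer`
implements a two-stage pipeline: an edge-preserving guided-filter denoiser
followed by a U-shaped transformer segmentation network built from dual
(spatial + channel) attention blocks, trained with a composite Dice plus
binary cross-entropy loss.

# Stage one: guided filtering

The guided filter expresses the output as a local linear transform of a
guidance image $K$ — here the BT.601 grayscale of the tile itself. Within
each $(2r+1)\times(2r+1)$ window $\omega_k$,

$$a_k = \frac{\overline{Kq}_k - \bar K_k \bar q_k}{\sigma_k^2 + \epsilon},
\qquad b_k = \bar q_k - a_k \bar K_k,$$

and each pixel averages the coefficients of all windows containing it,
$p_i = \bar a_i K_i + \bar b_i$. Flat regions (variance $\ll \epsilon$)
are averaged strongly; high-variance regions (edges) pass through. Two
analytic limits pin the implementation down and are verified by the test
suite:

* **Identity limit.** With $K = q$ and $\epsilon = 0$, $a_k = 1$,
  $b_k = 0$, and the output equals the input exactly wherever the window
  variance is nonzero.
* **Mean-filter limit.** With $\epsilon$ far above every window variance,
  $a_k \to 0$, $b_k \to \bar q_k$, and the filter becomes a double box
  mean.

Numerical choices:

* Intensities are normalized to $[0,1]$ at load; the default regularizer
  is $\epsilon = 0.01$ on that scale and the default radius is $r = 4$ for
  512 px tiles (neither is stated by the method's sources; these values
  noticeably denoise the synthetic tiles below without erasing the
  background texture).
* Box means use running sums, so the arithmetic is $O(N)$ per call,
  independent of the radius; border windows are normalized by their
  in-bounds pixel count, which makes constant images exact fixed points.
* Windows of exactly zero variance with $\epsilon = 0$ are a $0/0$ case;
  the implementation takes the $\epsilon \to 0^+$ limit $a = 0$,
  $b = \bar q_k$, which still reproduces the input on constant regions.
* Color tiles are filtered per channel under one shared grayscale guide.
* A bilateral post-filter (spatial sigma 3 px, range sigma 0.1) is
  available but disabled by default: the pipeline's own figures treat
  directed filtering as the denoising stage, and the bilateral step is
  mentioned without parameters. It is exposed as `bilateralPost()` and a
  flag on `DenoiseParams`.

# Stage two: the dual-attention U-shaped transformer

The network tokenizes the tile with an overlapping patch embedding — a
dense projection of $7\times7$ neighborhoods at stride 4 (padding 3), the
standard realization of factor-4 overlapping patches — giving an
$H/4 \times W/4$ grid of $C$-dimensional tokens. The encoder alternates
dual-attention blocks and $2\times2$ patch merging so the schedule is
$C$ at $H/4$, $2C$ at $H/8$, $4C$ at $H/16$, followed by a two-block
bottleneck at $H/16$. The stated dimension schedule is taken as
authoritative, so the network has exactly two merging steps. The decoder
mirrors the encoder: patch expanding (a linear doubling of channels
followed by a pixel-shuffle, halving channels per $2\times$ upsampling),
skip fusion, dual blocks, then a final $4\times$ expansion and a linear
head to two per-pixel class scores.

## The dual block

Each block applies, in order, with a residual connection around every
sub-step:

1. efficient (spatial) attention,
2. LayerNorm + Mix-FFN,
3. transposed (channel) attention,
4. LayerNorm + Mix-FFN.

LayerNorm sits inside the FFN branch only — the attention sub-layers act
on the raw residual stream, exactly as the block equations are written,
rather than in pre-norm convention. The Mix-FFN is
$\mathrm{FC}(\mathrm{GELU}(\mathrm{DWConv}(\mathrm{FC}(\cdot))))$ with a
depthwise $3\times3$ convolution on the token grid providing implicit
positional mixing; it is kept as written even though the surrounding
description calls the architecture convolution-free.

**Efficient attention** is the linear-complexity factorization
$E(Q,K,V) = \rho_q(Q)\,(\rho_k(K)^\top V)$: $\rho_q$ normalizes each
query over its channels, $\rho_k$ normalizes each key channel over
tokens, so both factors are convex weights and the inner product is a
$d\times d$ global context — no $N \times N$ map is ever materialized.

**Transposed attention** is cross-covariance (channel) attention:
$T(Q,K,V) = V\,\mathrm{softmax}(K^\top Q/\tau)$ with $Q, K$
L2-normalized per channel column and a learnable positive temperature
per head, parameterized as $\tau = e^{\theta}$ with $\theta$ initialized
to 0 ($\tau_0 = 1$). Cost is quadratic in the embedding dimension,
linear in tokens.

**Skip fusion (SCA).** At each skip, the upsampled decoder stream $X_1$
is linearly projected to $X_1'$, keys and values are projections of
$X_1'$, the query is a projection of the skipped encoder output $X_2$,
and the fusion core is $E = \rho_v(V)\,(\rho_k(K)^\top Q)$ with both
softmaxes over the token axis, keeping the context $d \times d$ and the
cost linear in $N$. The network adds $X_1'$ back to $E$ as a residual —
a package design choice: without a residual path the fused stream loses
its per-token detail and training stalls. The exported `scaAttention()`
computes the fusion core alone.

Multi-head splitting (defaults 1/2/4 heads per stage) applies to both
attention operators. The full-scale default is $C = 64$ with FFN
expansion 4; `tinyModelSpec()` ($C = 16$, expansion 2) is the desk-scale
configuration used throughout the tests.

## Loss

$\mathrm{loss} = 0.6\,\mathrm{DiceLoss} + 0.4\,\mathrm{BCE}$ on the
foreground probability $p = \sigma(s_2 - s_1)$, where the soft Dice loss
uses an additive smoothing constant $s = 1$ on pixel counts, and the
decision threshold is $0.5$.

# Training in plain R

No automatic-differentiation framework is assumed: the package carries a
small reverse-mode tape over matrices (`R/autodiff.R`) and analytic
backward rules for every operator, verified against central finite
differences in the test suite. The optimizer is SGD with momentum 0.9,
base learning rate 0.05, weight decay $10^{-4}$ and batch size 4; runs
are fully seeded, keep the best-validation-Dice checkpoint and stop
early after 20 epochs without improvement (replacing by-eye convergence
monitoring with an explicit rule).

Three stabilization choices matter and were made once, on optimization
grounds:

* **Fan-scaled initialization.** Weights are truncated-normal with
  Glorot variance scaling. A fixed small standard deviation (the common
  ViT choice) collapses this network: the non-residual projections
  (merging, expanding, skip fusion) each shrink the signal several-fold,
  and the decoder output degenerates to a spatial constant.
* **Residual-branch gain 0.35 and gradient clipping.** The residual
  stream has no normalization of its own, so unit-gain branch outputs
  make the stream grow with depth and SGD at the stated base rate
  diverges; scaling the attention/FFN output projections by 0.35 at init
  and clipping the global gradient norm at 1 keeps it stable.
* **Prior-matched head bias.** The head bias starts at the foreground
  class prior (foreground logit $-2$, $p \approx 0.12$), the standard
  remedy for the long plateau that class imbalance otherwise induces at
  the start of training.

# Synthetic data

The real osteosarcoma slides behind this method are embargoed, so the
package generates H&E-like tiles with exact ground truth: filled
ellipses in hematoxylin-like purple (mean RGB 0.35/0.25/0.55) on an
eosin-like pink background (0.90/0.75/0.85), placed without overlap by
bounded rejection sampling so the mask's connected components equal the
nucleus count. The background texture is a smooth low-frequency sinusoid
mixture rather than white noise, so denoising experiments can
distinguish texture preservation from noise removal. Corruption follows
the stated noise model — additive Gaussian (default sd 0.05) plus
salt-and-pepper impulses (default 2% of pixels) — and the augmentation
is joint integer translation of tile and mask. Datasets are written with
a seeded 80/20 train/validation split at tile level.

What the generator does **not** emulate: stain variability and
deconvolution physics, nucleus texture/chromatin structure, overlapping
or touching nuclei, scanner artifacts, and whole-slide context. Passing
the desk-scale learning tests therefore demonstrates that the
architecture, gradients and pipeline work end to end — not that the
reported clinical-slide accuracy transfers.

# Problem sizes used by the tests

The test suite trains the `tinyModelSpec()` network on 64 px tiles with
3–6 nuclei of 4–8 px semi-axes: 20 training and 5 validation tiles for
30 epochs (reaching validation Dice above 0.85), and a single-tile
overfit for 200 steps (Dice above 0.95). These sizes were chosen as the
smallest round numbers at which the learning behaviour is unambiguous.
Operator correctness is established separately, against brute-force
oracles at small sizes, so the desk-scale runs only need to demonstrate
optimization, not correctness.

# Known limitations

* Training is CPU-bound R; the full 512 px, 500-epoch regime of the
  original setting is out of reach here and is documented as requiring
  a GPU port.
* Only binary (nucleus/background) heads are supported.
* The exact configuration behind the published parameter count is not
  recoverable from the text, so parameter parity is not asserted;
  `countParameters()` reports exact counts for any configuration.
* AUC is not reported: it would require score-calibration choices the
  method's description does not make. Probability maps can be saved at
  prediction time for downstream ROC analysis.
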