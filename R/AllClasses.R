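#' @import methods
#' @importFrom stats rnorm runif plogis pnorm dnorm
NULL

#' Guided-filter denoising parameters
#'
#' Parameters of the edge-preserving guided filter and the optional bilateral
#' post-filter. The filter window is \code{(2*radius+1)} pixels square and
#' \code{epsilon} is the regularizer on the variance of the guidance image,
#' on the normalized \code{[0,1]} intensity scale. The bilateral stage is
#' disabled by default.
#'
#' @slot radius integer window half-width r (window is (2r+1) x (2r+1)).
#' @slot epsilon non-negative regularizer on the [0,1] intensity scale.
#' @slot bilateralEnabled logical; run the bilateral post-filter.
#' @slot bilateralSigmaSpatial spatial Gaussian sigma of the bilateral
#'   filter, in pixels.
#' @slot bilateralSigmaRange range (intensity) Gaussian sigma of the
#'   bilateral filter, on the [0,1] scale.
#' @exportClass DenoiseParams
setClass("DenoiseParams",
  representation(
    radius = "integer",
    epsilon = "numeric",
    bilateralEnabled = "logical",
    bilateralSigmaSpatial = "numeric",
    bilateralSigmaRange = "numeric"
  ),
  prototype(
    radius = 4L, epsilon = 0.01, bilateralEnabled = FALSE,
    bilateralSigmaSpatial = 3, bilateralSigmaRange = 0.1
  )
)

setValidity("DenoiseParams", function(object) {
  msg <- NULL
  if (length(object@radius) != 1L || object@radius < 1L)
    msg <- c(msg, "radius must be a single integer >= 1")
  if (length(object@epsilon) != 1L || object@epsilon < 0)
    msg <- c(msg, "epsilon must be a single number >= 0")
  if (object@bilateralSigmaSpatial <= 0 || object@bilateralSigmaRange <= 0)
    msg <- c(msg, "bilateral sigmas must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param radius integer window half-width.
#' @param epsilon non-negative regularizer.
#' @param bilateral logical, enable the bilateral post-filter.
#' @param sigmaSpatial,sigmaRange bilateral filter sigmas.
#' @return A \code{DenoiseParams} object.
#' @rdname DenoiseParams-class
#' @examples
#' denoiseParams(radius = 4, epsilon = 0.01)
#' @export
denoiseParams <- function(radius = 4L, epsilon = 0.01, bilateral = FALSE,
                          sigmaSpatial = 3, sigmaRange = 0.1) {
  new("DenoiseParams", radius = as.integer(radius), epsilon = epsilon,
      bilateralEnabled = isTRUE(bilateral),
      bilateralSigmaSpatial = sigmaSpatial, bilateralSigmaRange = sigmaRange)
}

setMethod("show", "DenoiseParams", function(object) {
  cat("DenoiseParams: r =", object@radius, ", epsilon =", object@epsilon,
      if (object@bilateralEnabled) {
        sprintf(", bilateral (sigma_s = %g px, sigma_r = %g)",
                object@bilateralSigmaSpatial, object@bilateralSigmaRange)
      } else ", bilateral off", "\n")
})

#' Composite segmentation loss weights
#'
#' Weights of the composite training loss
#' \code{loss = diceWeight * softDiceLoss + bceWeight * BCE}; the two weights
#' must sum to one. \code{smoothing} is the additive smoothing constant of the
#' soft Dice term (on pixel counts).
#'
#' @slot diceWeight,bceWeight non-negative weights summing to 1.
#' @slot smoothing positive Dice smoothing constant.
#' @exportClass LossWeights
setClass("LossWeights",
  representation(diceWeight = "numeric", bceWeight = "numeric",
                 smoothing = "numeric"),
  prototype(diceWeight = 0.6, bceWeight = 0.4, smoothing = 1)
)

setValidity("LossWeights", function(object) {
  msg <- NULL
  if (abs(object@diceWeight + object@bceWeight - 1) > 1e-12)
    msg <- c(msg, "diceWeight + bceWeight must equal 1")
  if (object@diceWeight < 0 || object@bceWeight < 0)
    msg <- c(msg, "loss weights must be non-negative")
  if (object@smoothing <= 0)
    msg <- c(msg, "smoothing must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param dice,bce weights of the Dice and binary cross-entropy terms.
#' @param smoothing Dice smoothing constant.
#' @return A \code{LossWeights} object.
#' @rdname LossWeights-class
#' @export
lossWeights <- function(dice = 0.6, bce = 0.4, smoothing = 1) {
  new("LossWeights", diceWeight = dice, bceWeight = bce, smoothing = smoothing)
}

#' Segmentation network architecture specification
#'
#' Configuration of the dual-attention U-shaped transformer. The encoder
#' embeds the image with an overlapping patch embedding (stride 4), then runs
#' three stages of dual-attention blocks at resolutions H/4 (dim C), H/8
#' (2C) and H/16 (4C), with 2x2 patch merging between stages, followed by a
#' two-block bottleneck at H/16. The decoder mirrors the encoder with patch
#' expanding and cross-attention skip fusion, and a final 4x expansion plus
#' linear projection to per-pixel class scores.
#'
#' @slot inChannels number of input channels (3 for RGB).
#' @slot numClasses number of output classes (2: nucleus / background).
#' @slot baseDim embedding dimension C at the first stage.
#' @slot stageDepths integer vector, dual-attention blocks per encoder stage.
#' @slot headsPerStage integer vector, attention heads per stage.
#' @slot bottleneckDepth dual-attention blocks in the bottleneck.
#' @slot patchKernel,patchStride,patchPad overlapping patch embedding
#'   geometry; the stride is fixed at 4.
#' @slot ffnExpansion expansion ratio of the Mix-FFN hidden layer.
#' @slot dropout dropout rate applied inside attention/FFN during training.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    inChannels = "integer", numClasses = "integer", baseDim = "integer",
    stageDepths = "integer", headsPerStage = "integer",
    bottleneckDepth = "integer",
    patchKernel = "integer", patchStride = "integer", patchPad = "integer",
    ffnExpansion = "numeric", dropout = "numeric"
  ),
  prototype(
    inChannels = 3L, numClasses = 2L, baseDim = 64L,
    stageDepths = c(2L, 2L, 2L), headsPerStage = c(1L, 2L, 4L),
    bottleneckDepth = 2L,
    patchKernel = 7L, patchStride = 4L, patchPad = 3L,
    ffnExpansion = 4, dropout = 0
  )
)

setValidity("ModelSpec", function(object) {
  msg <- NULL
  if (object@patchStride != 4L)
    msg <- c(msg, "patch embedding stride must be 4 (factor-4 resolution reduction)")
  if (length(object@stageDepths) != length(object@headsPerStage))
    msg <- c(msg, "stageDepths and headsPerStage must have equal length")
  dims <- object@baseDim * 2^(seq_along(object@headsPerStage) - 1L)
  if (any(dims %% object@headsPerStage != 0L))
    msg <- c(msg, "stage dimension must be divisible by its head count")
  if (object@inChannels != 3L)
    msg <- c(msg, "inChannels must be 3 (RGB input)")
  if (object@numClasses != 2L)
    msg <- c(msg, "numClasses must be 2 (nucleus / background)")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@ffnExpansion < 1)
    msg <- c(msg, "ffnExpansion must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param baseDim embedding dimension C.
#' @param stageDepths blocks per encoder stage.
#' @param headsPerStage heads per stage.
#' @param bottleneckDepth blocks in the bottleneck.
#' @param ffnExpansion Mix-FFN expansion ratio.
#' @param dropout dropout rate.
#' @param numClasses number of classes.
#' @return A \code{ModelSpec} object.
#' @rdname ModelSpec-class
#' @examples
#' modelSpec(baseDim = 16, ffnExpansion = 2)  # desk-scale spec
#' @export
modelSpec <- function(baseDim = 64L, stageDepths = c(2L, 2L, 2L),
                      headsPerStage = c(1L, 2L, 4L), bottleneckDepth = 2L,
                      ffnExpansion = 4, dropout = 0, numClasses = 2L) {
  new("ModelSpec", baseDim = as.integer(baseDim),
      stageDepths = as.integer(stageDepths),
      headsPerStage = as.integer(headsPerStage),
      bottleneckDepth = as.integer(bottleneckDepth),
      ffnExpansion = ffnExpansion, dropout = dropout,
      numClasses = as.integer(numClasses))
}

#' A small architecture for desk-scale experiments and tests
#'
#' @param baseDim embedding dimension, default 16.
#' @return A \code{ModelSpec} with C = \code{baseDim} and Mix-FFN expansion 2.
#' @export
tinyModelSpec <- function(baseDim = 16L) {
  modelSpec(baseDim = baseDim, ffnExpansion = 2)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: C =", object@baseDim,
      "| stages", paste(object@stageDepths, collapse = "/"),
      "| heads", paste(object@headsPerStage, collapse = "/"),
      "| bottleneck", object@bottleneckDepth,
      "| FFN x", object@ffnExpansion, "\n")
})

#' Synthetic H&E-like tile generator specification
#'
#' Conditions under which synthetic tiles are generated: elliptical
#' hematoxylin-stained nuclei on an eosin-like background with a smooth
#' low-frequency texture, corrupted by Gaussian plus salt-and-pepper noise.
#'
#' @slot tileSize tile side in pixels, divisible by 16 (default 512).
#' @slot nNucleiRange integer range of nuclei per tile.
#' @slot axisRange range of ellipse semi-axis lengths in pixels.
#' @slot nucleusColor,nucleusSigma mean RGB and per-nucleus sd of the
#'   nucleus stain (hematoxylin-like purple).
#' @slot backgroundColor,backgroundSigma mean RGB and per-tile sd of the
#'   background stain (eosin-like pink).
#' @slot textureAmplitude amplitude of the smooth background texture.
#' @slot gaussianSigma sd of the additive Gaussian noise.
#' @slot saltPepperFraction fraction of pixels hit by impulse noise.
#' @slot seed base RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    tileSize = "integer", nNucleiRange = "integer", axisRange = "numeric",
    nucleusColor = "numeric", nucleusSigma = "numeric",
    backgroundColor = "numeric", backgroundSigma = "numeric",
    textureAmplitude = "numeric", gaussianSigma = "numeric",
    saltPepperFraction = "numeric", seed = "integer"
  ),
  prototype(
    tileSize = 512L, nNucleiRange = c(8L, 16L), axisRange = c(10, 24),
    nucleusColor = c(0.35, 0.25, 0.55), nucleusSigma = 0.03,
    backgroundColor = c(0.90, 0.75, 0.85), backgroundSigma = 0.02,
    textureAmplitude = 0.02, gaussianSigma = 0.05,
    saltPepperFraction = 0.02, seed = 42L
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (object@tileSize %% 16L != 0L)
    msg <- c(msg, "tileSize must be divisible by 16")
  if (object@saltPepperFraction < 0 || object@saltPepperFraction > 1)
    msg <- c(msg, "saltPepperFraction must be in [0, 1]")
  if (length(object@nucleusColor) != 3L || length(object@backgroundColor) != 3L)
    msg <- c(msg, "stain colors must be RGB triples")
  if (length(object@nNucleiRange) != 2L || any(object@nNucleiRange < 0L))
    msg <- c(msg, "nNucleiRange must be two non-negative integers")
  if (length(object@axisRange) != 2L || any(object@axisRange <= 0))
    msg <- c(msg, "axisRange must be two positive lengths")
  if (object@gaussianSigma < 0)
    msg <- c(msg, "gaussianSigma must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param tileSize tile side in pixels.
#' @param nNucleiRange integer range of nuclei per tile.
#' @param axisRange ellipse semi-axis range in pixels.
#' @param gaussianSigma Gaussian noise sd.
#' @param saltPepperFraction impulse-noise pixel fraction.
#' @param seed base RNG seed.
#' @param ... further slots passed to \code{new()}.
#' @return A \code{SyntheticSpec} object.
#' @rdname SyntheticSpec-class
#' @examples
#' syntheticSpec(tileSize = 64, nNucleiRange = c(3, 6), axisRange = c(4, 8))
#' @export
syntheticSpec <- function(tileSize = 512L, nNucleiRange = c(8L, 16L),
                          axisRange = c(10, 24), gaussianSigma = 0.05,
                          saltPepperFraction = 0.02, seed = 42L, ...) {
  new("SyntheticSpec", tileSize = as.integer(tileSize),
      nNucleiRange = as.integer(nNucleiRange), axisRange = axisRange,
      gaussianSigma = gaussianSigma, saltPepperFraction = saltPepperFraction,
      seed = as.integer(seed), ...)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@tileSize, "x", object@tileSize, "px,",
      object@nNucleiRange[1], "-", object@nNucleiRange[2], "nuclei,",
      "noise: gaussian sd", object@gaussianSigma,
      "+ salt-pepper", object@saltPepperFraction, "\n")
})

#' Training configuration
#'
#' Optimization settings for the segmentation network: SGD with momentum 0.9,
#' base learning rate 0.05, weight decay 1e-4 and batch size 4. The epoch
#' count defaults to 500 for full-scale runs; desk-scale runs use far fewer.
#'
#' @slot baseLr base learning rate.
#' @slot momentum SGD momentum.
#' @slot weightDecay L2 weight decay.
#' @slot batchSize mini-batch size.
#' @slot epochs number of training epochs.
#' @slot patience early-stopping patience on validation Dice, in epochs.
#' @slot seed RNG seed driving weight init and shuffling.
#' @slot loss a \code{LossWeights} object.
#' @slot gradClip global gradient-norm clip threshold.
#' @slot denoiseInputs logical; guided-filter inputs before training and
#'   prediction.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    baseLr = "numeric", momentum = "numeric", weightDecay = "numeric",
    batchSize = "integer", epochs = "integer", patience = "integer",
    seed = "integer", loss = "LossWeights", gradClip = "numeric",
    denoiseInputs = "logical"
  ),
  prototype(
    baseLr = 0.05, momentum = 0.9, weightDecay = 1e-4, batchSize = 4L,
    epochs = 500L, patience = 20L, seed = 42L,
    loss = new("LossWeights"), gradClip = 1, denoiseInputs = TRUE
  )
)

setValidity("TrainConfig", function(object) {
  msg <- NULL
  if (object@baseLr <= 0) msg <- c(msg, "baseLr must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @param baseLr base learning rate.
#' @param momentum SGD momentum.
#' @param weightDecay L2 weight decay.
#' @param batchSize mini-batch size.
#' @param epochs training epochs.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed.
#' @param loss a \code{LossWeights}.
#' @param gradClip global gradient-norm clip threshold.
#' @param denoiseInputs guided-filter inputs first.
#' @return A \code{TrainConfig} object.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(baseLr = 0.05, momentum = 0.9, weightDecay = 1e-4,
                        batchSize = 4L, epochs = 500L, patience = 20L,
                        seed = 42L, loss = lossWeights(), gradClip = 1,
                        denoiseInputs = TRUE) {
  new("TrainConfig", baseLr = baseLr, momentum = momentum,
      weightDecay = weightDecay, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), patience = as.integer(patience),
      seed = as.integer(seed), loss = loss, gradClip = gradClip,
      denoiseInputs = isTRUE(denoiseInputs))
}

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig: SGD lr", object@baseLr, "momentum", object@momentum,
      "wd", object@weightDecay, "| batch", object@batchSize,
      "| epochs", object@epochs, "| seed", object@seed, "\n")
})

#' Dual-attention U-shaped transformer model
#'
#' Holds the architecture specification and the named list of trainable
#' parameter arrays. Create with \code{\link{buildModel}}.
#'
#' @slot spec a \code{ModelSpec}.
#' @slot params named list of numeric arrays (weights).
#' @exportClass DualAttentionUNet
setClass("DualAttentionUNet",
  representation(spec = "ModelSpec", params = "list"))

setMethod("show", "DualAttentionUNet", function(object) {
  cat("DualAttentionUNet with", length(object@params), "parameter tensors,",
      format(countParameters(object), big.mark = ","),
      "trainable scalars\n")
  show(object@spec)
})

#' @describeIn DualAttentionUNet-class the architecture specification.
#' @param object a \code{DualAttentionUNet}.
#' @export
setGeneric("modelSpecOf", function(object) standardGeneric("modelSpecOf"))

#' @rdname DualAttentionUNet-class
#' @export
setMethod("modelSpecOf", "DualAttentionUNet", function(object) object@spec)
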