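## The U-shaped network. Encoder: overlapping patch embedding (H/4, C),
## stage 1 dual blocks, merge, stage 2 (H/8, 2C), merge, stage 3 (H/16,
## 4C), then a two-block bottleneck at H/16. Decoder: expand to H/8, fuse
## with the stage-2 skip, dual blocks, expand to H/4, fuse with stage 1,
## dual blocks, final 4x expansion and a linear head to per-pixel class
## scores. The printed dimension schedule (C, 2C, 4C at H/4, H/8, H/16) is
## authoritative, so there are two merges, not three.

forwardGraph <- function(ctx, img, spec) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("input height and width must be divisible by 16, got ",
         H, " x ", W)
  C <- spec@baseDim
  heads <- spec@headsPerStage
  depths <- spec@stageDepths
  ex <- spec@ffnExpansion

  em <- nfPatchEmbed(ctx, img, spec)
  x <- em$x; h <- em$h; w <- em$w

  for (b in seq_len(depths[1]))
    x <- nfDualBlock(ctx, sprintf("enc1.b%d", b), x, heads[1], C, h, w, ex)
  skip1 <- x

  x <- nfPatchMerge(ctx, "merge1", x, h, w, C)
  h <- h %/% 2L; w <- w %/% 2L
  for (b in seq_len(depths[2]))
    x <- nfDualBlock(ctx, sprintf("enc2.b%d", b), x, heads[2], 2L * C,
                     h, w, ex)
  skip2 <- x

  x <- nfPatchMerge(ctx, "merge2", x, h, w, 2L * C)
  h <- h %/% 2L; w <- w %/% 2L
  for (b in seq_len(depths[3]))
    x <- nfDualBlock(ctx, sprintf("enc3.b%d", b), x, heads[3], 4L * C,
                     h, w, ex)
  for (b in seq_len(spec@bottleneckDepth))
    x <- nfDualBlock(ctx, sprintf("bot.b%d", b), x, heads[3], 4L * C,
                     h, w, ex)

  x <- nfPatchExpand(ctx, "up2", x, h, w, 4L * C)
  h <- h * 2L; w <- w * 2L
  x <- nfScaFuse(ctx, "sca2", x, skip2, 2L * C)
  for (b in seq_len(depths[2]))
    x <- nfDualBlock(ctx, sprintf("dec2.b%d", b), x, heads[2], 2L * C,
                     h, w, ex)

  x <- nfPatchExpand(ctx, "up1", x, h, w, 2L * C)
  h <- h * 2L; w <- w * 2L
  x <- nfScaFuse(ctx, "sca1", x, skip1, C)
  for (b in seq_len(depths[1]))
    x <- nfDualBlock(ctx, sprintf("dec1.b%d", b), x, heads[1], C, h, w, ex)

  ## final 4x expansion: linear C -> 16C, two pixel shuffles, linear head
  x <- nfLinear(ctx, "final.expand", x, C, 16L * C)
  x <- adPixelShuffle2(x, h, w)
  x <- adPixelShuffle2(x, 2L * h, 2L * w)
  ## head bias starts at the imbalance-aware prior (foreground ~ 0.12) so
  ## early steps go into separating pixels, not drifting the global rate
  scores <- nfLinear(ctx, "final.head", x, C, spec@numClasses)
  prior <- nfParam(ctx, "final.prior", spec@numClasses, "zeros")
  if (ctx$init) {
    ctx$params[["final.prior"]] <- c(1, -1)   # fg logit -2, p ~ 0.12
    prior$value <- ctx$params[["final.prior"]]
  }
  scores <- adAddBias(scores, prior)
  list(scores = scores, H = H, W = W)
}

#' Build a dual-attention U-shaped transformer
#'
#' Initializes all trainable parameters under the given seed: fan-scaled
#' truncated-normal weights (scaled down on residual-branch output
#' projections to keep the residual stream near unit variance), zero
#' biases, unit LayerNorm gains, channel-attention temperatures at 1, and
#' a class-prior head bias.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param seed RNG seed for weight initialization.
#' @return a \code{\link{DualAttentionUNet}}.
#' @examples
#' m <- buildModel(tinyModelSpec(), seed = 1)
#' countParameters(m)
#' @export
buildModel <- function(spec = modelSpec(), seed = 42L) {
  validObject(spec)
  set.seed(seed)
  ctx <- newCtx(init = TRUE)
  dummy <- array(0, dim = c(32L, 32L, spec@inChannels))
  forwardGraph(ctx, dummy, spec)   # materializes every parameter
  new("DualAttentionUNet", spec = spec, params = ctx$params)
}

#' Per-pixel class scores for an image
#'
#' Runs the network forward (evaluation mode, no dropout) and returns raw
#' class scores. Height and width must be divisible by 16 (see
#' \code{\link{segmentTile}} for automatic padding).
#'
#' @param model a \code{\link{DualAttentionUNet}}.
#' @param img \code{c(h, w, 3)} array in \code{[0,1]}.
#' @return numeric array \code{c(h, w, numClasses)} of scores.
#' @export
forwardScores <- function(model, img) {
  assertRGB(img)
  ctx <- newCtx(params = model@params)
  fw <- forwardGraph(ctx, img, model@spec)
  array(fw$scores$value, dim = c(fw$H, fw$W, model@spec@numClasses))
}

#' Probability of nucleus per pixel
#'
#' Foreground (nucleus) probability, the softmax of the two class scores.
#'
#' @inheritParams forwardScores
#' @return h x w matrix of probabilities.
#' @export
nucleusProbability <- function(model, img) {
  s <- forwardScores(model, img)
  plogis(s[, , 2L] - s[, , 1L])
}

#' Segment a tile into a binary nucleus mask
#'
#' Predicts the nucleus mask by thresholding the foreground probability at
#' 0.5. Tiles whose sides are not divisible by 16 are reflectively padded
#' and the prediction cropped back.
#'
#' @inheritParams forwardScores
#' @param denoise optional \code{\link{DenoiseParams}}; if supplied, the
#'   tile is guided-filtered first.
#' @param threshold decision threshold on the foreground probability.
#' @return list with \code{mask} (0/1 matrix) and \code{prob}
#'   (probability matrix).
#' @export
segmentTile <- function(model, img, denoise = NULL, threshold = 0.5) {
  assertRGB(img)
  if (!is.null(denoise)) img <- guidedFilterRGB(img, denoise)
  H <- dim(img)[1]; W <- dim(img)[2]
  padH <- (16L - H %% 16L) %% 16L
  padW <- (16L - W %% 16L) %% 16L
  if (padH > 0L || padW > 0L) {
    img <- reflectPad(img, padH, padW)
  }
  prob <- nucleusProbability(model, img)
  prob <- prob[seq_len(H), seq_len(W), drop = FALSE]
  list(mask = (prob >= threshold) + 0, prob = prob)
}

reflectPad <- function(img, padH, padW) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(padH)])
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(padW)])
  img[ri, ci, , drop = FALSE]
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars in a model (or in the model a
#' specification would build).
#'
#' @param object a \code{DualAttentionUNet} or \code{ModelSpec}.
#' @return integer count.
#' @export
setGeneric("countParameters", function(object)
  standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "DualAttentionUNet", function(object) {
  sum(vapply(object@params, length, 0L))
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "ModelSpec", function(object) {
  countParameters(buildModel(object, seed = 0L))
})

#' Composite Dice + binary cross-entropy loss
#'
#' \code{loss = 0.6 * softDiceLoss + 0.4 * BCE} by default, where
#' \code{softDiceLoss = 1 - (2 |P.G| + s)/(|P| + |G| + s)} on foreground
#' probabilities P derived from the class scores, G the 0/1 truth mask and
#' s the smoothing constant.
#'
#' @param scores \code{c(h, w, 2)} score array (as from
#'   \code{\link{forwardScores}}).
#' @param mask 0/1 truth matrix of matching spatial shape.
#' @param weights a \code{\link{LossWeights}}.
#' @return named numeric vector: \code{total}, \code{dice} (Dice loss),
#'   \code{bce}.
#' @export
compositeLoss <- function(scores, mask, weights = lossWeights()) {
  assertMask(mask)
  if (!all(dim(scores)[1:2] == dim(mask)))
    stop("score and mask shapes do not match")
  z <- as.vector(scores[, , 2L] - scores[, , 1L])
  g <- as.vector(mask)
  p <- plogis(z)
  s <- weights@smoothing
  dice <- 1 - (2 * sum(p * g) + s) / (sum(p) + sum(g) + s)
  bce <- mean(pmax(z, 0) + log1p(exp(-abs(z))) - g * z)
  c(total = weights@diceWeight * dice + weights@bceWeight * bce,
    dice = dice, bce = bce)
}

## tape version of the composite loss; maskVec is a plain 0/1 vector in
## token order
adCompositeLoss <- function(scores, maskVec, weights) {
  z <- adFgLogit(scores)
  p <- adSigmoid(z)
  s <- weights@smoothing
  inter <- adSum(adMul(p, adConst(maskVec)))
  num <- adAddConst(adScale(inter, 2), s)
  den <- adAddConst(adSum(p), sum(maskVec) + s)
  diceLoss <- adAddConst(adScale(adDiv(num, den), -1), 1)
  bce <- adBceLogits(z, maskVec)
  adAdd(adScale(diceLoss, weights@diceWeight),
        adScale(bce, weights@bceWeight))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file embedding the architecture
#' specification and all parameter arrays.
#'
#' @param model a \code{DualAttentionUNet}.
#' @param path file path.
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the model.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "DualAttentionUNet"))
  saveRDS(list(spec = specAsList(model@spec), params = model@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  new("DualAttentionUNet", spec = specFromList(obj$spec),
      params = obj$params)
}

specAsList <- function(spec) {
  nm <- slotNames(spec)
  stats::setNames(lapply(nm, function(s) slot(spec, s)), nm)
}

specFromList <- function(lst) {
  do.call(new, c(list("ModelSpec"), lst))
}
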