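## Training, prediction and evaluation. The optimizer is SGD with momentum
## and weight decay; the loss is the composite Dice + BCE. Each epoch
## reports the mean training loss and the validation Dice; the checkpoint
## kept is the epoch with the best validation Dice, with early stopping on
## a patience window.

readManifest <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

loadPairs <- function(manifest, denoise = NULL) {
  manifest <- readManifest(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  missing <- !file.exists(manifest$image) | !file.exists(manifest$mask)
  if (any(missing))
    stop("manifest entries not found on disk: ",
         paste(manifest$image[missing], collapse = ", "))
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- readImageRGB(manifest$image[i])
    if (!is.null(denoise)) img <- guidedFilterRGB(img, denoise)
    list(image = img, mask = readMask(manifest$mask[i]),
         name = basename(manifest$image[i]))
  })
}

## one SGD step over a mini-batch; returns the batch loss
sgdStep <- function(model, state, batch, cfg) {
  adBegin()
  ctx <- newCtx(params = model@params, train = TRUE,
                dropout = model@spec@dropout)
  total <- NULL
  for (item in batch) {
    fw <- forwardGraph(ctx, item$image, model@spec)
    loss <- adCompositeLoss(fw$scores, as.vector(item$mask), cfg@loss)
    total <- if (is.null(total)) loss else adAdd(total, loss)
  }
  total <- adScale(total, 1 / length(batch))
  lossVal <- total$value
  if (!is.finite(lossVal)) {
    adEnd()
    stop("non-finite training loss; aborting (inspect learning rate/inputs)")
  }
  adBackward(total)
  lr <- cfg@baseLr; mom <- cfg@momentum; wd <- cfg@weightDecay
  ## clip by global gradient norm: SGD at the default base rate is
  ## otherwise derailed by the occasional large Dice-term gradient
  gnorm <- sqrt(sum(vapply(ctx$nodes, function(n)
    if (is.null(n$grad)) 0 else sum(n$grad^2), 0)))
  scale <- if (gnorm > cfg@gradClip) cfg@gradClip / gnorm else 1
  for (nm in names(ctx$nodes)) {
    g <- ctx$nodes[[nm]]$grad
    if (is.null(g)) next
    g <- g * scale + wd * model@params[[nm]]
    v <- state$velocity[[nm]]
    v <- if (is.null(v)) -lr * g else mom * v - lr * g
    state$velocity[[nm]] <- v
    model@params[[nm]] <- model@params[[nm]] + v
  }
  adEnd()
  list(model = model, loss = lossVal)
}

validationDice <- function(model, valData) {
  if (length(valData) == 0L) return(NA_real_)
  mean(vapply(valData, function(item) {
    pred <- (nucleusProbability(model, item$image) >= 0.5) + 0
    diceCoefficient(pred, item$mask)
  }, 0))
}

#' Train the segmentation network
#'
#' Full training loop: seeded initialization and shuffling, SGD with
#' momentum and weight decay on the composite Dice + BCE loss, per-epoch
#' training loss and validation Dice, checkpointing of the best-validation
#' epoch and early stopping when the validation Dice has not improved for
#' \code{cfg@patience} epochs. With \code{epochs = 0} the initialized
#' model is returned with its metrics.
#'
#' @param trainManifest,valManifest data.frames (or TSV paths) with columns
#'   \code{image} and \code{mask}.
#' @param spec a \code{\link{ModelSpec}}.
#' @param cfg a \code{\link{TrainConfig}}.
#' @param denoise optional \code{\link{DenoiseParams}} applied to every
#'   input tile before training (and to be applied again at prediction).
#' @param runDir optional directory; learning curves (CSV) and a run
#'   manifest (YAML) are written there.
#' @return list with \code{model} (best checkpoint), \code{history}
#'   (data.frame epoch/loss/valDice), \code{bestEpoch}, \code{bestDice}.
#' @export
trainModel <- function(trainManifest, valManifest = NULL,
                       spec = modelSpec(), cfg = trainConfig(),
                       denoise = NULL, runDir = NULL) {
  validObject(spec); validObject(cfg)
  if (isTRUE(cfg@denoiseInputs) && is.null(denoise))
    denoise <- denoiseParams()
  trainData <- loadPairs(trainManifest, denoise)
  valData <- if (is.null(valManifest)) list() else
    loadPairs(valManifest, denoise)

  model <- buildModel(spec, seed = cfg@seed)
  state <- new.env(parent = emptyenv())
  state$velocity <- list()

  best <- list(params = model@params,
               dice = validationDice(model, valData), epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        valDice = numeric())
  sinceBest <- 0L
  set.seed(cfg@seed + 1L)
  nTrain <- length(trainData)

  for (epoch in seq_len(cfg@epochs)) {
    ord <- sample(nTrain)
    starts <- seq(1L, nTrain, by = cfg@batchSize)
    losses <- numeric(length(starts))
    for (s in seq_along(starts)) {
      idx <- ord[starts[s]:min(starts[s] + cfg@batchSize - 1L, nTrain)]
      step <- sgdStep(model, state, trainData[idx], cfg)
      model <- step$model
      losses[s] <- step$loss
    }
    vd <- validationDice(model, valData)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         valDice = vd))
    improved <- !is.na(vd) && (is.na(best$dice) || vd > best$dice)
    if (improved || length(valData) == 0L) {
      best <- list(params = model@params, dice = vd, epoch = epoch)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= cfg@patience) break
    }
  }

  bestModel <- new("DualAttentionUNet", spec = spec, params = best$params)
  if (!is.null(runDir)) {
    dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(history, file.path(runDir, "learning_curves.csv"),
                     row.names = FALSE)
    manifest <- list(
      seed = cfg@seed, baseLr = cfg@baseLr, momentum = cfg@momentum,
      weightDecay = cfg@weightDecay, batchSize = cfg@batchSize,
      epochs = cfg@epochs, epochsRun = nrow(history),
      bestEpoch = best$epoch, bestValDice = best$dice,
      packageVersion = as.character(utils::packageVersion("nucformer")))
    yaml::write_yaml(manifest, file.path(runDir, "run_manifest.yaml"))
    saveCheckpoint(bestModel, file.path(runDir, "checkpoint.rds"))
  }
  list(model = bestModel, history = history,
       bestEpoch = best$epoch, bestDice = best$dice)
}

#' Predict nucleus masks for a directory of tiles
#'
#' Segments every image in \code{imageDir} and writes one \code{\{0,255\}}
#' mask PNG per input, mirroring the input filename. Re-running with the
#' same inputs reproduces identical outputs.
#'
#' @param model a \code{DualAttentionUNet} (or checkpoint path).
#' @param imageDir directory of input tiles.
#' @param outDir output directory, created if missing.
#' @param denoise optional \code{\link{DenoiseParams}} applied before
#'   segmentation.
#' @param saveProb if \code{TRUE}, also save probability maps as grayscale
#'   PNGs under \code{outDir/prob/}.
#' @return invisibly, the vector of written mask paths.
#' @export
predictDir <- function(model, imageDir, outDir, denoise = NULL,
                       saveProb = FALSE) {
  if (is.character(model)) model <- loadCheckpoint(model)
  files <- list.files(imageDir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE)
  if (length(files) == 0L) stop("no images found in ", imageDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (saveProb)
    dir.create(file.path(outDir, "prob"), showWarnings = FALSE)
  out <- character(length(files))
  for (i in seq_along(files)) {
    img <- readImageRGB(file.path(imageDir, files[i]))
    seg <- segmentTile(model, img, denoise = denoise)
    stem <- sub("\\.[^.]+$", ".png", files[i])
    out[i] <- file.path(outDir, stem)
    writeMask(seg$mask, out[i])
    if (saveProb)
      EBImage::writeImage(EBImage::Image(t(seg$prob)),
                          file.path(outDir, "prob", stem))
  }
  invisible(out)
}

#' Read a pipeline configuration from YAML
#'
#' Sections \code{denoise}, \code{model}, \code{train} and \code{data} map
#' to \code{\link{DenoiseParams}}, \code{\link{ModelSpec}},
#' \code{\link{TrainConfig}} and \code{\link{SyntheticSpec}}; absent
#' sections take the package defaults.
#'
#' @param path YAML file path.
#' @return list with elements \code{denoise}, \code{model}, \code{train},
#'   \code{data}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    denoise = do.call(denoiseParams, cfg$denoise %||% list()),
    model = do.call(modelSpec, cfg$model %||% list()),
    train = do.call(trainConfig, cfg$train %||% list()),
    data = do.call(syntheticSpec, cfg$data %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
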