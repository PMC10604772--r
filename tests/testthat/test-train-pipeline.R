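test_that("zero-epoch training returns the initialized model with metrics", {
  dir <- file.path(tempdir(), "zero-epoch")
  unlink(dir, recursive = TRUE)
  ds <- makeDataset(4, deskTileSpec(seed = 60L), dir, splitFraction = 0.5)
  cfg <- trainConfig(epochs = 0L, seed = 1L, denoiseInputs = FALSE)
  fit <- trainModel(ds$train, ds$val, spec = tinyModelSpec(8L), cfg = cfg)
  expect_s4_class(fit$model, "DualAttentionUNet")
  expect_equal(fit$bestEpoch, 0L)
  expect_true(is.finite(fit$bestDice))
  init <- buildModel(tinyModelSpec(8L), seed = 1L)
  expect_identical(fit$model@params, init@params)
})

test_that("training is reproducible under a fixed seed", {
  dir <- file.path(tempdir(), "repro")
  unlink(dir, recursive = TRUE)
  ds <- makeDataset(6, deskTileSpec(seed = 61L), dir)
  cfg <- trainConfig(epochs = 2L, seed = 5L, denoiseInputs = FALSE)
  run <- function() trainModel(ds$train, ds$val, spec = tinyModelSpec(8L),
                               cfg = cfg)
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$history$valDice, f2$history$valDice)
})

test_that("training aborts on empty or broken manifests", {
  expect_error(trainModel(data.frame(image = character(),
                                     mask = character()),
                          spec = tinyModelSpec(8L)),
               "empty")
  expect_error(trainModel(data.frame(image = "no-such-file.png",
                                     mask = "none.png"),
                          spec = tinyModelSpec(8L)),
               "not found")
})

test_that("prediction writes idempotent mask files that match the inputs", {
  fit <- trainedFixture()
  outDir <- file.path(tempdir(), "pred-out")
  unlink(outDir, recursive = TRUE)
  imgDir <- file.path(fit$dataDir, "images")
  p1 <- predictDir(fit$model, imgDir, outDir,
                   denoise = denoiseParams(), saveProb = TRUE)
  expect_true(all(file.exists(p1)))
  expect_setequal(basename(p1), list.files(imgDir))
  m <- readMask(p1[1])
  expect_true(all(m %in% c(0, 1)))
  expect_true(file.exists(file.path(outDir, "prob", basename(p1[1]))))
  md1 <- tools::md5sum(p1)
  predictDir(fit$model, imgDir, outDir, denoise = denoiseParams())
  expect_identical(unname(tools::md5sum(p1)), unname(md1))
})

test_that("denoising on versus off changes predictions on noisy tiles", {
  fit <- trainedFixture()
  tile <- generateTile(deskTileSpec(seed = 77L), noisy = TRUE)
  on <- segmentTile(fit$model, tile$noisyImage, denoise = denoiseParams())
  off <- segmentTile(fit$model, tile$noisyImage, denoise = NULL)
  expect_false(identical(on$prob, off$prob))
})

test_that("evaluating predictions against themselves yields perfect scores", {
  fit <- trainedFixture()
  maskDir <- file.path(fit$dataDir, "masks")
  res <- evaluateMasks(maskDir, maskDir)
  expect_true(all(res[res$image == "mean",
                      c("accuracy", "precision", "recall",
                        "iou", "dsc", "f1")] == 1))
})

test_that("denoise-before-segment helps on noisy validation tiles", {
  fit <- trainedFixture()
  val <- fit$dataset$val
  dsOn <- numeric(nrow(val)); dsOff <- numeric(nrow(val))
  for (i in seq_len(nrow(val))) {
    noisy <- readImageRGB(val$image[i])
    truth <- readMask(val$mask[i])
    dsOn[i] <- diceCoefficient(
      segmentTile(fit$model, noisy, denoise = denoiseParams())$mask, truth)
    dsOff[i] <- diceCoefficient(
      segmentTile(fit$model, noisy, denoise = NULL)$mask, truth)
  }
  expect_gt(mean(dsOn), mean(dsOff))
})

test_that("run artifacts capture enough to relaunch the run", {
  dir <- file.path(tempdir(), "runout")
  unlink(dir, recursive = TRUE)
  ds <- makeDataset(4, deskTileSpec(seed = 62L), dir, splitFraction = 0.5)
  runDir <- file.path(dir, "run")
  fit <- trainModel(ds$train, ds$val, spec = tinyModelSpec(8L),
                    cfg = trainConfig(epochs = 1L, seed = 2L,
                                      denoiseInputs = FALSE),
                    runDir = runDir)
  expect_true(file.exists(file.path(runDir, "learning_curves.csv")))
  expect_true(file.exists(file.path(runDir, "checkpoint.rds")))
  man <- yaml::read_yaml(file.path(runDir, "run_manifest.yaml"))
  expect_equal(man$seed, 2L)
  expect_equal(man$baseLr, 0.05)
  back <- loadCheckpoint(file.path(runDir, "checkpoint.rds"))
  expect_identical(back@params, fit$model@params)
})

test_that("YAML pipeline configuration round-trips into S4 objects", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "denoise:", "  radius: 3", "  epsilon: 0.02",
    "model:", "  baseDim: 16", "  ffnExpansion: 2",
    "train:", "  epochs: 7", "  seed: 9",
    "data:", "  tileSize: 64"), f)
  cfg <- readPipelineConfig(f)
  expect_equal(cfg$denoise@radius, 3L)
  expect_equal(cfg$model@baseDim, 16L)
  expect_equal(cfg$train@epochs, 7L)
  expect_equal(cfg$train@baseLr, 0.05)
  expect_equal(cfg$data@tileSize, 64L)
})
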