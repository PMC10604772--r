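nf <- asNamespace("nucformer")

tinySpec <- tinyModelSpec()

test_that("model specification enforces its invariants", {
  expect_error(modelSpec(baseDim = 10, headsPerStage = c(4, 4, 4)),
               "divisible")
  expect_error(modelSpec(stageDepths = c(2, 2), headsPerStage = c(1, 2, 4)),
               "length")
  sp <- tinyModelSpec()
  expect_equal(sp@patchStride, 4L)
})

test_that("patch embedding reduces resolution by a factor of four", {
  model <- buildModel(tinySpec, seed = 1)
  ctx <- nf$newCtx(params = model@params)
  set.seed(40)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  em <- nf$nfPatchEmbed(ctx, img, tinySpec)
  expect_equal(c(em$h, em$w), c(16L, 16L))
  expect_equal(dim(em$x$value), c(256L, 16L))
  # 512 x 512 grids embed to 128 x 128 tokens (geometry only)
  ec <- nf$embedColumns(array(0, c(512, 16, 3)), 7L, 4L, 3L)
  expect_equal(c(ec$h, ec$w), c(128L, 4L))
})

test_that("patch merging and expanding follow the 2x schedule", {
  model <- buildModel(tinySpec, seed = 1)
  ctx <- nf$newCtx(params = model@params)
  set.seed(41)
  x <- nf$adConst(matrix(rnorm(16 * 16 * 16), 256, 16))
  m <- nf$nfPatchMerge(ctx, "merge1", x, 16L, 16L, 16L)
  expect_equal(dim(m$value), c(64L, 32L))
  e <- nf$nfPatchExpand(ctx, "up1", nf$adConst(matrix(rnorm(64 * 32), 64)),
                        8L, 8L, 32L)
  expect_equal(dim(e$value), c(256L, 16L))
  expect_error(nf$nfPatchMerge(ctx, "m", x, 15L, 15L, 16L), "even")
})

test_that("pixel shuffle is an exact inverse-permutation pair", {
  set.seed(42)
  x <- matrix(rnorm(6 * 4 * 16), 24, 16)
  nd <- nf$adConst(x)
  nf$adBegin()
  y <- nf$adPixelShuffle2(nf$adNode(x, list(nd), function(g) list(g)), 6L, 4L)
  expect_equal(dim(y$value), c(96L, 4L))
  # back-propagating the shuffled values must reconstruct the input exactly
  loss <- nf$adSum(nf$adMul(y, nf$adConst(y$value)))
  nf$adBackward(loss)
  expect_equal(nd$grad, x, tolerance = 1e-12)
  nf$adEnd()
  # merging the expanded grid restores the grid shape
  sp <- tinySpec
  model <- buildModel(sp, seed = 2)
  ctx <- nf$newCtx(params = model@params)
  ex <- nf$nfPatchExpand(ctx, "up1", nf$adConst(matrix(rnorm(64 * 32), 64)),
                         8L, 8L, 32L)
  mg <- nf$nfPatchMerge(ctx, "merge1", ex, 16L, 16L, 16L)
  expect_equal(dim(mg$value), c(64L, 32L))
})

test_that("forward pass yields per-pixel scores and is deterministic", {
  model <- buildModel(tinySpec, seed = 3)
  set.seed(43)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  s1 <- forwardScores(model, img)
  expect_equal(dim(s1), c(64L, 64L, 2L))
  expect_true(all(is.finite(s1)))
  expect_identical(s1, forwardScores(model, img))
  expect_error(forwardScores(model, array(0, c(60, 64, 3))), "divisible")
  # every spatial size divisible by 16 in range works
  for (n in c(32L, 48L)) {
    s <- forwardScores(model, array(runif(n * n * 3), c(n, n, 3)))
    expect_equal(dim(s), c(n, n, 2L))
  }
})

test_that("segmentTile pads non-multiple-of-16 tiles reflectively", {
  model <- buildModel(tinySpec, seed = 3)
  img <- array(runif(40 * 52 * 3), c(40, 52, 3))
  seg <- segmentTile(model, img)
  expect_equal(dim(seg$mask), c(40L, 52L))
  expect_true(all(seg$mask %in% c(0, 1)))
})

test_that("zero-initialized residual branches make blocks the identity", {
  model <- buildModel(tinySpec, seed = 4)
  params <- model@params
  # zero every attention output projection and every FFN output projection
  for (nm in grep("(\\.o\\.w|\\.o\\.b|\\.fc2\\.w|\\.fc2\\.b)$",
                  names(params), value = TRUE))
    params[[nm]][] <- 0
  ctx <- nf$newCtx(params = params)
  set.seed(44)
  x <- matrix(rnorm(256 * 16), 256, 16)
  outE <- nf$nfDualBlock(ctx, "enc1.b1", nf$adConst(x), 1L, 16L, 16L, 16L, 2)
  expect_equal(outE$value, x, tolerance = 1e-12)
  # chains of such blocks (the whole encoder stage) stay the identity
  out2 <- nf$nfDualBlock(ctx, "enc1.b2", outE, 1L, 16L, 16L, 16L, 2)
  expect_equal(out2$value, x, tolerance = 1e-12)
})

test_that("dual block composition equals its four sub-steps applied in order", {
  model <- buildModel(tinySpec, seed = 5)
  ctx <- nf$newCtx(params = model@params)
  set.seed(45)
  x <- matrix(rnorm(64 * 16), 64, 16)
  block <- nf$nfDualBlock(ctx, "enc1.b1", nf$adConst(x), 1L, 16L, 8L, 8L, 2)
  ctx2 <- nf$newCtx(params = model@params)
  s <- nf$adConst(x)
  s <- nf$adAdd(s, nf$nfAttention(ctx2, "enc1.b1.ea", s, 1L, 16L, "efficient"))
  s <- nf$nfMixFfn(ctx2, "enc1.b1.ff1", s, 16L, 32L, 8L, 8L)
  s <- nf$adAdd(s, nf$nfAttention(ctx2, "enc1.b1.ta", s, 1L, 16L, "transposed"))
  s <- nf$nfMixFfn(ctx2, "enc1.b1.ff2", s, 16L, 32L, 8L, 8L)
  expect_equal(block$value, s$value, tolerance = 1e-6)
})

test_that("network attention agrees with the exported operators", {
  # the in-network efficient attention head reproduces efficientAttention()
  model <- buildModel(tinySpec, seed = 6)
  ctx <- nf$newCtx(params = model@params)
  set.seed(46)
  x <- matrix(rnorm(64 * 16), 64, 16)
  out <- nf$nfAttention(ctx, "enc1.b1.ea", nf$adConst(x), 1L, 16L,
                        "efficient")
  p <- model@params
  Q <- x %*% p[["enc1.b1.ea.q.w"]] + matrix(p[["enc1.b1.ea.q.b"]], 64, 16,
                                            byrow = TRUE)
  K <- x %*% p[["enc1.b1.ea.k.w"]] + matrix(p[["enc1.b1.ea.k.b"]], 64, 16,
                                            byrow = TRUE)
  V <- x %*% p[["enc1.b1.ea.v.w"]] + matrix(p[["enc1.b1.ea.v.b"]], 64, 16,
                                            byrow = TRUE)
  ref <- efficientAttention(Q, K, V) %*% p[["enc1.b1.ea.o.w"]] +
    matrix(p[["enc1.b1.ea.o.b"]], 64, 16, byrow = TRUE)
  expect_equal(out$value, ref, tolerance = 1e-10)
})

test_that("every trainable parameter receives a finite gradient", {
  model <- buildModel(tinySpec, seed = 7)
  set.seed(47)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mask <- matrix(rbinom(32 * 32, 1, 0.2), 32)
  nf$adBegin()
  ctx <- nf$newCtx(params = model@params)
  fw <- nf$forwardGraph(ctx, img, tinySpec)
  loss <- nf$adCompositeLoss(fw$scores, as.vector(mask), lossWeights())
  nf$adBackward(loss)
  for (nm in names(model@params)) {
    g <- ctx$nodes[[nm]]$grad
    expect_false(is.null(g), info = nm)
    expect_true(all(is.finite(g)), info = nm)
  }
  nf$adEnd()
})

test_that("gradients match central finite differences on sampled weights", {
  spec8 <- tinyModelSpec(8L)
  model <- buildModel(spec8, seed = 8)
  set.seed(48)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mask <- matrix(rbinom(32 * 32, 1, 0.3), 32)
  w <- lossWeights()
  lossOf <- function(params) {
    ctx <- nf$newCtx(params = params)
    fw <- nf$forwardGraph(ctx, img, spec8)
    nf$adCompositeLoss(fw$scores, as.vector(mask), w)$value
  }
  nf$adBegin()
  ctx <- nf$newCtx(params = model@params)
  fw <- nf$forwardGraph(ctx, img, spec8)
  loss <- nf$adCompositeLoss(fw$scores, as.vector(mask), w)
  nf$adBackward(loss)
  grads <- lapply(ctx$nodes, function(n) n$grad)
  nf$adEnd()
  set.seed(49)
  for (nm in sample(names(model@params), 8)) {
    k <- sample(length(model@params[[nm]]), 1)
    eps <- 1e-5
    up <- model@params; up[[nm]][k] <- up[[nm]][k] + eps
    dn <- model@params; dn[[nm]][k] <- dn[[nm]][k] - eps
    gnum <- (lossOf(up) - lossOf(dn)) / (2 * eps)
    expect_lt(abs(gnum - grads[[nm]][k]), 1e-6 + 1e-3 * abs(gnum))
  }
})

test_that("parameter counting is exact, deterministic and monotone", {
  m1 <- buildModel(tinyModelSpec(8L), seed = 9)
  m2 <- buildModel(tinyModelSpec(8L), seed = 10)
  expect_identical(countParameters(m1), countParameters(m2))
  expect_gt(countParameters(tinyModelSpec(16L)),
            countParameters(tinyModelSpec(8L)))
  # a single linear layer d_in -> d_out with bias: d_in*d_out + d_out
  ctx <- nf$newCtx(init = TRUE)
  nf$nfLinear(ctx, "probe", nf$adConst(matrix(0, 2, 5)), 5L, 3L)
  expect_equal(sum(lengths(ctx$params)), 5 * 3 + 3)
})

test_that("composite loss applies the 0.6/0.4 weighting as stated", {
  set.seed(50)
  for (k in 1:10) {
    scores <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    mask <- matrix(rbinom(256, 1, 0.4), 16)
    l <- compositeLoss(scores, mask)
    expect_equal(unname(l["total"]),
                 0.6 * unname(l["dice"]) + 0.4 * unname(l["bce"]),
                 tolerance = 1e-12)
  }
  # perfectly confident correct prediction: both terms vanish
  mask <- matrix(rbinom(256, 1, 0.3), 16)
  scores <- array(0, c(16, 16, 2))
  scores[, , 2] <- ifelse(mask == 1, 50, -50)
  l <- compositeLoss(scores, mask)
  expect_lt(unname(l["total"]), 0.01)
  # fully wrong confident prediction on an empty truth: Dice loss -> 1,
  # so its weighted share -> 0.6
  l2 <- compositeLoss(array(rep(c(-50, 50), each = 256), c(16, 16, 2)),
                      matrix(0, 16, 16))
  expect_equal(unname(0.6 * l2["dice"]), 0.6, tolerance = 5e-3)
  expect_error(compositeLoss(scores, matrix(2, 16, 16)), "0 or 1")
})

test_that("checkpoints round-trip models exactly", {
  model <- buildModel(tinyModelSpec(8L), seed = 11)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(model, f)
  back <- loadCheckpoint(f)
  expect_identical(back@params, model@params)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(forwardScores(back, img), forwardScores(model, img))
})
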