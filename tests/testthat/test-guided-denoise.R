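test_that("grayscale conversion uses BT.601 luminance", {
  expect_equal(toGrayscale(array(c(1, 0, 0), c(1, 1, 3)))[1, 1], 0.299)
  expect_equal(toGrayscale(array(0, c(4, 4, 3))), matrix(0, 4, 4))
  v <- matrix(runif(16), 4)
  achro <- array(rep(v, 3), c(4, 4, 3))
  expect_equal(toGrayscale(achro), v, tolerance = 1e-12)
  expect_error(toGrayscale(matrix(0, 4, 4)), "3")
})

test_that("box mean matches the naive window oracle and handles borders", {
  expect_equal(boxMean(matrix(c(0, 1, 0), 1), 1),
               matrix(c(0.5, 1 / 3, 0.5), 1))
  expect_equal(boxMean(matrix(pi, 9, 7), 3), matrix(pi, 9, 7))
  set.seed(10)
  for (r in c(1, 2, 5)) {
    x <- matrix(runif(13 * 17), 13)
    expect_lt(max(abs(boxMean(x, r) - bruteBoxMean(x, r))), 1e-10)
  }
  expect_error(boxMean(matrix(0, 4, 4), 0), "radius")
})

test_that("box mean arithmetic is radius-independent (running sums)", {
  x <- matrix(runif(512 * 512), 512)
  t1 <- system.time(for (k in 1:3) boxMean(x, 4))["elapsed"]
  t2 <- system.time(for (k in 1:3) boxMean(x, 64))["elapsed"]
  # a naive windowed mean would be ~256x slower at 16x the radius
  expect_lt(t2, 3 * t1 + 0.05)
})

test_that("guided filter is the identity when K = q and epsilon = 0", {
  set.seed(1)
  q <- matrix(runif(256), 16)
  gf <- guidedFilter(q, q, denoiseParams(radius = 2, epsilon = 0),
                     coefficients = TRUE)
  expect_lt(max(abs(gf$a - 1)), 1e-12)
  expect_lt(max(abs(gf$b)), 1e-12)
  expect_lt(max(abs(gf$output - q)), 1e-10)
})

test_that("guided filter tends to a double box mean for huge epsilon", {
  set.seed(2)
  q <- matrix(runif(256), 16)
  out <- guidedFilter(q, q, denoiseParams(radius = 2, epsilon = 1e6))
  expect_lt(max(abs(out - boxMean(boxMean(q, 2), 2))), 1e-6)
})

test_that("guided filter matches the per-window brute-force oracle", {
  set.seed(3)
  for (k in 1:6) {
    n <- sample(9:32, 1)
    m <- sample(9:32, 1)
    q <- matrix(runif(n * m), n)
    K <- if (k %% 2 == 0) q else matrix(runif(n * m), n)
    r <- sample(1:3, 1)
    eps <- sample(c(0, 0.01, 0.1), 1)
    got <- guidedFilter(q, K, denoiseParams(radius = r, epsilon = eps))
    expect_lt(max(abs(got - bruteGuidedFilter(q, K, r, eps))), 1e-8)
  }
})

test_that("zero-variance windows with epsilon 0 reproduce constant regions", {
  q <- matrix(0.4, 12, 12)
  out <- guidedFilter(q, q, denoiseParams(radius = 2, epsilon = 0))
  expect_equal(out, q, tolerance = 1e-12)
})

test_that("guided filter validates its inputs", {
  q <- matrix(runif(64), 8)
  expect_error(guidedFilter(q, matrix(0, 4, 4)), "shape")
  expect_error(denoiseParams(epsilon = -1), "epsilon")
  expect_error(denoiseParams(radius = 0), "radius")
})

test_that("RGB filtering shares one gray guide across channels", {
  set.seed(4)
  v <- matrix(runif(256), 16)
  achro <- array(rep(v, 3), c(16, 16, 3))
  p <- denoiseParams(radius = 2, epsilon = 0.01)
  out <- guidedFilterRGB(achro, p)
  ref <- guidedFilter(v, v, p)
  for (ch in 1:3) expect_equal(out[, , ch], clip01(ref), tolerance = 1e-12)
})

test_that("guided filtering improves color PSNR on a noisy synthetic tile", {
  tile <- generateTile(deskTileSpec(seed = 5L), noisy = TRUE)
  den <- guidedFilterRGB(tile$noisyImage, denoiseParams())
  expect_gt(psnrColor(den, tile$image), psnrColor(tile$noisyImage, tile$image))
})

test_that("the slope is non-negative for a self-guided filter", {
  # Eq-5-style local linear model: a_k = var/(var+eps) >= 0 when K = q
  set.seed(6)
  q <- matrix(runif(400), 20)
  gf <- guidedFilter(q, q, denoiseParams(radius = 3, epsilon = 0.05),
                     coefficients = TRUE)
  expect_true(all(gf$a >= 0))
  expect_true(all(gf$a <= 1))
})

test_that("bilateral post-filter keeps constants, edges, and the Gaussian limit", {
  const <- array(0.5, c(12, 12, 3))
  p <- denoiseParams(bilateral = TRUE, sigmaSpatial = 1.5, sigmaRange = 0.1)
  expect_equal(bilateralPost(const, p), const, tolerance = 1e-12)

  # sigma_range -> Inf: converges to a normalized spatial Gaussian blur
  set.seed(7)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pInf <- denoiseParams(bilateral = TRUE, sigmaSpatial = 1.5,
                        sigmaRange = 1e6)
  got <- bilateralPost(img, pInf)
  R <- ceiling(3 * 1.5)
  gauss <- function(x, ss) {
    h <- nrow(x); w <- ncol(x)
    num <- matrix(0, h, w); den <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      wi <- max(1, i - R):min(h, i + R)
      wj <- max(1, j - R):min(w, j + R)
      wgt <- exp(-(outer((wi - i)^2, (wj - j)^2, "+")) / (2 * ss^2))
      num[i, j] <- sum(wgt * x[wi, wj]); den[i, j] <- sum(wgt)
    }
    num / den
  }
  for (ch in 1:3)
    expect_lt(max(abs(got[, , ch] - gauss(img[, , ch], 1.5))), 1e-3)

  # a step edge stays at the same location
  step <- array(0, c(8, 16, 3)); step[, 9:16, ] <- 1
  ps <- denoiseParams(bilateral = TRUE, sigmaSpatial = 2, sigmaRange = 0.05)
  sm <- bilateralPost(step, ps)
  grad <- abs(diff(sm[4, , 1]))
  expect_equal(which.max(grad), 8L)
  expect_error(bilateralPost(step, denoiseParams(bilateral = TRUE,
                                                 sigmaRange = -1)),
               "positive")
})
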