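## Synthetic H&E-like tiles with paired ground-truth nucleus masks. Nuclei
## are filled ellipses with random orientation in hematoxylin-like purple
## on an eosin-like pink background carrying a smooth low-frequency
## texture; corruption is Gaussian plus salt-and-pepper noise. The smooth
## texture (rather than white noise) lets denoising experiments separate
## texture preservation from noise removal.

#' Generate one synthetic tile with its nucleus mask
#'
#' Places non-overlapping elliptical nuclei by rejection sampling (ellipses
#' are kept one dilation step apart so the mask's connected-component count
#' equals the nucleus count) and returns the clean tile and its binary
#' mask. Deterministic given \code{spec@seed}.
#'
#' @param spec a \code{\link{SyntheticSpec}}.
#' @param noisy if \code{TRUE}, also return the tile with the spec's noise
#'   model applied.
#' @return list with \code{image} (clean \code{c(h,w,3)} array),
#'   \code{mask} (0/1 matrix), and if requested \code{noisyImage}.
#' @examples
#' tile <- generateTile(syntheticSpec(tileSize = 64, nNucleiRange = c(3, 5),
#'                                    axisRange = c(4, 8), seed = 7))
#' sum(tile$mask)
#' @export
generateTile <- function(spec = syntheticSpec(), noisy = FALSE) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@tileSize
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)

  ## eosin-like background with a smooth sinusoid texture
  base <- spec@backgroundColor + rnorm(3L, 0, spec@backgroundSigma)
  tex <- matrix(0, n, n)
  for (k in 1:3) {
    fy <- runif(1, 0.5, 3) / n; fx <- runif(1, 0.5, 3) / n
    ph <- runif(1, 0, 2 * pi)
    tex <- tex + sin(2 * pi * (fy * yy + fx * xx) + ph) / 3
  }
  tex <- tex * spec@textureAmplitude
  img <- array(0, dim = c(n, n, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] + tex

  ## non-overlapping elliptical nuclei by bounded rejection sampling
  mask <- matrix(0, n, n)
  guard <- matrix(0, n, n)   # mask dilated by ~1.5 px, enforces separation
  nNuc <- if (spec@nNucleiRange[2] > spec@nNucleiRange[1]) {
    sample(spec@nNucleiRange[1]:spec@nNucleiRange[2], 1L)
  } else spec@nNucleiRange[1]
  placed <- 0L
  tries <- 0L
  while (placed < nNuc) {
    tries <- tries + 1L
    if (tries > 1000L)
      stop("infeasible nucleus packing: placed ", placed, " of ", nNuc,
           " after 1000 attempts; reduce count or axis lengths")
    a <- runif(1, spec@axisRange[1], spec@axisRange[2])
    b <- runif(1, spec@axisRange[1], spec@axisRange[2])
    th <- runif(1, 0, pi)
    cy <- runif(1, 1 + a, n - a)
    cx <- runif(1, 1 + b, n - b)
    ell <- ellipseMask(yy, xx, cy, cx, a, b, th, pad = 0)
    grd <- ellipseMask(yy, xx, cy, cx, a, b, th, pad = 1.5)
    if (any(guard[grd] > 0)) next
    col <- spec@nucleusColor + rnorm(3L, 0, spec@nucleusSigma)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ell] <- col[ch]
      img[, , ch] <- plane
    }
    mask[ell] <- 1
    guard[grd] <- 1
    placed <- placed + 1L
  }
  img <- clip01(img)
  out <- list(image = img, mask = mask)
  if (noisy) {
    noisyImg <- addGaussianNoise(img, spec@gaussianSigma)
    noisyImg <- addSaltPepper(noisyImg, spec@saltPepperFraction)
    out$noisyImage <- noisyImg
  }
  out
}

ellipseMask <- function(yy, xx, cy, cx, a, b, theta, pad = 0) {
  dy <- yy - cy; dx <- xx - cx
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  (u / (a + pad))^2 + (v / (b + pad))^2 <= 1
}

#' Add i.i.d. Gaussian noise to an image
#'
#' Zero-mean Gaussian noise added independently per channel, clipped to
#' \code{[0,1]}.
#'
#' @param img \code{c(h,w,3)} array.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional RNG seed.
#' @return noisy RGB array.
#' @export
addGaussianNoise <- function(img, sigma, seed = NULL) {
  assertRGB(img)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  if (!is.null(seed)) set.seed(seed)
  clip01(img + array(rnorm(length(img), 0, sigma), dim = dim(img)))
}

#' Add salt-and-pepper noise to an image
#'
#' A \code{fraction} share of pixels is set to pure black or white (equal
#' odds, all three channels of a hit pixel); the rest are untouched.
#'
#' @param img \code{c(h,w,3)} array.
#' @param fraction fraction of pixels corrupted, in \code{[0,1]}.
#' @param seed optional RNG seed.
#' @return noisy RGB array.
#' @export
addSaltPepper <- function(img, fraction, seed = NULL) {
  assertRGB(img)
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  if (fraction == 0) return(img)
  if (!is.null(seed)) set.seed(seed)
  h <- dim(img)[1]; w <- dim(img)[2]
  nPix <- h * w
  hit <- which(runif(nPix) < fraction)
  if (length(hit) == 0L) return(img)
  val <- sample(c(0, 1), length(hit), replace = TRUE)
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[hit] <- val
    out[, , ch] <- plane
  }
  out
}

#' Translate a tile and its mask jointly
#'
#' Applies the same integer pixel shift to image and mask (the training
#' augmentation); vacated strips take the background fill color in the
#' image and 0 in the mask.
#'
#' @param img \code{c(h,w,3)} array.
#' @param mask 0/1 matrix.
#' @param shift integer vector \code{c(dy, dx)}; if \code{NULL}, drawn
#'   uniformly from \code{[-maxShift, maxShift]^2}.
#' @param maxShift bound on the random shift.
#' @param fill RGB fill for vacated pixels.
#' @param seed optional RNG seed for the random shift.
#' @return list with shifted \code{image} and \code{mask}.
#' @export
augmentTranslate <- function(img, mask, shift = NULL, maxShift = 16L,
                             fill = c(0.90, 0.75, 0.85), seed = NULL) {
  assertRGB(img); assertMask(mask)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(shift))
    shift <- sample(seq(-maxShift, maxShift), 2L, replace = TRUE)
  dy <- as.integer(shift[1]); dx <- as.integer(shift[2])
  h <- dim(img)[1]; w <- dim(img)[2]
  outImg <- array(rep(fill, each = h * w), dim = dim(img))
  outMask <- matrix(0, h, w)
  srcY <- seq_len(h) - dy; srcX <- seq_len(w) - dx
  okY <- srcY >= 1L & srcY <= h; okX <- srcX >= 1L & srcX <= w
  if (any(okY) && any(okX)) {
    outImg[which(okY), which(okX), ] <- img[srcY[okY], srcX[okX], ,
                                            drop = FALSE]
    outMask[which(okY), which(okX)] <- mask[srcY[okY], srcX[okX]]
  }
  list(image = outImg, mask = outMask)
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{clean/}, \code{images/} (noisy) and \code{masks/}
#' subdirectories of \code{n} tiles plus seeded-random 80/20 (by default)
#' train/validation manifests. Tile i is generated with seed
#' \code{spec@seed + i}, so the dataset is reproducible.
#'
#' @param n number of tiles (>= 2).
#' @param spec a \code{\link{SyntheticSpec}}.
#' @param dir output directory, created if missing.
#' @param splitFraction train fraction in (0, 1).
#' @param augment if \code{TRUE}, each training tile is also written in a
#'   translated copy.
#' @return list of data.frames \code{train} and \code{val} with columns
#'   \code{image}, \code{mask}, \code{clean}; also written as
#'   \code{train_manifest.tsv} / \code{val_manifest.tsv} in \code{dir}.
#' @export
makeDataset <- function(n, spec = syntheticSpec(), dir,
                        splitFraction = 0.8, augment = FALSE) {
  if (n < 2L) stop("need at least 2 tiles to split")
  if (splitFraction <= 0 || splitFraction >= 1)
    stop("splitFraction must be in (0, 1)")
  for (d in c("clean", "images", "masks"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tspec <- spec
    tspec@seed <- spec@seed + i
    tile <- generateTile(tspec, noisy = TRUE)
    stem <- sprintf("tile_%04d.png", i)
    writeImageRGB(tile$image, file.path(dir, "clean", stem))
    writeImageRGB(tile$noisyImage, file.path(dir, "images", stem))
    writeMask(tile$mask, file.path(dir, "masks", stem))
    rows[[i]] <- data.frame(
      image = file.path(dir, "images", stem),
      mask = file.path(dir, "masks", stem),
      clean = file.path(dir, "clean", stem))
  }
  manifest <- do.call(rbind, rows)

  set.seed(spec@seed)
  nTrain <- max(1L, min(n - 1L, round(splitFraction * n)))
  trainIdx <- sort(sample(n, nTrain))
  train <- manifest[trainIdx, , drop = FALSE]
  val <- manifest[-trainIdx, , drop = FALSE]

  if (augment) {
    aug <- vector("list", nrow(train))
    for (j in seq_len(nrow(train))) {
      img <- readImageRGB(train$image[j])
      msk <- readMask(train$mask[j])
      sh <- augmentTranslate(img, msk, maxShift = spec@tileSize %/% 8L,
                             fill = spec@backgroundColor,
                             seed = spec@seed + 10000L + j)
      stem <- sprintf("tile_aug_%04d.png", j)
      writeImageRGB(sh$image, file.path(dir, "images", stem))
      writeMask(sh$mask, file.path(dir, "masks", stem))
      aug[[j]] <- data.frame(image = file.path(dir, "images", stem),
                             mask = file.path(dir, "masks", stem),
                             clean = NA_character_)
    }
    train <- rbind(train, do.call(rbind, aug))
  }

  utils::write.table(train, file.path(dir, "train_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(val, file.path(dir, "val_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(train = train, val = val)
}
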