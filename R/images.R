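## Image containers are plain base-R arrays on the [0,1] intensity scale:
## an RGB image is height x width x 3, a grayscale image or binary mask is
## height x width. EBImage handles the file formats; its x-first layout is
## transposed to row-major (y, x) on the way in and out.

#' Read an RGB image
#'
#' Reads a PNG/TIFF/JPEG image and returns a height x width x 3 array of
#' intensities in \code{[0,1]} (channel order R, G, B). Grayscale files are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @return numeric array \code{c(h, w, 3)} in \code{[0,1]}.
#' @export
readImageRGB <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] < 3L) {
    stop("expected a 1-, 3- or 4-channel image, got ", dim(img)[3], " channels")
  }
  clip01(aperm(img, c(2L, 1L, 3L)))
}

#' Write an RGB image
#'
#' @param img numeric array \code{c(h, w, 3)} in \code{[0,1]}; values are
#'   clipped before writing.
#' @param path output path; the extension selects the format (png/tiff/jpeg).
#' @return \code{path}, invisibly.
#' @export
writeImageRGB <- function(img, path) {
  assertRGB(img)
  x <- EBImage::Image(aperm(clip01(img), c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(x, path)
  invisible(path)
}

#' Read a binary nucleus mask
#'
#' Reads a mask image (foreground encoded as 255 or 1) and returns a
#' height x width matrix over \code{\{0,1\}} with 1 = nucleus.
#'
#' @param path file path.
#' @return integer-valued 0/1 matrix.
#' @export
readMask <- function(path) {
  m <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (t(m) >= 0.5) + 0
}

#' Write a binary mask as a \code{\{0,255\}} PNG
#'
#' @param mask 0/1 matrix, 1 = nucleus.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  assertMask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1.0)), path)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Luminance with ITU-R BT.601 weights: \code{0.299 R + 0.587 G + 0.114 B}.
#' This grayscale serves as the guidance image of the guided filter.
#'
#' @param img \code{c(h, w, 3)} array in \code{[0,1]}.
#' @return h x w matrix in \code{[0,1]}.
#' @examples
#' toGrayscale(array(c(1, 0, 0), dim = c(1, 1, 3)))  # 0.299
#' @export
toGrayscale <- function(img) {
  assertRGB(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  if (!is.matrix(g)) g <- matrix(g, dim(img)[1], dim(img)[2])
  g
}

#' Clip intensities to [0,1]
#'
#' @param x numeric array.
#' @return \code{x} with values clamped to \code{[0,1]}.
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

assertRGB <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB image as a height x width x 3 array")
  if (!all(is.finite(img)))
    stop("image contains non-finite values")
  invisible(img)
}

assertGray <- function(img) {
  if (!is.matrix(img))
    stop("expected a grayscale image as a height x width matrix")
  if (!all(is.finite(img)))
    stop("image contains non-finite values")
  invisible(img)
}

assertMask <- function(mask) {
  if (!is.matrix(mask))
    stop("expected a mask as a height x width matrix")
  if (!all(mask %in% c(0, 1)))
    stop("mask values must all be 0 or 1")
  invisible(mask)
}
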