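## Guided (directed) filtering. The output is a local linear transform of the
## guidance image: within each window w_k, p_i = a_k K_i + b_k with
##   a_k = (mean(K q) - mean(K) mean(q)) / (var(K) + epsilon)
##   b_k = mean(q) - a_k mean(K)
## and each pixel averages the coefficients of every window containing it:
##   p_i = abar_i K_i + bbar_i.
## All window statistics are running-sum box means, so the cost is O(N)
## regardless of the radius.

#' Box mean with count-normalized borders
#'
#' Mean of each pixel's \code{(2*radius+1)} square window, where border
#' windows are normalized by the number of in-bounds pixels (so constant
#' images are exact fixed points everywhere). Computed with running sums
#' (integral images): O(N) arithmetic independent of the radius.
#'
#' @param img numeric matrix.
#' @param radius integer window half-width, >= 1.
#' @return matrix of window means, same shape as \code{img}.
#' @examples
#' boxMean(matrix(c(0, 1, 0), 1), 1)  # 0.5, 1/3, 0.5
#' @export
boxMean <- function(img, radius) {
  assertGray(img)
  radius <- as.integer(radius)
  if (length(radius) != 1L || radius < 1L)
    stop("radius must be a single integer >= 1")
  boxSum(img, radius) / boxCounts(nrow(img), ncol(img), radius)
}

## running-sum window sums along rows then columns
boxSum <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  up <- pmin(seq_len(h) + radius, h)
  lo <- pmax(seq_len(h) - radius, 1L)
  cs <- rbind(0, apply(img, 2L, cumsum))
  rs <- cs[up + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  upc <- pmin(seq_len(w) + radius, w)
  loc <- pmax(seq_len(w) - radius, 1L)
  cs2 <- cbind(0, t(apply(rs, 1L, cumsum)))
  cs2[, upc + 1L, drop = FALSE] - cs2[, loc, drop = FALSE]
}

boxCounts <- function(h, w, radius) {
  rc <- pmin(seq_len(h) + radius, h) - pmax(seq_len(h) - radius, 1L) + 1L
  cc <- pmin(seq_len(w) + radius, w) - pmax(seq_len(w) - radius, 1L) + 1L
  outer(rc, cc)
}

#' Guided filter on a grayscale image
#'
#' Edge-preserving smoothing of \code{q} steered by the guidance image
#' \code{K}. With \code{K = q} and \code{epsilon = 0} the filter is the
#' identity (slope 1, offset 0 wherever the window variance is nonzero); as
#' \code{epsilon} grows far beyond the window variances it tends to a double
#' box mean. Windows with zero variance and \code{epsilon = 0} take the
#' limiting coefficients \code{a = 0}, \code{b = mean(q)}.
#'
#' @param q grayscale input image (matrix).
#' @param K guidance image, same shape as \code{q}.
#' @param params a \code{\link{DenoiseParams}}.
#' @param coefficients if \code{TRUE}, also return the per-window slopes
#'   \code{a}, offsets \code{b} and their box-averaged versions.
#' @return the filtered matrix, or (with \code{coefficients = TRUE}) a list
#'   with elements \code{output}, \code{a}, \code{b}, \code{meanA},
#'   \code{meanB}.
#' @examples
#' q <- matrix(runif(64), 8)
#' all.equal(guidedFilter(q, q, denoiseParams(radius = 2, epsilon = 0)), q)
#' @export
guidedFilter <- function(q, K, params = denoiseParams(),
                         coefficients = FALSE) {
  assertGray(q); assertGray(K)
  if (!identical(dim(q), dim(K)))
    stop("input and guidance images must have identical shapes")
  validObject(params)
  r <- params@radius; eps <- params@epsilon

  meanK <- boxMean(K, r)
  meanQ <- boxMean(q, r)
  corrK <- boxMean(K * K, r)
  corrKq <- boxMean(K * q, r)
  varK <- corrK - meanK * meanK
  covKq <- corrKq - meanK * meanQ

  den <- varK + eps
  a <- ifelse(den > 0, covKq / den, 0)   # a -> 0 as eps -> 0+ on flat windows
  b <- meanQ - a * meanK

  meanA <- boxMean(a, r)
  meanB <- boxMean(b, r)
  out <- meanA * K + meanB
  if (coefficients) {
    list(output = out, a = a, b = b, meanA = meanA, meanB = meanB)
  } else {
    out
  }
}

#' Guided filter on an RGB image
#'
#' Filters each channel independently with a shared guidance image, the
#' grayscale of the input itself; output is clipped to \code{[0,1]}.
#'
#' @param img \code{c(h, w, 3)} array in \code{[0,1]}.
#' @param params a \code{\link{DenoiseParams}}. If
#'   \code{params@bilateralEnabled}, the bilateral post-filter is applied
#'   after the guided filter.
#' @return denoised RGB array, same shape.
#' @export
guidedFilterRGB <- function(img, params = denoiseParams()) {
  assertRGB(img)
  guide <- toGrayscale(img)
  out <- img
  for (ch in 1:3)
    out[, , ch] <- guidedFilter(img[, , ch], guide, params)
  out <- clip01(out)
  if (params@bilateralEnabled) out <- bilateralPost(out, params)
  out
}

#' Bilateral post-filter
#'
#' Gaussian-weighted range/spatial bilateral smoothing applied per channel,
#' an optional second denoising stage after the guided filter. The window is
#' truncated at three spatial sigmas and weights are renormalized per pixel.
#'
#' @param img \code{c(h, w, 3)} array in \code{[0,1]}.
#' @param params a \code{\link{DenoiseParams}} supplying
#'   \code{bilateralSigmaSpatial} (pixels) and \code{bilateralSigmaRange}
#'   (intensity).
#' @return filtered RGB array.
#' @export
bilateralPost <- function(img, params = denoiseParams(bilateral = TRUE)) {
  assertRGB(img)
  ss <- params@bilateralSigmaSpatial
  sr <- params@bilateralSigmaRange
  if (ss <= 0 || sr <= 0) stop("bilateral sigmas must be positive")
  out <- img
  for (ch in 1:3)
    out[, , ch] <- bilateralGray(img[, , ch], ss, sr)
  out
}

bilateralGray <- function(x, sigmaSpatial, sigmaRange) {
  h <- nrow(x); w <- ncol(x)
  R <- max(1L, as.integer(ceiling(3 * sigmaSpatial)))
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  for (du in -R:R) {
    di <- max(1L, 1L - du):min(h, h - du)
    si <- di + du
    for (dv in -R:R) {
      sw <- exp(-(du^2 + dv^2) / (2 * sigmaSpatial^2))
      dj <- max(1L, 1L - dv):min(w, w - dv)
      sj <- dj + dv
      shifted <- x[si, sj, drop = FALSE]
      wgt <- sw * exp(-(x[di, dj, drop = FALSE] - shifted)^2 /
                        (2 * sigmaRange^2))
      num[di, dj] <- num[di, dj] + wgt * shifted
      den[di, dj] <- den[di, dj] + wgt
    }
  }
  num / den
}
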