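## Image-quality and segmentation metrics. PSNR follows the 8-bit
## convention (peak value 255); images held internally on [0,1] are mapped
## to the 8-bit scale before the squared error is taken.

#' Mean squared error between two images
#'
#' Mean of squared pixel differences over all \code{m*n} pixels, on the
#' scale of the inputs.
#'
#' @param i,k numeric matrices of identical shape.
#' @return scalar MSE.
#' @examples
#' mseImage(matrix(100), matrix(110))  # 100
#' @export
mseImage <- function(i, k) {
  if (!identical(dim(i), dim(k)))
    stop("images must have identical shapes")
  mean((i - k)^2)
}

eightBit <- function(x) if (max(x) <= 1) x * 255 else x

#' Grayscale peak signal-to-noise ratio
#'
#' \code{10 * log10(255^2 / MSE)} in dB, with peak value 255 (8-bit
#' convention). Inputs on \code{[0,1]} are rescaled to 8-bit first.
#' Identical images give \code{Inf}.
#'
#' @param i,k grayscale matrices of identical shape.
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnrGray <- function(i, k) {
  m <- mseImage(eightBit(i), eightBit(k))
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Color peak signal-to-noise ratio
#'
#' As \code{\link{psnrGray}} but the squared error is averaged over all
#' three channels (divisor \code{3*m*n}).
#'
#' @param i,k RGB arrays \code{c(h, w, 3)} of identical shape.
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnrColor <- function(i, k) {
  assertRGB(i); assertRGB(k)
  if (!identical(dim(i), dim(k)))
    stop("images must have identical shapes")
  m <- mean((eightBit(i) - eightBit(k))^2)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

#' Pixel confusion counts
#'
#' Tallies of true/false positives/negatives between a predicted and a
#' ground-truth binary nucleus mask (1 = nucleus).
#'
#' @param pred,truth 0/1 matrices of identical shape.
#' @return a \code{ConfusionCounts} object.
#' @examples
#' confusionCounts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
confusionCounts <- function(pred, truth) {
  assertMask(pred); assertMask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("masks must have identical shapes")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  newConfusion(tp, tn, fp, fn)
}

#' @rdname confusionCounts
#' @slot tp,tn,fp,fn non-negative pixel tallies.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) "counts must be non-negative" else TRUE
})

#' @param tp,tn,fp,fn non-negative counts.
#' @rdname confusionCounts
#' @export
newConfusion <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %g  TN %g  FP %g  FN %g\n",
              object@tp, object@tn, object@fp, object@fn))
})

#' Segmentation metrics from confusion counts
#'
#' Accuracy, precision, recall, IoU, Dice similarity coefficient and F1
#' from pixel confusion counts:
#' \code{Acc = (TP+TN)/total}, \code{Pre = TP/(TP+FP)},
#' \code{Re = TP/(TP+FN)}, \code{IoU = TP/(TP+FP+FN)},
#' \code{DSC = 2 TP/(2 TP+FP+FN)}, \code{F1 = 2 Pre Re/(Pre+Re)}.
#' On binary masks DSC and F1 coincide, and \code{DSC = 2 IoU/(1+IoU)}.
#' When both masks are empty (no foreground anywhere) the overlap metrics
#' are 1 by convention; any other 0/0 case yields 0.
#'
#' @param counts a \code{ConfusionCounts}.
#' @return named numeric vector with elements \code{accuracy},
#'   \code{precision}, \code{recall}, \code{iou}, \code{dsc}, \code{f1}.
#' @examples
#' segMetrics(newConfusion(1, 1, 1, 1))
#' @export
segMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  frac <- function(num, den, empty = 0) if (den > 0) num / den else empty
  bothEmpty <- (tp + fp + fn) == 0
  acc <- frac(tp + tn, total)
  pre <- frac(tp, tp + fp, empty = as.numeric(bothEmpty))
  rec <- frac(tp, tp + fn, empty = as.numeric(bothEmpty))
  iou <- frac(tp, tp + fp + fn, empty = 1)
  dsc <- frac(2 * tp, 2 * tp + fp + fn, empty = 1)
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else
    as.numeric(bothEmpty)
  c(accuracy = acc, precision = pre, recall = rec, iou = iou,
    dsc = dsc, f1 = f1)
}

#' Dice coefficient between two binary masks
#'
#' Convenience wrapper: \code{segMetrics(confusionCounts(pred, truth))["dsc"]}.
#'
#' @param pred,truth 0/1 matrices.
#' @return scalar Dice similarity coefficient.
#' @export
diceCoefficient <- function(pred, truth) {
  unname(segMetrics(confusionCounts(pred, truth))["dsc"])
}

#' Batch mask evaluation over directories
#'
#' Pairs predicted and ground-truth mask files by name and reports
#' per-image and mean segmentation metrics. Files present in only one
#' directory are skipped with a warning.
#'
#' @param predDir directory of predicted \code{\{0,255\}} mask PNGs.
#' @param truthDir directory of ground-truth masks.
#' @param outCsv optional path; the table is written there as CSV.
#' @return data.frame of per-image metrics plus a final \code{mean} row.
#' @export
evaluateMasks <- function(predDir, truthDir, outCsv = NULL) {
  pf <- list.files(predDir)
  tf <- list.files(truthDir)
  common <- intersect(pf, tf)
  if (length(common) == 0L)
    stop("no matching mask filenames between ", predDir, " and ", truthDir)
  odd <- c(setdiff(pf, tf), setdiff(tf, pf))
  if (length(odd))
    warning("skipping unmatched files: ", paste(odd, collapse = ", "))
  rows <- lapply(sort(common), function(f) {
    m <- segMetrics(confusionCounts(readMask(file.path(predDir, f)),
                                    readMask(file.path(truthDir, f))))
    data.frame(image = f, t(m))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(image = "mean",
                               t(colMeans(out[, -1, drop = FALSE]))))
  if (!is.null(outCsv)) utils::write.csv(out, outCsv, row.names = FALSE)
  out
}
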