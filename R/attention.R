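## The three attention operators as plain matrix functions, with tokens as
## rows (N x d). These are the mathematical cores used inside the network;
## the network additionally wraps them with projections, heads and
## residuals. Exposing them directly keeps the operator definitions
## independently checkable against brute-force evaluations.

#' Row-wise and column-wise softmax
#'
#' Numerically stable softmax of a matrix along rows or columns.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape whose rows (resp. columns) sum to 1.
#' @export
softmaxRows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' @rdname softmaxRows
#' @export
softmaxCols <- function(x) t(softmaxRows(t(x)))

#' L2-normalize matrix columns
#'
#' Divides each column by its Euclidean norm (columns with norm below
#' \code{1e-12} are left unscaled). In channel attention, each column of Q
#' and K is one channel's response over all tokens.
#'
#' @param x numeric matrix.
#' @return matrix with unit-norm columns.
#' @export
l2NormalizeCols <- function(x) {
  n <- sqrt(colSums(x^2))
  n[n < 1e-12] <- 1
  sweep(x, 2L, n, "/")
}

#' Efficient (linear-complexity) spatial attention
#'
#' \code{E(Q,K,V) = rho_q(Q) (rho_k(K)' V)} where \code{rho_q} is a softmax
#' over each query's channels (rows) and \code{rho_k} a softmax over each
#' key channel's tokens (columns). The inner product \code{rho_k(K)' V} is
#' formed first, a d_k x d_v global context, so no N x N attention map is
#' ever materialized and the cost is linear in the token count N.
#'
#' @param Q,K,V matrices with tokens as rows; \code{Q} is N x d_k,
#'   \code{K} is N x d_k, \code{V} is N x d_v.
#' @return N x d_v matrix of attended tokens.
#' @export
efficientAttention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  if (!all(is.finite(Q)) || !all(is.finite(K)) || !all(is.finite(V)))
    stop("attention inputs must be finite")
  softmaxRows(Q) %*% (t(softmaxCols(K)) %*% V)
}

#' Transposed (cross-covariance) channel attention
#'
#' \code{T(Q,K,V) = V CT} with \code{CT = softmax(K' Q / tau)} where Q and K
#' are first L2-normalized per channel column and the softmax runs over each
#' context column (the key-channel axis). The attention map is d_k x d_q —
#' channels attend to channels — so the cost is quadratic in the embedding
#' dimension but linear in the token count.
#'
#' @param Q,K,V matrices with tokens as rows, all N x d.
#' @param tau positive temperature.
#' @return N x d matrix of attended tokens.
#' @export
transposedAttention <- function(Q, K, V, tau = 1) {
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V))
  if (tau <= 0) stop("tau must be positive")
  Qn <- l2NormalizeCols(Q)
  Kn <- l2NormalizeCols(K)
  V %*% softmaxCols(crossprod(Kn, Qn) / tau)
}

#' Standard softmax dot-product attention (reference)
#'
#' \code{softmax(Q K' / sqrt(d) + B) V} with an optional additive bias B.
#' Quadratic in the token count; kept as the reference point the efficient
#' operator approximates in cost, and used only for analysis and testing —
#' the network never calls it.
#'
#' @param Q,K,V token matrices; \code{Q} N_q x d, \code{K}, \code{V} N x d.
#' @param B additive bias, scalar or N_q x N matrix (default 0).
#' @return N_q x d matrix.
#' @export
standardAttention <- function(Q, K, V, B = 0) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  softmaxRows(Q %*% t(K) / sqrt(ncol(Q)) + B) %*% V
}

#' Skip-connection cross-attention core
#'
#' The fusion operator of the skip path:
#' \code{E = rho_v(V) (rho_k(K)' Q)}, where K and V come from the decoder
#' stream and Q from the skipped encoder stage. \code{rho_v} and
#' \code{rho_k} are softmaxes over the token axis (columns), so the context
#' \code{rho_k(K)' Q} is d x d and the cost stays linear in N.
#'
#' @param Q,K,V matrices with tokens as rows, all N x d.
#' @return N x d matrix.
#' @export
scaAttention <- function(Q, K, V) {
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V), ncol(K) == ncol(Q))
  softmaxCols(V) %*% (t(softmaxCols(K)) %*% Q)
}
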