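## Network building blocks, written against the differentiation tape in
## autodiff.R. Parameters live in a forward "context": a named list of
## plain arrays (ctx$params) plus, per forward pass, one tape node per
## parameter (ctx$nodes). In init mode, parameters are materialized lazily
## the first time a layer asks for them, which keeps the parameter registry
## and the forward graph in sync by construction.

newCtx <- function(params = list(), init = FALSE, train = FALSE,
                   dropout = 0) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$nodes <- list()
  ctx$init <- init
  ctx$train <- train
  ctx$dropout <- dropout
  ctx
}

## Glorot-style fan-scaled truncated normal keeps the token scale stable
## through the non-residual projections (merging, expanding, skip fusion);
## a fixed small sd would shrink the signal geometrically with depth.
initArray <- function(dims, init, sd = 0.02, gain = 1) {
  n <- prod(dims)
  if (init == "xavier") {
    fan <- if (length(dims) == 2L) dims[1] + dims[2] else 2L * dims[1] * dims[2]
    sd <- gain * sqrt(2 / fan)
    init <- "tnorm"
  }
  v <- switch(init,
    tnorm = pmin(pmax(rnorm(n, 0, sd), -2 * sd), 2 * sd),
    zeros = rep(0, n),
    ones = rep(1, n),
    stop("unknown init: ", init))
  if (length(dims) > 1L) array(v, dim = dims) else v
}

nfParam <- function(ctx, name, dims, init = "tnorm", sd = 0.02, gain = 1) {
  if (is.null(ctx$params[[name]])) {
    if (!ctx$init)
      stop("unknown parameter '", name, "' outside init mode")
    ctx$params[[name]] <- initArray(dims, init, sd, gain)
  }
  nd <- ctx$nodes[[name]]
  if (is.null(nd)) {
    nd <- adNode(ctx$params[[name]])
    ctx$nodes[[name]] <- nd
  }
  nd
}

## crossprod node: t(a) %*% b
adCrossprod <- function(a, b) {
  av <- a$value; bv <- b$value
  adNode(crossprod(av, bv), list(a, b), function(g) {
    list(bv %*% t(g), av %*% g)
  })
}

## residual-branch output projections take gain < 1 so the residual stream
## keeps the embedding's scale at init (there is no norm on that stream)
nfLinear <- function(ctx, name, x, dIn, dOut, init = "xavier", gain = 1) {
  W <- nfParam(ctx, paste0(name, ".w"), c(dIn, dOut), init, gain = gain)
  b <- nfParam(ctx, paste0(name, ".b"), dOut, "zeros")
  adAddBias(adMatmul(x, W), b)
}

## one multi-head attention sub-layer (no norm, residual added by caller):
## projections Q,K,V, per-head operator, head concat, output projection
nfAttention <- function(ctx, name, x, heads, dim,
                        type = c("efficient", "transposed")) {
  type <- match.arg(type)
  q <- nfLinear(ctx, paste0(name, ".q"), x, dim, dim)
  k <- nfLinear(ctx, paste0(name, ".k"), x, dim, dim)
  v <- nfLinear(ctx, paste0(name, ".v"), x, dim, dim)
  hd <- dim %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * hd + 1L):(h * hd)
    Qh <- adCols(q, idx); Kh <- adCols(k, idx); Vh <- adCols(v, idx)
    if (type == "efficient") {
      ## rho_q(Q) (rho_k(K)' V): global context first, never N x N
      ctxmat <- adCrossprod(adSoftmaxCols(Kh), Vh)
      outs[[h]] <- adMatmul(adSoftmaxRows(Qh), ctxmat)
    } else {
      ## V softmax_cols(Kn' Qn / tau), channel-by-channel attention
      logtau <- nfParam(ctx, paste0(name, ".logtau", h), 1L, "zeros")
      invtau <- adExp(adScale(logtau, -1))
      Qn <- adL2NormCols(Qh); Kn <- adL2NormCols(Kh)
      ct <- adSoftmaxCols(adMulScalar(adCrossprod(Kn, Qn), invtau))
      outs[[h]] <- adMatmul(Vh, ct)
    }
  }
  cat_ <- if (heads == 1L) outs[[1L]] else adCbind(outs)
  out <- nfLinear(ctx, paste0(name, ".o"), cat_, dim, dim, gain = 0.35)
  if (ctx$train && ctx$dropout > 0) out <- adDropout(out, ctx$dropout)
  out
}

## Mix-FFN sub-layer with its LayerNorm, residual included:
## x + FC2(GELU(DWConv(FC1(LN(x)))))
nfMixFfn <- function(ctx, name, x, dim, hidden, h, w) {
  g <- nfParam(ctx, paste0(name, ".ln.g"), dim, "ones")
  b <- nfParam(ctx, paste0(name, ".ln.b"), dim, "zeros")
  y <- adLayerNorm(x, g, b)
  y <- nfLinear(ctx, paste0(name, ".fc1"), y, dim, hidden)
  wD <- nfParam(ctx, paste0(name, ".dw.w"), c(3L, 3L, hidden), "xavier")
  bD <- nfParam(ctx, paste0(name, ".dw.b"), hidden, "zeros")
  y <- adDwConv3(y, wD, bD, h, w)
  y <- adGelu(y)
  y <- nfLinear(ctx, paste0(name, ".fc2"), y, hidden, dim, gain = 0.35)
  if (ctx$train && ctx$dropout > 0) y <- adDropout(y, ctx$dropout)
  adAdd(x, y)
}

## the dual-attention block: spatial (efficient) attention, norm + Mix-FFN,
## channel (transposed) attention, norm + Mix-FFN, each with a residual
nfDualBlock <- function(ctx, name, x, heads, dim, h, w, expansion) {
  hidden <- as.integer(round(dim * expansion))
  x <- adAdd(x, nfAttention(ctx, paste0(name, ".ea"), x, heads, dim,
                            "efficient"))
  x <- nfMixFfn(ctx, paste0(name, ".ff1"), x, dim, hidden, h, w)
  x <- adAdd(x, nfAttention(ctx, paste0(name, ".ta"), x, heads, dim,
                            "transposed"))
  nfMixFfn(ctx, paste0(name, ".ff2"), x, dim, hidden, h, w)
}

## 2x2 token merge indices for an (h, w) grid in column-major token order
mergeIndices <- function(h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  i2 <- rep(seq_len(h2), times = w2)
  j2 <- rep(seq_len(w2), each = h2)
  f <- function(di, dj) (2L * i2 - 1L + di) + h * (2L * j2 - 2L + dj)
  list(f(0L, 0L), f(1L, 0L), f(0L, 1L), f(1L, 1L))
}

## 2x2 patch merging: concatenate each 2x2 neighborhood (4d) and project
## linearly to 2d; halves the grid, doubles the channels
nfPatchMerge <- function(ctx, name, x, h, w, dim) {
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("patch merging needs an even token grid, got ", h, " x ", w)
  idx <- mergeIndices(h, w)
  xcat <- adCbind(lapply(idx, function(i) adRowsGather(x, i)))
  nfLinear(ctx, name, xcat, 4L * dim, 2L * dim)
}

## patch expanding: linear d -> 2d then pixel shuffle to (2h, 2w, d/2)
nfPatchExpand <- function(ctx, name, x, h, w, dim) {
  if (dim %% 2L != 0L)
    stop("patch expanding needs an even channel count, got ", dim)
  y <- nfLinear(ctx, name, x, dim, 2L * dim)
  adPixelShuffle2(y, h, w)
}

## skip-connection attention fusion: decoder stream x1 gives keys/values,
## skipped encoder stage x2 gives queries; E = rho_v(V) (rho_k(K)' Q),
## returned with a residual connection to the projected decoder stream
nfScaFuse <- function(ctx, name, x1, x2, dim) {
  x1p <- nfLinear(ctx, paste0(name, ".fc"), x1, dim, dim)
  K <- nfLinear(ctx, paste0(name, ".k"), x1p, dim, dim)
  V <- nfLinear(ctx, paste0(name, ".v"), x1p, dim, dim)
  Q <- nfLinear(ctx, paste0(name, ".q"), x2, dim, dim)
  E <- adMatmul(adSoftmaxCols(V), adCrossprod(adSoftmaxCols(K), Q))
  adAdd(E, x1p)
}

## overlapping patch embedding: dense projection over k x k neighborhoods
## with stride s and zero padding p; the image enters as a constant
embedColumns <- function(img, k, s, p) {
  H <- dim(img)[1]; W <- dim(img)[2]; nc <- dim(img)[3]
  P <- array(0, dim = c(H + 2L * p, W + 2L * p, nc))
  P[p + seq_len(H), p + seq_len(W), ] <- img
  ho <- (H + 2L * p - k) %/% s + 1L
  wo <- (W + 2L * p - k) %/% s + 1L
  r0 <- (seq_len(ho) - 1L) * s
  c0 <- (seq_len(wo) - 1L) * s
  cols <- matrix(0, ho * wo, k * k * nc)
  cidx <- 0L
  for (ch in seq_len(nc)) for (v in seq_len(k)) for (u in seq_len(k)) {
    cidx <- cidx + 1L
    cols[, cidx] <- as.vector(P[r0 + u, c0 + v, ch])
  }
  list(cols = cols, h = ho, w = wo)
}

nfPatchEmbed <- function(ctx, img, spec) {
  k <- spec@patchKernel; s <- spec@patchStride; p <- spec@patchPad
  em <- embedColumns(img, k, s, p)
  C <- spec@baseDim
  x <- nfLinear(ctx, "embed.proj", adConst(em$cols),
                k * k * spec@inChannels, C)
  g <- nfParam(ctx, "embed.ln.g", C, "ones")
  b <- nfParam(ctx, "embed.ln.b", C, "zeros")
  list(x = adLayerNorm(x, g, b), h = em$h, w = em$w)
}
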