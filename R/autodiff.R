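## A minimal reverse-mode differentiation tape over numeric arrays. Nodes
## are environments holding a value, an accumulated gradient and a backward
## closure; forward calls append nodes to a global tape, and adBackward()
## sweeps it in reverse. Only what the network needs is implemented. All
## token tensors are N x d matrices (tokens as rows); grid-aware ops
## (depthwise conv, merging, shuffling) carry the (h, w) geometry
## explicitly, with tokens in column-major grid order.

.nfTape <- new.env(parent = emptyenv())
.nfTape$nodes <- NULL
.nfTape$n <- 0L
.nfTape$active <- FALSE

adBegin <- function(capacity = 8192L) {
  .nfTape$nodes <- vector("list", capacity)
  .nfTape$n <- 0L
  .nfTape$active <- TRUE
  invisible(NULL)
}

adEnd <- function() {
  .nfTape$nodes <- NULL
  .nfTape$n <- 0L
  .nfTape$active <- FALSE
  invisible(NULL)
}

adNode <- function(value, parents = NULL, back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (.nfTape$active && !is.null(back)) {
    nd$parents <- parents
    nd$back <- back
    n <- .nfTape$n + 1L
    if (n > length(.nfTape$nodes)) length(.nfTape$nodes) <- 2L * n
    .nfTape$nodes[[n]] <- nd
    .nfTape$n <- n
  }
  nd
}

adConst <- function(x) adNode(x)

## reverse sweep; afterwards every reachable node carries its gradient
adBackward <- function(loss) {
  loss$grad <- 1
  nodes <- .nfTape$nodes
  for (i in rev(seq_len(.nfTape$n))) {
    nd <- nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$back(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra primitives ----

adMatmul <- function(a, b) {
  av <- a$value; bv <- b$value
  adNode(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

adAdd <- function(a, b) {
  adNode(a$value + b$value, list(a, b), function(g) list(g, g))
}

adSub <- function(a, b) {
  adNode(a$value - b$value, list(a, b), function(g) list(g, -g))
}

adMul <- function(a, b) {
  av <- a$value; bv <- b$value
  adNode(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

adDiv <- function(a, b) {
  av <- a$value; bv <- b$value
  adNode(av / bv, list(a, b), function(g) list(g / bv, -g * av / bv^2))
}

adScale <- function(a, s) {  # s plain numeric constant
  adNode(a$value * s, list(a), function(g) list(g * s))
}

adAddConst <- function(a, s) {
  adNode(a$value + s, list(a), function(g) list(g))
}

## multiply every element of x by a length-1 node s
adMulScalar <- function(x, s) {
  xv <- x$value; sv <- s$value
  adNode(xv * sv, list(x, s), function(g) list(g * sv, sum(g * xv)))
}

adExp <- function(a) {
  v <- exp(a$value)
  adNode(v, list(a), function(g) list(g * v))
}

adAddBias <- function(x, b) {  # b is a length-d node added to every row
  xv <- x$value
  v <- xv + matrix(b$value, nrow(xv), ncol(xv), byrow = TRUE)
  adNode(v, list(x, b), function(g) list(g, colSums(g)))
}

adSum <- function(x) {
  d <- dim(x$value)
  adNode(sum(x$value), list(x), function(g) {
    gg <- array(g, dim = if (is.null(d)) length(x$value) else d)
    list(gg)
  })
}

## ---- nonlinearities ----

adGelu <- function(x) {  # exact GELU: x * pnorm(x)
  xv <- x$value
  ph <- pnorm(xv)
  adNode(xv * ph, list(x), function(g) list(g * (ph + xv * dnorm(xv))))
}

adSigmoid <- function(x) {
  v <- plogis(x$value)
  adNode(v, list(x), function(g) list(g * v * (1 - v)))
}

adSoftmaxRows <- function(x) {
  v <- softmaxRows(x$value)
  adNode(v, list(x), function(g) {
    list(v * (g - rowSums(g * v)))
  })
}

adSoftmaxCols <- function(x) {
  v <- softmaxCols(x$value)
  adNode(v, list(x), function(g) {
    list(v * sweep(g, 2L, colSums(g * v), "-"))
  })
}

adL2NormCols <- function(x) {
  xv <- x$value
  n <- sqrt(colSums(xv^2))
  n[n < 1e-12] <- 1
  v <- sweep(xv, 2L, n, "/")
  adNode(v, list(x), function(g) {
    d <- colSums(v * g)
    list(sweep(g - sweep(v, 2L, d, "*"), 2L, n, "/"))
  })
}

## LayerNorm over each row (token) with learnable gain/offset vectors
adLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xh <- xc / sd
  gv <- gamma$value
  v <- sweep(xh, 2L, gv, "*") + matrix(beta$value, nrow(xv), ncol(xv),
                                       byrow = TRUE)
  adNode(v, list(x, gamma, beta), function(g) {
    gxh <- sweep(g, 2L, gv, "*")
    gx <- (gxh - rowMeans(gxh) - xh * rowMeans(gxh * xh)) / sd
    list(gx, colSums(g * xh), colSums(g))
  })
}

## ---- grid-aware ops ----

## depthwise 3x3 convolution on tokens laid out as an (h, w) grid,
## zero-padded; w has dim c(3, 3, d), b length d
adDwConv3 <- function(x, wgt, bias, h, w) {
  xv <- x$value
  d <- ncol(xv)
  X <- array(xv, dim = c(h, w, d))
  wv <- wgt$value
  out <- array(rep(bias$value, each = h * w), dim = c(h, w, d))
  for (du in -1:1) {
    di <- max(1L, 1L - du):min(h, h - du); si <- di + du
    for (dv in -1:1) {
      dj <- max(1L, 1L - dv):min(w, w - dv); sj <- dj + dv
      kw <- rep(wv[du + 2L, dv + 2L, ], each = length(di) * length(dj))
      out[di, dj, ] <- out[di, dj, , drop = FALSE] +
        kw * X[si, sj, , drop = FALSE]
    }
  }
  adNode(matrix(out, h * w, d), list(x, wgt, bias), function(g) {
    G <- array(g, dim = c(h, w, d))
    gX <- array(0, dim = c(h, w, d))
    gW <- array(0, dim = c(3L, 3L, d))
    for (du in -1:1) {
      di <- max(1L, 1L - du):min(h, h - du); si <- di + du
      for (dv in -1:1) {
        dj <- max(1L, 1L - dv):min(w, w - dv); sj <- dj + dv
        kw <- rep(wv[du + 2L, dv + 2L, ], each = length(di) * length(dj))
        Gd <- G[di, dj, , drop = FALSE]
        gX[si, sj, ] <- gX[si, sj, , drop = FALSE] + kw * Gd
        gW[du + 2L, dv + 2L, ] <-
          colSums(matrix(Gd * X[si, sj, , drop = FALSE],
                         ncol = d))
      }
    }
    list(matrix(gX, h * w, d), gW, colSums(g))
  })
}

## select a block of columns (used for head splitting)
adCols <- function(x, idx) {
  xv <- x$value
  adNode(xv[, idx, drop = FALSE], list(x), function(g) {
    gg <- matrix(0, nrow(xv), ncol(xv))
    gg[, idx] <- g
    list(gg)
  })
}

adCbind <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  ncols <- vapply(vals, ncol, 0L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  adNode(do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

## gather rows by a (duplicate-free) index vector
adRowsGather <- function(x, idx) {
  xv <- x$value
  adNode(xv[idx, , drop = FALSE], list(x), function(g) {
    gg <- matrix(0, nrow(xv), ncol(xv))
    gg[idx, ] <- g
    list(gg)
  })
}

## pixel-shuffle upsampling: (h, w, D) tokens -> (2h, 2w, D/4); channel
## index decomposed as (c_out, subrow, subcol), c_out fastest
adPixelShuffle2 <- function(x, h, w) {
  xv <- x$value
  D <- ncol(xv)
  if (D %% 4L != 0L) stop("channel count must be divisible by 4")
  Do <- D %/% 4L
  A <- array(xv, dim = c(h, w, Do, 2L, 2L))
  v <- matrix(aperm(A, c(4L, 1L, 5L, 2L, 3L)), h * w * 4L, Do)
  adNode(v, list(x), function(g) {
    G <- array(g, dim = c(2L, h, 2L, w, Do))
    list(matrix(aperm(G, c(2L, 4L, 5L, 1L, 3L)), h * w, D))
  })
}

## binary cross-entropy from logits against a fixed 0/1 target vector
adBceLogits <- function(z, target) {
  zv <- z$value
  n <- length(zv)
  sp <- pmax(zv, 0) + log1p(exp(-abs(zv)))   # stable softplus
  adNode(sum(sp - target * zv) / n, list(z), function(g) {
    list(g * (plogis(zv) - target) / n)
  })
}

## foreground logit: difference of the two class score columns
adFgLogit <- function(scores) {
  sv <- scores$value
  stopifnot(ncol(sv) == 2L)
  adNode(sv[, 2L] - sv[, 1L], list(scores), function(g) {
    list(cbind(-g, g))
  })
}

## inverted dropout (train-time only); mask drawn from the current RNG
adDropout <- function(x, rate) {
  if (rate <= 0) return(x)
  xv <- x$value
  keep <- (matrix(runif(length(xv)), nrow(xv)) >= rate) / (1 - rate)
  adNode(xv * keep, list(x), function(g) list(g * keep))
}
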