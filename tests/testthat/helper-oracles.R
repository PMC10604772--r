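# Independent brute-force oracles: every operator under test is
# re-evaluated here with explicit per-window / per-element loops, kept
# deliberately free of the package's vectorized implementations.

bruteBoxMean <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    wi <- max(1, i - r):min(h, i + r)
    wj <- max(1, j - r):min(w, j + r)
    out[i, j] <- mean(x[wi, wj])
  }
  out
}

bruteGuidedFilter <- function(q, K, r, eps) {
  h <- nrow(q); w <- ncol(q)
  a <- matrix(0, h, w); b <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    wi <- max(1, i - r):min(h, i + r)
    wj <- max(1, j - r):min(w, j + r)
    Kw <- K[wi, wj]; qw <- q[wi, wj]
    mk <- mean(Kw); mq <- mean(qw)
    vk <- mean(Kw * Kw) - mk * mk
    cv <- mean(Kw * qw) - mk * mq
    a[i, j] <- if (vk + eps > 0) cv / (vk + eps) else 0
    b[i, j] <- mq - a[i, j] * mk
  }
  ma <- matrix(0, h, w); mb <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    wi <- max(1, i - r):min(h, i + r)
    wj <- max(1, j - r):min(w, j + r)
    ma[i, j] <- mean(a[wi, wj]); mb[i, j] <- mean(b[wi, wj])
  }
  ma * K + mb
}

loopSoftmaxRow <- function(v) { e <- exp(v - max(v)); e / sum(e) }

# efficient attention by explicit loops: out_i = rho_q(Q)_i %*% sum_j
# rho_k(K)_j' V_j with rho_k a per-channel softmax over tokens
loopEfficientAttention <- function(Q, K, V) {
  N <- nrow(Q); dk <- ncol(Q); dv <- ncol(V)
  Kn <- matrix(0, N, dk)
  for (c in seq_len(dk)) Kn[, c] <- loopSoftmaxRow(K[, c])
  ctxm <- matrix(0, dk, dv)
  for (a in seq_len(dk)) for (b in seq_len(dv))
    for (j in seq_len(N)) ctxm[a, b] <- ctxm[a, b] + Kn[j, a] * V[j, b]
  out <- matrix(0, N, dv)
  for (i in seq_len(N)) {
    qi <- loopSoftmaxRow(Q[i, ])
    for (b in seq_len(dv))
      out[i, b] <- sum(qi * ctxm[, b])
  }
  out
}

# transposed attention by explicit loops: columns of Q, K L2-normalized,
# CT = softmax over the key-channel axis of Kn' Qn / tau, out = V CT
loopTransposedAttention <- function(Q, K, V, tau = 1) {
  N <- nrow(Q); d <- ncol(Q)
  l2 <- function(M) {
    for (c in seq_len(ncol(M))) {
      nrm <- sqrt(sum(M[, c]^2))
      if (nrm >= 1e-12) M[, c] <- M[, c] / nrm
    }
    M
  }
  Qn <- l2(Q); Kn <- l2(K)
  S <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in seq_len(d))
    S[a, b] <- sum(Kn[, a] * Qn[, b]) / tau
  CT <- matrix(0, d, d)
  for (b in seq_len(d)) CT[, b] <- loopSoftmaxRow(S[, b])
  out <- matrix(0, N, d)
  for (i in seq_len(N)) for (b in seq_len(d))
    out[i, b] <- sum(V[i, ] * CT[, b])
  out
}

loopStandardAttention <- function(Q, K, V, B = 0) {
  Nq <- nrow(Q); N <- nrow(K); d <- ncol(Q)
  Bm <- if (is.matrix(B)) B else matrix(B, Nq, N)
  out <- matrix(0, Nq, ncol(V))
  for (i in seq_len(Nq)) {
    s <- numeric(N)
    for (j in seq_len(N)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d) + Bm[i, j]
    wgt <- loopSoftmaxRow(s)
    for (b in seq_len(ncol(V))) out[i, b] <- sum(wgt * V[, b])
  }
  out
}

# skip-fusion core by explicit loops: E = rho_v(V) (rho_k(K)' Q), both
# softmaxes over the token axis
loopScaAttention <- function(Q, K, V) {
  N <- nrow(Q); d <- ncol(Q)
  smCols <- function(M) { for (c in seq_len(ncol(M))) M[, c] <- loopSoftmaxRow(M[, c]); M }
  Kn <- smCols(K); Vn <- smCols(V)
  ctxm <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in seq_len(d))
    ctxm[a, b] <- sum(Kn[, a] * Q[, b])
  out <- matrix(0, N, d)
  for (i in seq_len(N)) for (b in seq_len(d))
    out[i, b] <- sum(Vn[i, ] * ctxm[, b])
  out
}

# a small synthetic tile spec used throughout the desk-scale tests
deskTileSpec <- function(seed = 42L) {
  syntheticSpec(tileSize = 64L, nNucleiRange = c(3L, 6L),
                axisRange = c(4, 8), seed = seed)
}

# Shared desk-scale training run (25 tiles at 64 px, C = 16, 30 epochs,
# seed 42), computed once per test session and reused by the pipeline and
# acceptance tests.
.fixtures <- new.env(parent = emptyenv())

trainedFixture <- function() {
  if (!is.null(.fixtures$fit)) return(.fixtures$fit)
  dir <- file.path(tempdir(), "nucformer-fixture")
  ds <- makeDataset(25, deskTileSpec(), dir)
  cfg <- trainConfig(epochs = 30L, patience = 30L, seed = 42L,
                     denoiseInputs = TRUE)
  fit <- trainModel(ds$train, ds$val, spec = tinyModelSpec(), cfg = cfg)
  fit$dataset <- ds
  fit$dataDir <- dir
  .fixtures$fit <- fit
  fit
}

overfitFixture <- function() {
  if (!is.null(.fixtures$overfit)) return(.fixtures$overfit)
  tile <- generateTile(deskTileSpec(seed = 7L))
  dir <- file.path(tempdir(), "nucformer-overfit")
  dir.create(file.path(dir, "img"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "msk"), recursive = TRUE, showWarnings = FALSE)
  writeImageRGB(tile$image, file.path(dir, "img", "t.png"))
  writeMask(tile$mask, file.path(dir, "msk", "t.png"))
  manifest <- data.frame(image = file.path(dir, "img", "t.png"),
                         mask = file.path(dir, "msk", "t.png"))
  cfg <- trainConfig(epochs = 200L, batchSize = 1L, patience = 200L,
                     seed = 42L, denoiseInputs = FALSE)
  fit <- trainModel(manifest, valManifest = NULL, spec = tinyModelSpec(),
                    cfg = cfg)
  fit$tile <- tile
  .fixtures$overfit <- fit
  fit
}
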