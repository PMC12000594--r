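# Primitive differentiable layers. Every *_fwd returns list(out, cache); the
# matching *_bwd consumes (cache, dout) and returns gradients. Array
# convention: token tensors are (N, S, F) with matrix views (N*S, F) obtained
# by dim<- (column-major, trial index fastest); conv feature maps are kept in
# the shapes noted per function. All math is double precision.

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x, y) ifelse(x > 0, 1, y + 1)

# ---- temporal convolution (1 x Kc, length-preserving zero padding) ----------
# X: (N, C, T) -> H: array (N, C, T, F1). Weight Wt: (F1, Kc), no bias.
tconv_fwd <- function(X, Wt) {
  d <- dim(X); N <- d[1L]; C <- d[2L]; T <- d[3L]
  Kc <- ncol(Wt); F1 <- nrow(Wt)
  pl <- (Kc - 1L) %/% 2L
  Xm <- X; dim(Xm) <- c(N * C, T)
  Xpad <- matrix(0, N * C, T + Kc - 1L)
  Xpad[, pl + seq_len(T)] <- Xm
  idx <- outer(seq_len(T), seq_len(Kc) - 1L, `+`)   # (T, Kc) into padded axis
  Xcol <- Xpad[, as.vector(idx)]
  dim(Xcol) <- c(N * C * T, Kc)
  H <- Xcol %*% t(Wt)                               # (N*C*T, F1)
  dim(H) <- c(N, C, T, F1)
  list(out = H, cache = list(Xcol = Xcol, Wt = Wt, dims = d, Kc = Kc, pl = pl))
}

tconv_bwd <- function(cache, dH) {
  d <- cache$dims; N <- d[1L]; C <- d[2L]; T <- d[3L]
  Kc <- cache$Kc; pl <- cache$pl
  F1 <- dim(dH)[4L]
  dHm <- dH; dim(dHm) <- c(N * C * T, F1)
  dWt <- t(dHm) %*% cache$Xcol
  dXcol <- dHm %*% cache$Wt                         # (N*C*T, Kc)
  dim(dXcol) <- c(N * C, T, Kc)
  dXpad <- matrix(0, N * C, T + Kc - 1L)
  for (k in seq_len(Kc))
    dXpad[, (k - 1L) + seq_len(T)] <-
      dXpad[, (k - 1L) + seq_len(T)] + dXcol[, , k]
  dX <- dXpad[, pl + seq_len(T), drop = FALSE]
  dim(dX) <- c(N, C, T)
  list(dX = dX, dWt = dWt)
}

# ---- spatial depthwise convolution (C x 1, depth multiplier 1, no bias) -----
# H: (N, C, T, F1), Ws: (F1, C) -> out matrix (N*T, F1), rows (n, t).
sconv_fwd <- function(H, Ws) {
  d <- dim(H); N <- d[1L]; C <- d[2L]; T <- d[3L]; F1 <- d[4L]
  A <- aperm(H, c(1L, 3L, 4L, 2L))                  # (N, T, F1, C)
  dim(A) <- c(N * T, F1, C)
  out <- matrix(0, N * T, F1)
  for (f in seq_len(F1))
    out[, f] <- A[, f, , drop = TRUE] %*% Ws[f, ]
  list(out = out, cache = list(A = A, Ws = Ws, dims = d))
}

sconv_bwd <- function(cache, dout) {
  d <- cache$dims; N <- d[1L]; C <- d[2L]; T <- d[3L]; F1 <- d[4L]
  dWs <- matrix(0, F1, C)
  dA <- array(0, c(N * T, F1, C))
  for (f in seq_len(F1)) {
    Af <- cache$A[, f, , drop = TRUE]
    if (is.null(dim(Af))) Af <- matrix(Af, nrow = N * T)
    dWs[f, ] <- crossprod(Af, dout[, f])
    dA[, f, ] <- outer(dout[, f], cache$Ws[f, ])
  }
  dim(dA) <- c(N, T, F1, C)
  dH <- aperm(dA, c(1L, 4L, 2L, 3L))                # back to (N, C, T, F1)
  list(dH = dH, dWs = dWs)
}

# ---- batch normalization over (N*T) per feature map -------------------------
bn_fwd <- function(X, g, b, running, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc^2)
    n <- nrow(X)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var +
      momentum * v * n / max(n - 1L, 1L)
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(X, 2L, mu)
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, ivar, `*`)
  out <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(out = out, running = running,
       cache = list(xhat = xhat, ivar = ivar, g = g, train = train))
}

bn_bwd <- function(cache, dout) {
  xhat <- cache$xhat; ivar <- cache$ivar; g <- cache$g
  n <- nrow(dout)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2L, g, `*`)
  if (cache$train) {
    dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
                  sweep(xhat, 2L, colMeans(dxhat * xhat), `*`),
                2L, ivar, `*`)
  } else {
    dX <- sweep(dxhat, 2L, ivar, `*`)
  }
  list(dX = dX, dg = dg, db = db)
}

# ---- average pooling along time, kernel = stride = P, ceil mode -------------
# X: (N, T, F) -> (N, Tp, F); trailing short window averages its own length
# (count excludes padding).
avgpool_fwd <- function(X, P) {
  d <- dim(X); N <- d[1L]; T <- d[2L]; F <- d[3L]
  Tp <- as.integer(ceiling(T / P))
  out <- array(0, c(N, Tp, F))
  lens <- integer(Tp)
  for (s in seq_len(Tp)) {
    rng <- ((s - 1L) * P + 1L):min(s * P, T)
    lens[s] <- length(rng)
    out[, s, ] <- apply(X[, rng, , drop = FALSE], c(1L, 3L), mean)
  }
  list(out = out, cache = list(dims = d, P = P, Tp = Tp, lens = lens))
}

avgpool_bwd <- function(cache, dout) {
  d <- cache$dims
  dX <- array(0, d)
  for (s in seq_len(cache$Tp)) {
    rng <- ((s - 1L) * cache$P + 1L):min(s * cache$P, d[2L])
    contrib <- dout[, s, , drop = FALSE] / cache$lens[s]
    for (t in rng) dX[, t, ] <- dX[, t, ] + contrib[, 1L, ]
  }
  dX
}

# ---- inverted dropout -------------------------------------------------------
dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  mask <- array(stats::rbinom(length(X), 1L, 1 - p) / (1 - p), dim(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

# ---- layer normalization over the feature dimension -------------------------
# X: matrix (rows = tokens, cols = features).
ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * ivar
  out <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(out = out, cache = list(xhat = xhat, ivar = ivar, g = g))
}

ln_bwd <- function(cache, dout) {
  xhat <- cache$xhat; ivar <- cache$ivar; g <- cache$g
  Fdim <- ncol(dout)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2L, g, `*`)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * ivar
  list(dX = dX, dg = dg, db = db)
}

# ---- multi-head scaled dot-product attention --------------------------------
# X3: (N, S, F2); projections without bias terms. Returns the concatenated
# head outputs projected by Wo, plus per-(trial, head) caches for backward.
mha_fwd <- function(X3, Wq, Wk, Wv, Wo, heads) {
  d <- dim(X3); N <- d[1L]; S <- d[2L]; F2 <- d[3L]
  if (F2 %% heads != 0L)
    stop(sprintf("embed_dim %d not divisible by %d heads", F2, heads))
  dk <- F2 %/% heads
  Xm <- X3; dim(Xm) <- c(N * S, F2)
  Q <- Xm %*% Wq; K <- Xm %*% Wk; V <- Xm %*% Wv
  ctx <- matrix(0, N * S, F2)
  Acache <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- n + N * (seq_len(S) - 1L)
    Ah <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      Qn <- Q[rows, cols, drop = FALSE]
      Kn <- K[rows, cols, drop = FALSE]
      Vn <- V[rows, cols, drop = FALSE]
      A <- softmax_rows(Qn %*% t(Kn) / sqrt(dk))
      ctx[rows, cols] <- A %*% Vn
      Ah[[h]] <- A
    }
    Acache[[n]] <- Ah
  }
  out <- ctx %*% Wo
  list(out = out, cache = list(Xm = Xm, Q = Q, K = K, V = V, ctx = ctx,
                               A = Acache, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                               N = N, S = S, F2 = F2, heads = heads, dk = dk))
}

mha_bwd <- function(cache, dout) {
  N <- cache$N; S <- cache$S; F2 <- cache$F2
  heads <- cache$heads; dk <- cache$dk
  dWo <- crossprod(cache$ctx, dout)
  dctx <- dout %*% t(cache$Wo)
  dQ <- matrix(0, N * S, F2); dK <- dQ; dV <- dQ
  for (n in seq_len(N)) {
    rows <- n + N * (seq_len(S) - 1L)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      A <- cache$A[[n]][[h]]
      Vn <- cache$V[rows, cols, drop = FALSE]
      dctx_nh <- dctx[rows, cols, drop = FALSE]
      dA <- dctx_nh %*% t(Vn)
      dV[rows, cols] <- crossprod(A, dctx_nh)
      dS <- A * (dA - rowSums(dA * A))              # softmax jacobian
      Qn <- cache$Q[rows, cols, drop = FALSE]
      Kn <- cache$K[rows, cols, drop = FALSE]
      dQ[rows, cols] <- dS %*% Kn / sqrt(dk)
      dK[rows, cols] <- crossprod(dS, Qn) / sqrt(dk)
    }
  }
  dWq <- crossprod(cache$Xm, dQ)
  dWk <- crossprod(cache$Xm, dK)
  dWv <- crossprod(cache$Xm, dV)
  dXm <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  list(dX = dXm, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}
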