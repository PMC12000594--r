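#' Configuration of one convolution branch
#'
#' Each branch applies `f1` temporal filters of length `kc` (length-preserving
#' zero padding), a depthwise spatial filter over all channels (one spatial
#' filter per temporal map, depth multiplier 1, no bias), batch
#' normalization, ELU, average pooling of kernel and stride `pool`
#' (ceil mode: a trailing short window averages its own length), and dropout.
#'
#' @param f1 number of temporal filters.
#' @param kc temporal kernel length in samples.
#' @param pool average-pooling length `P` in samples.
#' @param dropout dropout probability after pooling.
#' @return A `conv_branch_config`.
#' @export
conv_branch_config <- function(f1 = 16L, kc = 85L, pool = 52L, dropout = 0.5) {
  if (kc < 1L || pool < 1L) stop("kc and pool must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(f1 = as.integer(f1), kc = as.integer(kc),
                 pool = as.integer(pool), dropout = dropout),
            class = "conv_branch_config")
}

#' Full MSCFormer architecture configuration
#'
#' Defaults reproduce the benchmark architecture: three branches with
#' temporal kernels 85/65/45 sharing `f1 = 16` filters and pooling `P = 52`,
#' an embedding width `F2 = 3 * f1 = 48`, a 5-layer post-norm Transformer
#' encoder with 8 heads and feed-forward width `4 * F2 = 192`, and a
#' class-token softmax classifier with dropout 0.25. The token count is
#' `Tp = ceiling(samples / pool)`. Projection matrices Q/K/V/O carry no bias
#' terms; the feed-forward linears do.
#'
#' @param channels input channel count `C` (22 for IV-2a, 3 for IV-2b).
#' @param samples trial length `T` in samples (1000 for both benchmarks).
#' @param n_classes number of classes `M`.
#' @param f1 temporal filters per branch (shared).
#' @param kernels integer vector of temporal kernel lengths, one per branch.
#' @param pool shared average-pooling length `P`.
#' @param depth encoder depth `L`.
#' @param heads attention heads `h`; must divide `embed_dim`.
#' @param ff_dim feed-forward hidden width (default `4 * embed_dim`).
#' @param conv_dropout,encoder_dropout,classifier_dropout dropout rates.
#' @param bn_momentum,bn_eps,ln_eps normalization constants.
#' @return A `network_config`; `embed_dim` is always `3 * f1` and `head_dim`
#'   is `embed_dim / heads`.
#' @export
network_config <- function(channels, samples, n_classes,
                           f1 = 16L, kernels = c(85L, 65L, 45L), pool = 52L,
                           depth = 5L, heads = 8L, ff_dim = NULL,
                           conv_dropout = 0.5, encoder_dropout = 0.25,
                           classifier_dropout = 0.25,
                           bn_momentum = 0.1, bn_eps = 1e-5, ln_eps = 1e-5) {
  embed_dim <- length(kernels) * f1
  if (is.null(ff_dim)) ff_dim <- 4L * embed_dim
  if (embed_dim %% heads != 0L)
    stop(sprintf("embed_dim %d is not divisible by heads %d", embed_dim, heads))
  if (depth < 0L) stop("depth must be >= 0")
  cfg <- structure(list(
    channels = as.integer(channels), samples = as.integer(samples),
    n_classes = as.integer(n_classes), f1 = as.integer(f1),
    kernels = as.integer(kernels), pool = as.integer(pool),
    depth = as.integer(depth), heads = as.integer(heads),
    embed_dim = as.integer(embed_dim), ff_dim = as.integer(ff_dim),
    head_dim = as.integer(embed_dim %/% heads),
    conv_dropout = conv_dropout, encoder_dropout = encoder_dropout,
    classifier_dropout = classifier_dropout,
    bn_momentum = bn_momentum, bn_eps = bn_eps, ln_eps = ln_eps
  ), class = "network_config")
  cfg$n_tokens <- as.integer(ceiling(cfg$samples / cfg$pool))
  cfg
}

#' Number of tokens emitted by the convolution module
#' @param cfg a `network_config`.
#' @return `ceiling(samples / pool)`.
#' @export
token_length <- function(cfg) as.integer(ceiling(cfg$samples / cfg$pool))

# fan-in scaled uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
.init_mat <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Initialize an MSCFormer or MSNet model
#'
#' Conv and linear weights use fan-in-scaled uniform initialization; the
#' class token and positional table are drawn from N(0, 0.02); normalization
#' gains start at 1 and every bias at 0. Deterministic under `seed`.
#'
#' @param cfg a [network_config()].
#' @param variant `"mscformer"` (conv module + Transformer encoder +
#'   class-token classifier) or `"msnet"` (the ablation: conv module,
#'   flattened tokens, same classifier contract).
#' @param seed integer seed for the weight draw.
#' @return A `msc_model`: list with `cfg`, `variant`, `params` (named list of
#'   trainable arrays) and `state` (batch-norm running statistics).
#' @export
init_model <- function(cfg, variant = c("mscformer", "msnet"), seed = 1L) {
  variant <- match.arg(variant)
  p <- list()
  state <- list()
  with_local_seed(seed, {
    for (i in seq_along(cfg$kernels)) {
      kc <- cfg$kernels[i]
      p[[paste0("b", i, "_Wt")]] <- .init_mat(cfg$f1, kc, kc)
      p[[paste0("b", i, "_Ws")]] <- .init_mat(cfg$f1, cfg$channels, cfg$channels)
      p[[paste0("b", i, "_bn_g")]] <- rep(1, cfg$f1)
      p[[paste0("b", i, "_bn_b")]] <- rep(0, cfg$f1)
      state[[paste0("b", i, "_bn")]] <- list(mean = rep(0, cfg$f1),
                                             var = rep(1, cfg$f1))
    }
    F2 <- cfg$embed_dim
    Tp <- token_length(cfg)
    if (variant == "mscformer") {
      p$cls <- stats::rnorm(F2, 0, 0.02)
      p$pos <- matrix(stats::rnorm((Tp + 1L) * F2, 0, 0.02), Tp + 1L, F2)
      for (l in seq_len(cfg$depth)) {
        pre <- paste0("l", l, "_")
        p[[paste0(pre, "Wq")]] <- .init_mat(F2, F2, F2)
        p[[paste0(pre, "Wk")]] <- .init_mat(F2, F2, F2)
        p[[paste0(pre, "Wv")]] <- .init_mat(F2, F2, F2)
        p[[paste0(pre, "Wo")]] <- .init_mat(F2, F2, F2)
        p[[paste0(pre, "ln1_g")]] <- rep(1, F2)
        p[[paste0(pre, "ln1_b")]] <- rep(0, F2)
        p[[paste0(pre, "W1")]] <- .init_mat(F2, cfg$ff_dim, F2)
        p[[paste0(pre, "b1")]] <- rep(0, cfg$ff_dim)
        p[[paste0(pre, "W2")]] <- .init_mat(cfg$ff_dim, F2, cfg$ff_dim)
        p[[paste0(pre, "b2")]] <- rep(0, F2)
        p[[paste0(pre, "ln2_g")]] <- rep(1, F2)
        p[[paste0(pre, "ln2_b")]] <- rep(0, F2)
      }
      p$clf_W <- .init_mat(F2, cfg$n_classes, F2)
    } else {
      p$clf_W <- .init_mat(Tp * F2, cfg$n_classes, Tp * F2)
    }
    p$clf_b <- rep(0, cfg$n_classes)
  })
  structure(list(cfg = cfg, variant = variant, params = p, state = state),
            class = "msc_model")
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (conv kernels, batch-norm affine terms,
#' class token, positional table, attention, feed-forward and layer-norm
#' weights, classifier). Batch-norm running statistics are not trainable and
#' are excluded.
#'
#' @param cfg a [network_config()].
#' @param variant `"mscformer"` or `"msnet"`.
#' @param in_thousands report `count / 1000` rounded to one decimal.
#' @return integer count (or one-decimal value when `in_thousands`).
#' @export
count_parameters <- function(cfg, variant = c("mscformer", "msnet"),
                             in_thousands = FALSE) {
  variant <- match.arg(variant)
  m <- init_model(cfg, variant, seed = 1L)
  n <- sum(vapply(m$params, length, integer(1)))
  if (in_thousands) round(n / 1000, 1L) else as.integer(n)
}

# ---- convolution module -----------------------------------------------------
# X: (N, C, T) standardized input. Returns tokens (N, Tp, F2) and caches.
conv_module_fwd <- function(model, X, train) {
  cfg <- model$cfg
  d <- dim(X); N <- d[1L]
  Tp <- token_length(cfg)
  F2 <- cfg$embed_dim
  tokens <- array(0, c(N, Tp, F2))
  caches <- vector("list", length(cfg$kernels))
  state <- model$state
  for (i in seq_along(cfg$kernels)) {
    pre <- paste0("b", i, "_")
    tc <- tconv_fwd(X, model$params[[paste0(pre, "Wt")]])
    sc <- sconv_fwd(tc$out, model$params[[paste0(pre, "Ws")]])
    bn <- bn_fwd(sc$out, model$params[[paste0(pre, "bn_g")]],
                 model$params[[paste0(pre, "bn_b")]],
                 state[[paste0(pre, "bn")]], train,
                 momentum = cfg$bn_momentum, eps = cfg$bn_eps)
    state[[paste0(pre, "bn")]] <- bn$running
    act <- elu(bn$out)
    A3 <- act; dim(A3) <- c(N, cfg$samples, cfg$f1)   # rows were (n, t)
    pl <- avgpool_fwd(A3, cfg$pool)
    dr <- dropout_fwd(pl$out, cfg$conv_dropout, train)
    tokens[, , (i - 1L) * cfg$f1 + seq_len(cfg$f1)] <- dr$out
    caches[[i]] <- list(tc = tc$cache, sc = sc$cache, bn = bn$cache,
                        bn_in = bn$out, pre_act = sc$out, pool = pl$cache,
                        drop = dr$cache)
  }
  list(tokens = tokens, caches = caches, state = state)
}

conv_module_bwd <- function(model, caches, dtokens) {
  cfg <- model$cfg
  N <- dim(dtokens)[1L]
  grads <- list()
  dX <- NULL
  for (i in seq_along(cfg$kernels)) {
    pre <- paste0("b", i, "_")
    cc <- caches[[i]]
    dbr <- dtokens[, , (i - 1L) * cfg$f1 + seq_len(cfg$f1), drop = FALSE]
    dim(dbr) <- c(N, token_length(cfg), cfg$f1)
    dpool <- dropout_bwd(cc$drop, dbr)
    dact <- avgpool_bwd(cc$pool, dpool)              # (N, T, F1)
    dim(dact) <- c(N * cfg$samples, cfg$f1)
    # ELU grad needs pre-activation input = bn output's input... use bn out
    dbn_out <- dact * elu_grad(cc$bn_in, elu(cc$bn_in))
    bn <- bn_bwd(cc$bn, dbn_out)
    grads[[paste0(pre, "bn_g")]] <- bn$dg
    grads[[paste0(pre, "bn_b")]] <- bn$db
    sc <- sconv_bwd(cc$sc, bn$dX)
    grads[[paste0(pre, "Ws")]] <- sc$dWs
    tc <- tconv_bwd(cc$tc, sc$dH)
    grads[[paste0(pre, "Wt")]] <- tc$dWt
    dX <- if (is.null(dX)) tc$dX else dX + tc$dX
  }
  grads$dX <- dX
  grads
}

# ---- full forward -----------------------------------------------------------

#' Forward pass of MSCFormer or MSNet
#'
#' Runs the convolution module, (for MSCFormer) the class-token Transformer
#' encoder, and the softmax classifier. In `train` mode dropout is active,
#' batch-norm uses batch statistics and a cache for the backward pass is
#' returned; in eval mode the pass is deterministic.
#'
#' @param model a model from [init_model()].
#' @param X input array `(N, C, T)` of standardized trials, or a single
#'   `C x T` matrix.
#' @param train logical; training mode.
#' @return list with `probs` (`N x M`, rows sum to 1), `tokens`, and in train
#'   mode `cache` plus updated batch-norm `state`.
#' @export
model_forward <- function(model, X, train = FALSE) {
  cfg <- model$cfg
  if (is.matrix(X)) { dim(X) <- c(1L, dim(X)) }
  if (dim(X)[2L] != cfg$channels || dim(X)[3L] != cfg$samples)
    stop(sprintf("input geometry (%d, %d) does not match config (%d, %d)",
                 dim(X)[2L], dim(X)[3L], cfg$channels, cfg$samples))
  N <- dim(X)[1L]
  conv <- conv_module_fwd(model, X, train)
  p <- model$params
  if (model$variant == "msnet") {
    flat <- conv$tokens                              # flatten, token index fastest
    dim(flat) <- c(N, token_length(cfg) * cfg$embed_dim)
    dr <- dropout_fwd(flat, cfg$classifier_dropout, train)
    logits <- dr$out %*% p$clf_W + matrix(p$clf_b, N, cfg$n_classes, byrow = TRUE)
    probs <- softmax_rows(logits)
    return(list(probs = probs, tokens = conv$tokens, state = conv$state,
                cache = if (train) list(conv = conv$caches, flat = flat,
                                        drop = dr$cache, probs = probs) else NULL))
  }
  if (cfg$depth < 1L)
    stop("MSCFormer requires depth >= 1; use variant `msnet` for the encoder-free ablation")
  Tp <- token_length(cfg); S <- Tp + 1L; F2 <- cfg$embed_dim
  seq3 <- array(0, c(N, S, F2))
  seq3[, 1L, ] <- matrix(p$cls, N, F2, byrow = TRUE)
  seq3[, -1L, ] <- conv$tokens
  seq3 <- seq3 + rep(p$pos, each = N)                # learnable positions
  layer_caches <- vector("list", cfg$depth)
  x3 <- seq3
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("l", l, "_")
    mh <- mha_fwd(x3, p[[paste0(pre, "Wq")]], p[[paste0(pre, "Wk")]],
                  p[[paste0(pre, "Wv")]], p[[paste0(pre, "Wo")]], cfg$heads)
    dr1 <- dropout_fwd(mh$out, cfg$encoder_dropout, train)
    xm <- x3; dim(xm) <- c(N * S, F2)
    r1 <- xm + dr1$out
    ln1 <- ln_fwd(r1, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]],
                  eps = cfg$ln_eps)
    U <- ln1$out %*% p[[paste0(pre, "W1")]] +
      matrix(p[[paste0(pre, "b1")]], N * S, cfg$ff_dim, byrow = TRUE)
    G <- gelu(U)
    Z <- G %*% p[[paste0(pre, "W2")]] +
      matrix(p[[paste0(pre, "b2")]], N * S, F2, byrow = TRUE)
    dr2 <- dropout_fwd(Z, cfg$encoder_dropout, train)
    r2 <- ln1$out + dr2$out
    ln2 <- ln_fwd(r2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]],
                  eps = cfg$ln_eps)
    layer_caches[[l]] <- list(mha = mh$cache, dr1 = dr1$cache, ln1 = ln1$cache,
                              ln1_out = ln1$out, U = U, G = G,
                              dr2 = dr2$cache, ln2 = ln2$cache)
    x3 <- ln2$out; dim(x3) <- c(N, S, F2)
  }
  ct <- x3[, 1L, , drop = FALSE]
  dim(ct) <- c(N, F2)
  drc <- dropout_fwd(ct, cfg$classifier_dropout, train)
  logits <- drc$out %*% p$clf_W + matrix(p$clf_b, N, cfg$n_classes, byrow = TRUE)
  probs <- softmax_rows(logits)
  list(probs = probs, tokens = conv$tokens, state = conv$state,
       encoder_out = x3,
       cache = if (train) list(conv = conv$caches, layers = layer_caches,
                               ct = ct, drc = drc$cache, probs = probs,
                               N = N, S = S) else NULL)
}

#' Cross-entropy loss
#'
#' Mean over trials of the negative log predicted probability of the true
#' class.
#'
#' @param probs `N x M` matrix of class probabilities.
#' @param labels integer labels in `[0, M)`.
#' @return scalar loss.
#' @export
cross_entropy <- function(probs, labels) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), labels + 1L)
  -mean(log(pmax(probs[idx], 1e-300)))
}

# Full backward pass; returns gradient list keyed like model$params.
model_backward <- function(model, fwd, X, labels) {
  cfg <- model$cfg
  p <- model$params
  cache <- fwd$cache
  N <- nrow(fwd$probs)
  M <- cfg$n_classes
  onehot <- matrix(0, N, M); onehot[cbind(seq_len(N), labels + 1L)] <- 1
  dlogits <- (fwd$probs - onehot) / N
  grads <- list()
  grads$clf_b <- colSums(dlogits)
  if (model$variant == "msnet") {
    flat_d <- dropout_bwd(cache$drop, dlogits %*% t(p$clf_W))
    # recompute dropped flat for weight grad
    flat_kept <- if (is.null(cache$drop)) cache$flat else cache$flat * cache$drop
    grads$clf_W <- crossprod(flat_kept, dlogits)
    dtok <- flat_d
    dim(dtok) <- c(N, token_length(cfg), cfg$embed_dim)
    cg <- conv_module_bwd(model, cache$conv, dtok)
    cg$dX <- NULL
    return(c(grads, cg))
  }
  ct_kept <- if (is.null(cache$drc)) cache$ct else cache$ct * cache$drc
  grads$clf_W <- crossprod(ct_kept, dlogits)
  dct <- dropout_bwd(cache$drc, dlogits %*% t(p$clf_W))
  S <- cache$S; F2 <- cfg$embed_dim
  dx3 <- array(0, c(N, S, F2))
  dx3[, 1L, ] <- dct
  for (l in rev(seq_len(cfg$depth))) {
    pre <- paste0("l", l, "_")
    lc <- cache$layers[[l]]
    dout <- dx3; dim(dout) <- c(N * S, F2)
    l2 <- ln_bwd(lc$ln2, dout)
    grads[[paste0(pre, "ln2_g")]] <- l2$dg
    grads[[paste0(pre, "ln2_b")]] <- l2$db
    dr2in <- dropout_bwd(lc$dr2, l2$dX)              # grad into Z
    grads[[paste0(pre, "b2")]] <- colSums(dr2in)
    grads[[paste0(pre, "W2")]] <- crossprod(lc$G, dr2in)
    dG <- dr2in %*% t(p[[paste0(pre, "W2")]])
    dU <- dG * gelu_grad(lc$U)
    grads[[paste0(pre, "b1")]] <- colSums(dU)
    grads[[paste0(pre, "W1")]] <- crossprod(lc$ln1_out, dU)
    dln1_out <- dU %*% t(p[[paste0(pre, "W1")]]) + l2$dX  # FF path + residual
    l1 <- ln_bwd(lc$ln1, dln1_out)
    grads[[paste0(pre, "ln1_g")]] <- l1$dg
    grads[[paste0(pre, "ln1_b")]] <- l1$db
    dmha_out <- dropout_bwd(lc$dr1, l1$dX)
    mh <- mha_bwd(lc$mha, dmha_out)
    grads[[paste0(pre, "Wq")]] <- mh$dWq
    grads[[paste0(pre, "Wk")]] <- mh$dWk
    grads[[paste0(pre, "Wv")]] <- mh$dWv
    grads[[paste0(pre, "Wo")]] <- mh$dWo
    dxm <- mh$dX + l1$dX                             # attention path + residual
    dim(dxm) <- c(N, S, F2)
    dx3 <- dxm
  }
  grads$pos <- apply(dx3, c(2L, 3L), sum)
  dcls <- dx3[, 1L, , drop = FALSE]
  dim(dcls) <- c(N, F2)
  grads$cls <- colSums(dcls)
  dtok <- dx3[, -1L, , drop = FALSE]
  cg <- conv_module_bwd(model, cache$conv, dtok)
  cg$dX <- NULL
  c(grads, cg)
}

#' Class probabilities from the MSCFormer network
#'
#' Convenience wrapper around [model_forward()] returning only the softmax
#' probabilities (rows sum to 1; classification uses the class-token
#' embedding after the last encoder layer). Raises if the model was built as
#' the encoder-free ablation or with zero encoder depth - MSNet is a distinct
#' head, not depth 0.
#'
#' @param model a `msc_model` with variant `"mscformer"`.
#' @param x `C x T` matrix or `(N, C, T)` array of standardized trials.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @return `N x M` probability matrix.
#' @export
mscformer_forward <- function(model, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (model$variant != "mscformer")
    stop("model is not an MSCFormer; use msnet_forward() for the ablation")
  model_forward(model, x, train = mode == "train")$probs
}

#' Class probabilities from the MSNet ablation
#'
#' Identical convolution module; the fused tokens are flattened to a vector
#' of length `Tp * F2` and fed to the classifier directly (no Transformer).
#'
#' @inheritParams mscformer_forward
#' @param model a `msc_model` with variant `"msnet"`.
#' @return `N x M` probability matrix.
#' @export
msnet_forward <- function(model, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (model$variant != "msnet")
    stop("model is not an MSNet ablation")
  model_forward(model, x, train = mode == "train")$probs
}
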