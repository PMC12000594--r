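# Stand-alone views of the network's building blocks. These wrap the same
# internals the full model uses, so the contracts verified here (token-length
# law, attention normalization, post-norm residuals) hold inside the model.

#' Run a single convolution branch on one trial
#'
#' Temporal convolution (length-preserving padding), depthwise spatial
#' convolution, batch normalization, ELU, ceil-mode average pooling and
#' (train-mode only) dropout. With `params = NULL` a deterministic
#' weight set is drawn under `seed`; pass explicit weights to probe the
#' arithmetic.
#'
#' @param x `C x T` matrix.
#' @param cfg a [conv_branch_config()].
#' @param params optional list with `Wt` (`f1 x kc`), `Ws` (`f1 x C`),
#'   `bn_g`, `bn_b` (`f1`); batch norm runs in inference mode with running
#'   mean 0 / variance 1 unless `running` is supplied.
#' @param running optional list(mean, var) for batch norm.
#' @param train logical; enables dropout and batch statistics.
#' @param seed seed for the default weight draw.
#' @return `f1 x Tp` feature map, `Tp = ceiling(T / pool)`.
#' @export
conv_branch_forward <- function(x, cfg, params = NULL, running = NULL,
                                train = FALSE, seed = 1L) {
  stopifnot(is.matrix(x))
  C <- nrow(x); T <- ncol(x)
  if (is.null(params)) {
    params <- with_local_seed(seed, list(
      Wt = .init_mat(cfg$f1, cfg$kc, cfg$kc),
      Ws = .init_mat(cfg$f1, C, C),
      bn_g = rep(1, cfg$f1), bn_b = rep(0, cfg$f1)))
  }
  if (ncol(params$Ws) != C)
    stop(sprintf("spatial kernel expects %d channels, input has %d",
                 ncol(params$Ws), C))
  if (is.null(running)) running <- list(mean = rep(0, cfg$f1),
                                        var = rep(1, cfg$f1))
  X <- array(x, c(1L, C, T))
  tc <- tconv_fwd(X, params$Wt)
  sc <- sconv_fwd(tc$out, params$Ws)
  bn <- bn_fwd(sc$out, params$bn_g, params$bn_b, running, train)
  act <- elu(bn$out)
  dim(act) <- c(1L, T, cfg$f1)
  pl <- avgpool_fwd(act, cfg$pool)
  out <- dropout_fwd(pl$out, cfg$dropout, train)$out
  t(matrix(out, dim(out)[2L], dim(out)[3L]))        # (f1, Tp)
}

#' Fuse per-branch feature maps into the token sequence
#'
#' Transposes each `F1 x Tp` branch map and concatenates along the feature
#' dimension: token `t` is `[branch1[, t], branch2[, t], branch3[, t]]`,
#' giving a `Tp x F2` matrix with `F2 = sum of branch F1`.
#'
#' @param maps list of `F1 x Tp` matrices with identical `Tp`.
#' @return `Tp x F2` token matrix.
#' @export
fuse_branches <- function(maps) {
  tp <- unique(vapply(maps, ncol, integer(1)))
  if (length(tp) != 1L) stop("branch feature maps disagree in token count")
  do.call(cbind, lapply(maps, t))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`; every attention row is a probability
#' vector (sums to 1).
#'
#' @param Q,K,V `n x d_k` matrices.
#' @return list with `out` (`n x d_k`) and `weights` (`n x n`).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  dk <- ncol(Q)
  if (dk == 0L) stop("d_k must be positive")
  A <- softmax_rows(Q %*% t(K) / sqrt(dk))
  list(out = A %*% V, weights = A)
}

#' Multi-head attention block with post-norm residual
#'
#' `LN(MHA(x) + x)`: parallel scaled dot-product attention over `heads`
#' subspaces, concatenated and projected by `Wo` (projections carry no
#' biases), followed by the residual connection and layer normalization.
#'
#' @param x `S x F2` token matrix.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`F2 x F2`) and `ln_g`,
#'   `ln_b` (length `F2`).
#' @param heads head count; must divide `F2`.
#' @return `S x F2` matrix.
#' @export
mha_block <- function(x, params, heads) {
  S <- nrow(x); F2 <- ncol(x)
  X3 <- array(x, c(1L, S, F2))
  mh <- mha_fwd(X3, params$Wq, params$Wk, params$Wv, params$Wo, heads)
  ln_fwd(x + mh$out, params$ln_g, params$ln_b)$out
}

#' Feed-forward block with post-norm residual
#'
#' `LN(FFN(x) + x)` with `FFN(x) = GELU(x W1 + b1) W2 + b2`.
#'
#' @param x `S x F2` token matrix.
#' @param params list with `W1` (`F2 x ff`), `b1`, `W2` (`ff x F2`), `b2`,
#'   `ln_g`, `ln_b`.
#' @return `S x F2` matrix.
#' @export
feed_forward_block <- function(x, params) {
  S <- nrow(x)
  U <- x %*% params$W1 + matrix(params$b1, S, length(params$b1), byrow = TRUE)
  Z <- gelu(U) %*% params$W2 +
    matrix(params$b2, S, length(params$b2), byrow = TRUE)
  ln_fwd(x + Z, params$ln_g, params$ln_b)$out
}

#' Save / load a model checkpoint
#'
#' Single-file bundle of the architecture configuration, variant, trainable
#' parameters and batch-norm running statistics.
#'
#' @param model a `msc_model`.
#' @param path file path.
#' @return `path` (save) or the restored `msc_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "msc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "msc_model")) stop(sprintf("'%s' is not a model checkpoint", path))
  m
}
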