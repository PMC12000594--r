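test_that("network_config ties the derived dimensions together", {
  cfg <- network_config(22, 1000, 4)
  expect_equal(cfg$embed_dim, 3L * cfg$f1)
  expect_equal(cfg$head_dim, cfg$embed_dim %/% cfg$heads)
  expect_equal(token_length(cfg), as.integer(ceiling(1000 / cfg$pool)))
  expect_error(network_config(22, 1000, 4, heads = 7L), "divisible")
  cfg16 <- network_config(22, 1000, 4, f1 = 16L)
  expect_equal(cfg16$embed_dim, 48L)
})

test_that("convolution module obeys the token-length law ceil(T/P)", {
  x <- matrix(stats::rnorm(22 * 1000), 22, 1000)
  out12 <- conv_branch_forward(x, conv_branch_config(f1 = 4L, kc = 85L,
                                                     pool = 12L))
  expect_equal(ncol(out12), 84L)
  out72 <- conv_branch_forward(x, conv_branch_config(f1 = 4L, kc = 85L,
                                                     pool = 72L))
  expect_equal(ncol(out72), 14L)
  # non-divisible case keeps the short trailing window
  out <- conv_branch_forward(matrix(0, 2, 10), conv_branch_config(
    f1 = 2L, kc = 3L, pool = 4L))
  expect_equal(ncol(out), 3L)
})

test_that("zero input through an inference-mode branch stays zero", {
  x <- matrix(0, 3, 50)
  out <- conv_branch_forward(x, conv_branch_config(f1 = 4L, kc = 7L, pool = 10L))
  expect_true(all(out == 0))   # BN with zero bias, ELU(0) = 0
})

test_that("branch channel mismatch is rejected", {
  cfg <- conv_branch_config(f1 = 2L, kc = 5L, pool = 5L)
  params <- list(Wt = matrix(0, 2, 5), Ws = matrix(0, 2, 4),
                 bn_g = c(1, 1), bn_b = c(0, 0))
  expect_error(conv_branch_forward(matrix(0, 3, 20), cfg, params), "channels")
})

test_that("branch fusion concatenates features token-wise", {
  maps <- list(matrix(1, 2, 3), matrix(2, 2, 3), matrix(3, 2, 3))
  tok <- fuse_branches(maps)
  expect_equal(dim(tok), c(3L, 6L))
  for (t in 1:3) expect_equal(tok[t, ], c(1, 1, 2, 2, 3, 3))
  expect_equal(ncol(fuse_branches(list(matrix(0, 16, 5), matrix(0, 16, 5),
                                       matrix(0, 16, 5)))), 48L)
  expect_equal(nrow(fuse_branches(list(matrix(1, 2, 1), matrix(2, 2, 1),
                                       matrix(3, 2, 1)))), 1L)
  expect_error(fuse_branches(list(matrix(0, 2, 3), matrix(0, 2, 4))),
               "disagree")
})

test_that("scaled dot-product attention matches a dense oracle", {
  # singleton: weight exactly 1, output = V row
  r <- scaled_dot_attention(matrix(2, 1, 1), matrix(3, 1, 1), matrix(5, 1, 1))
  expect_equal(r$weights, matrix(1, 1, 1))
  expect_equal(r$out, matrix(5, 1, 1))
  # identical tokens: uniform weights, output = column means of V
  Q <- matrix(1, 4, 2); K <- Q
  V <- matrix(stats::rnorm(8), 4, 2)
  r <- scaled_dot_attention(Q, K, V)
  expect_equal(r$weights, matrix(0.25, 4, 4))
  expect_equal(r$out, matrix(colMeans(V), 4, 2, byrow = TRUE))
  # n=2, d_k=1 numeric case against an explicit softmax computation
  Q <- matrix(c(1, 0)); K <- matrix(c(1, 0)); V <- matrix(c(1, 0))
  r <- scaled_dot_attention(Q, K, V)
  w11 <- exp(1) / (exp(1) + exp(0))
  oracle <- matrix(c(w11 * 1 + (1 - w11) * 0, 0.5 * 1 + 0.5 * 0))
  expect_equal(r$out, oracle, tolerance = 1e-9)
  # rows always sum to one
  set.seed(8)
  r <- scaled_dot_attention(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3),
                            matrix(rnorm(12), 4, 3))
  expect_equal(rowSums(r$weights), rep(1, 4), tolerance = 1e-6)
})

test_that("attention rows sum to one in every layer of the full model", {
  cfg <- tiny_net_config()
  m <- init_model(cfg, seed = 2L)
  X <- array(stats::rnorm(2 * 3 * 40), c(2, 3, 40))
  fw <- model_forward(m, X, train = TRUE)
  for (lc in fw$cache$layers)
    for (trial_heads in lc$mha$A)
      for (A in trial_heads)
        expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
})

test_that("multi-head block is post-norm and reduces to single-head", {
  set.seed(3)
  F2 <- 6L; S <- 4L
  params <- list(Wq = matrix(rnorm(36), 6), Wk = matrix(rnorm(36), 6),
                 Wv = matrix(rnorm(36), 6), Wo = matrix(rnorm(36), 6),
                 ln_g = rep(1, 6), ln_b = rep(0, 6))
  x <- matrix(rnorm(S * F2), S, F2)
  out1 <- mha_block(x, params, heads = 1L)
  expect_equal(dim(out1), dim(x))
  # independent post-norm oracle for h = 1
  A <- exp((x %*% params$Wq) %*% t(x %*% params$Wk) / sqrt(6))
  A <- A / rowSums(A)
  mha <- (A %*% (x %*% params$Wv)) %*% params$Wo
  res <- x + mha
  oracle <- t(apply(res, 1, function(v) (v - mean(v)) /
                      sqrt(mean((v - mean(v))^2) + 1e-5)))
  expect_equal(out1, oracle, tolerance = 1e-9)
  expect_error(mha_block(x, params, heads = 4L), "divisible")
})

test_that("feed-forward block is LN(FFN(x) + x) with exact GELU", {
  set.seed(4)
  x <- matrix(rnorm(6), 1, 6)
  zero <- list(W1 = matrix(0, 6, 8), b1 = rep(0, 8),
               W2 = matrix(0, 8, 6), b2 = rep(0, 6),
               ln_g = rep(1, 6), ln_b = rep(0, 6))
  ln_only <- (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-5)
  expect_equal(feed_forward_block(x, zero), ln_only, tolerance = 1e-9)
  params <- list(W1 = matrix(rnorm(48), 6, 8), b1 = rnorm(8),
                 W2 = matrix(rnorm(48), 8, 6), b2 = rnorm(6),
                 ln_g = rep(1, 6), ln_b = rep(0, 6))
  u <- as.vector(x %*% params$W1) + params$b1
  g <- u * stats::pnorm(u)                      # hand-rolled exact GELU
  z <- as.vector(g %*% params$W2) + params$b2 + as.vector(x)
  oracle <- (z - mean(z)) / sqrt(mean((z - mean(z))^2) + 1e-5)
  expect_equal(as.vector(feed_forward_block(x, params)), oracle,
               tolerance = 1e-6)
  # shape preservation for any ff width
  expect_equal(dim(feed_forward_block(matrix(rnorm(12), 2, 6),
                                      list(W1 = matrix(rnorm(6), 6, 1),
                                           b1 = 0, W2 = matrix(rnorm(6), 1, 6),
                                           b2 = rep(0, 6), ln_g = rep(1, 6),
                                           ln_b = rep(0, 6)))),
               c(2L, 6L))
})

test_that("encoder block commutes with token permutation", {
  # with no positional information the attention + FF stack is equivariant
  set.seed(5)
  F2 <- 6L; S <- 5L
  mparams <- list(Wq = matrix(rnorm(36), 6), Wk = matrix(rnorm(36), 6),
                  Wv = matrix(rnorm(36), 6), Wo = matrix(rnorm(36), 6),
                  ln_g = runif(6, 0.5, 1.5), ln_b = rnorm(6))
  fparams <- list(W1 = matrix(rnorm(48), 6, 8), b1 = rnorm(8),
                  W2 = matrix(rnorm(48), 8, 6), b2 = rnorm(6),
                  ln_g = runif(6, 0.5, 1.5), ln_b = rnorm(6))
  x <- matrix(rnorm(S * F2), S, F2)
  enc <- function(z) feed_forward_block(mha_block(z, mparams, heads = 2L),
                                        fparams)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  expect_equal(enc(x[perm, ]), enc(x)[perm, ], tolerance = 1e-9)
})

test_that("softmax output is a distribution and eval mode is deterministic", {
  cfg <- tiny_net_config(dropout = 0.3)
  m <- init_model(cfg, seed = 11L)
  X <- array(stats::rnorm(3 * 3 * 40), c(3, 3, 40))
  p1 <- mscformer_forward(m, X)
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, mscformer_forward(m, X))      # bit-identical repeat
  cfg4 <- network_config(5, 60, 4, f1 = 2L, kernels = c(5L, 3L, 3L),
                         pool = 20L, depth = 1L, heads = 2L, ff_dim = 8L)
  p4 <- mscformer_forward(init_model(cfg4, seed = 1L),
                          matrix(stats::rnorm(300), 5, 60))
  expect_equal(ncol(p4), 4L)
})

test_that("MSNet flattens tokens and refuses the depth-0 MSCFormer", {
  cfg <- tiny_net_config()
  m <- init_model(cfg, "msnet", seed = 1L)
  X <- array(stats::rnorm(2 * 3 * 40), c(2, 3, 40))
  p <- msnet_forward(m, X)
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
  expect_equal(nrow(m$params$clf_W), token_length(cfg) * cfg$embed_dim)
  cfg0 <- network_config(3, 40, 2, f1 = 2L, kernels = c(5L, 3L, 3L),
                         pool = 10L, depth = 0L, heads = 2L, ff_dim = 8L)
  m0 <- init_model(cfg0, "mscformer", seed = 1L)
  expect_error(model_forward(m0, X), "depth >= 1")
  expect_error(msnet_forward(m, X[1, , ]), NA)
})

test_that("parameter counts match the closed-form sum on a toy config", {
  cfg <- network_config(2, 10, 2, f1 = 1L, kernels = 7L, pool = 5L,
                        depth = 0L, heads = 1L, ff_dim = 4L)
  # by hand: Wt 1x7, Ws 1x2, BN 2; msnet classifier (Tp*F2) x M + M with
  # Tp = 2, F2 = 1, M = 2
  expect_equal(count_parameters(cfg, "msnet"), 7L + 2L + 2L + 4L + 2L)
  # one encoder layer, closed form:
  cfg1 <- network_config(2, 10, 2, f1 = 1L, kernels = 7L, pool = 5L,
                         depth = 1L, heads = 1L, ff_dim = 4L)
  conv <- 7L + 2L + 2L
  enc <- 4L * 1L * 1L + 4L * 1L +            # Q/K/V/O weights + 2 LN affine
    (1L * 4L + 4L) + (4L * 1L + 1L)          # FF with biases
  tok <- 1L + (2L + 1L) * 1L                 # class token + positions
  clf <- 1L * 2L + 2L
  expect_equal(count_parameters(cfg1), conv + enc + tok + clf)
})

test_that("2a/2b parameter difference decomposes into its closed form", {
  cfg2a <- network_config(22, 1000, 4)
  cfg2b <- network_config(3, 1000, 2)
  d <- count_parameters(cfg2a) - count_parameters(cfg2b)
  # spatial kernels: 3 branches x f1 x (22 - 3); classifier: (4 - 2) rows of
  # F2 weights + biases; token table identical (same pooling)
  expect_equal(d, 3L * 16L * 19L + 2L * 48L + 2L)
})

test_that("a gradient step on one batch decreases the training loss", {
  cfg <- tiny_net_config()
  m <- init_model(cfg, seed = 4L)
  set.seed(10)
  X <- array(stats::rnorm(6 * 3 * 40), c(6, 3, 40))
  y <- rep(c(0L, 1L), 3L)
  fw <- model_forward(m, X, train = TRUE)
  loss0 <- cross_entropy(fw$probs, y)
  gr <- mscformer:::model_backward(m, fw, NULL, y)
  lr <- 1e-2
  for (nm in names(gr)) m$params[[nm]] <- m$params[[nm]] - lr * gr[[nm]]
  m$state <- fw$state
  loss1 <- cross_entropy(model_forward(m, X, train = TRUE)$probs, y)
  expect_lt(loss1, loss0)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_net_config()
  m <- init_model(cfg, seed = 7L)
  set.seed(42)
  X <- array(stats::rnorm(4 * 3 * 40), c(4, 3, 40))
  y <- c(0L, 1L, 0L, 1L)
  fw <- model_forward(m, X, train = TRUE)
  gr <- mscformer:::model_backward(m, fw, NULL, y)
  lossfn <- function(mm) cross_entropy(model_forward(mm, X, train = TRUE)$probs, y)
  set.seed(1)
  for (nm in c("b1_Wt", "b2_Ws", "b3_bn_g", "cls", "pos", "l1_Wq", "l1_Wo",
               "l2_W1", "l2_b2", "l1_ln1_g", "clf_W", "clf_b")) {
    for (i in sample(length(m$params[[nm]]), min(3L, length(m$params[[nm]])))) {
      h <- 1e-6
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      num <- (lossfn(mp) - lossfn(mm)) / (2 * h)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip the model", {
  cfg <- tiny_net_config()
  m <- init_model(cfg, seed = 3L)
  f <- withr::local_tempfile()
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  X <- matrix(stats::rnorm(120), 3, 40)
  expect_identical(mscformer_forward(m, X), mscformer_forward(m2, X))
})
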