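#' Training-protocol configuration
#'
#' Benchmark defaults: Adam with learning rate 0.001, beta1 = 0.5,
#' beta2 = 0.999, batch size 288, 1000 epochs, five folds; weight decay 0 for
#' the 22-channel task and 0.001 for the 3-channel task (L2 on weights only,
#' excluding normalization parameters and biases).
#'
#' @param lr learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size trials per optimization step; may exceed the pool size,
#'   in which case an epoch is a single full-pool batch.
#' @param epochs training epochs per fold.
#' @param weight_decay L2 coefficient on weight matrices.
#' @param seed base seed; fold f uses `seed + f`.
#' @param folds number of cross-validation folds (>= 2).
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.5, beta2 = 0.999,
                         batch_size = 288L, epochs = 1000L,
                         weight_decay = 0, seed = 1L, folds = 5L) {
  if (folds < 2L) stop("folds must be >= 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 seed = as.integer(seed), folds = as.integer(folds)),
            class = "train_config")
}

# parameters exempt from weight decay: biases, norm affine terms
.decay_exempt <- function(name)
  grepl("(_b$)|(_b1$)|(_b2$)|(bn_[gb]$)|(ln[12]_[gb]$)", name)

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

adam_step <- function(params, grads, opt, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (cfg$weight_decay > 0 && !.decay_exempt(nm))
      g <- g + cfg$weight_decay * params[[nm]]
    opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * g
    opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      cfg$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + 1e-8)
  }
  list(params = params, opt = opt)
}

#' Split a training set into five (train, validation) fold pairs
#'
#' Trials are shuffled once under `seed` and divided into `folds`
#' approximately equal subsets (sizes differ by at most one); each subset
#' serves as the validation set exactly once, the remaining subsets as the
#' training portion.
#'
#' @param train a `trialset` with at least `folds` trials.
#' @param seed shuffle seed.
#' @param folds number of folds.
#' @return list of `folds` lists with elements `train`, `val` (trialsets) and
#'   `val_idx` (original indices).
#' @export
split_five_fold <- function(train, seed = 1L, folds = 5L) {
  n <- n_trials(train)
  if (n < folds) stop(sprintf("need at least %d trials for %d folds", folds, folds))
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-folds] + 1L)
  lapply(seq_len(folds), function(f) {
    val_idx <- sort(perm[starts[f]:ends[f]])
    list(train = subset_trials(train, setdiff(seq_len(n), val_idx)),
         val = subset_trials(train, val_idx),
         val_idx = val_idx)
  })
}

.eval_split <- function(model, ts, stats, batch = 64L) {
  std <- apply_standardizer(stats, ts)
  n <- n_trials(ts)
  probs <- matrix(0, n, length(ts$class_names))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    fw <- model_forward(model, std$signals[i:j, , , drop = FALSE], train = FALSE)
    probs[i:j, ] <- fw$probs
    i <- j + 1L
  }
  probs
}

#' Train one cross-validation fold
#'
#' Standardization statistics are fitted on the (un-augmented) training
#' subset and applied unchanged to training, augmented, validation and test
#' trials. S&R augmentation draws donors from the training subset only; a
#' leakage guard rejects overlapping train/validation provenance. Each epoch
#' cycles once over the shuffled augmented-plus-original pool in batches;
#' after every epoch the validation loss is computed without augmentation,
#' and the parameters with the lowest validation loss (earlier epoch on ties)
#' are restored before the single test-set evaluation.
#'
#' @param train_subset,val_subset disjoint `trialset`s from [split_five_fold()].
#' @param test held-out test-session `trialset` (same geometry).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param aug_cfg an [augment_config()], or `NULL` to disable augmentation.
#' @param variant `"mscformer"` or `"msnet"`.
#' @param fold_index integer tag recorded in the result.
#' @param verbose print per-epoch losses.
#' @return A `fold_result`: `fold_index`, `best_epoch`, `best_val_loss`,
#'   `test_accuracy` (percent), `test_kappa`, `confusion`, `probabilities`,
#'   `train_loss` and `val_loss` traces, and the trained `model`.
#' @export
train_one_fold <- function(train_subset, val_subset, test, net_cfg, train_cfg,
                           aug_cfg = augment_config(), variant = "mscformer",
                           fold_index = 1L, verbose = FALSE) {
  if (length(intersect(setdiff(train_subset$trial_ids, 0L),
                       val_subset$trial_ids)) > 0L)
    stop("leakage guard: training and validation subsets share trials")
  stats <- fit_standardizer(train_subset, "global")
  pool <- train_subset
  if (!is.null(aug_cfg)) {
    aug <- segment_reconstruct(train_subset, aug_cfg)
    if (n_trials(aug) > 0L) pool <- concat_trialsets(train_subset, aug)
  }
  pool_std <- apply_standardizer(stats, pool)
  val_std <- apply_standardizer(stats, val_subset)
  model <- init_model(net_cfg, variant, seed = train_cfg$seed)
  opt <- adam_init(model$params)
  n_pool <- n_trials(pool_std)
  train_trace <- numeric(train_cfg$epochs)
  val_trace <- numeric(train_cfg$epochs)
  best <- list(loss = Inf, epoch = 0L, params = model$params,
               state = model$state)
  with_local_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      perm <- sample.int(n_pool)
      i <- 1L
      ep_loss <- 0; n_batches <- 0L
      while (i <= n_pool) {
        j <- min(i + train_cfg$batch_size - 1L, n_pool)
        idx <- perm[i:j]
        fw <- model_forward(model, pool_std$signals[idx, , , drop = FALSE],
                            train = TRUE)
        model$state <- fw$state
        loss <- cross_entropy(fw$probs, pool_std$labels[idx])
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d (diverged)", ep))
        grads <- model_backward(model, fw, NULL, pool_std$labels[idx])
        upd <- adam_step(model$params, grads, opt, train_cfg)
        model$params <- upd$params
        opt <- upd$opt
        ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
        i <- j + 1L
      }
      train_trace[ep] <- ep_loss / n_batches
      vfw <- model_forward(model, val_std$signals, train = FALSE)
      vloss <- cross_entropy(vfw$probs, val_std$labels)
      val_trace[ep] <- vloss
      if (vloss < best$loss) {            # strict: ties keep the earlier epoch
        best <- list(loss = vloss, epoch = ep, params = model$params,
                     state = model$state)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        train_trace[ep], vloss))
    }
  })
  model$params <- best$params
  model$state <- best$state
  probs <- .eval_split(model, test, stats)
  pred <- max.col(probs, ties.method = "first") - 1L   # lower index on ties
  cm <- confusion_matrix(test$labels, pred, length(test$class_names))
  structure(list(fold_index = fold_index, best_epoch = best$epoch,
                 best_val_loss = best$loss,
                 test_accuracy = accuracy(cm), test_kappa = kappa_score(cm),
                 confusion = cm, probabilities = probs,
                 train_loss = train_trace, val_loss = val_trace,
                 model = model, standardizer = stats),
            class = "fold_result")
}

#' Run the subject-specific five-fold protocol
#'
#' Splits the training session into five folds, trains each fold (training
#' portion plus S&R augmentation), selects each fold's best-validation-loss
#' checkpoint, evaluates every selected model once on the held-out test
#' session, and averages the per-fold test metrics.
#'
#' @param train,test training- and test-session `trialset`s (shared geometry).
#' @param net_cfg,train_cfg,aug_cfg configurations; `aug_cfg = NULL` disables
#'   augmentation.
#' @param variant `"mscformer"` or `"msnet"`.
#' @param verbose print progress.
#' @return An `eval_report`: per-fold results, `mean_accuracy` (percent),
#'   `sd_accuracy`, `mean_kappa`, `mean_confusion`, and pooled per-trial
#'   `probabilities` with `labels` for ROC analysis.
#' @export
run_subject <- function(train, test, net_cfg, train_cfg,
                        aug_cfg = augment_config(), variant = "mscformer",
                        verbose = FALSE) {
  if (!identical(dim(train$signals)[2:3], dim(test$signals)[2:3]) ||
      train$fs != test$fs ||
      length(train$class_names) != length(test$class_names))
    stop("train/test geometry mismatch (channels, samples, fs or classes)")
  folds <- split_five_fold(train, seed = train_cfg$seed, folds = train_cfg$folds)
  results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold_cfg <- train_cfg
    fold_cfg$seed <- train_cfg$seed + f
    if (!is.null(aug_cfg)) aug_cfg$seed <- fold_cfg$seed
    results[[f]] <- train_one_fold(folds[[f]]$train, folds[[f]]$val, test,
                                   net_cfg, fold_cfg, aug_cfg, variant,
                                   fold_index = f, verbose = verbose)
    if (verbose)
      message(sprintf("fold %d: acc %.2f%%  kappa %.4f  (best epoch %d)",
                      f, results[[f]]$test_accuracy, results[[f]]$test_kappa,
                      results[[f]]$best_epoch))
  }
  acc <- vapply(results, `[[`, 0, "test_accuracy")
  kap <- vapply(results, `[[`, 0, "test_kappa")
  cms <- lapply(results, `[[`, "confusion")
  mean_cm <- Reduce(`+`, cms) / length(cms)
  probs <- do.call(rbind, lapply(results, `[[`, "probabilities"))
  structure(list(folds = results, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), mean_kappa = mean(kap),
                 fold_accuracies = acc, fold_kappas = kap,
                 mean_confusion = mean_cm,
                 probabilities = probs,
                 labels = rep(test$labels, length(results))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("five-fold evaluation: accuracy %.2f%% (S.D. %.2f), kappa %.4f\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_kappa))
  cat("per-fold accuracy:", paste(sprintf("%.2f", x$fold_accuracies),
                                  collapse = " "), "\n")
  invisible(x)
}
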