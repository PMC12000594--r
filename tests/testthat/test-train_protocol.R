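test_that("five-fold split partitions 288 trials into 58/58/58/57/57", {
  ts <- rand_trialset(n = 288L, C = 1L, T = 4L, seed = 1L)
  folds <- split_five_fold(ts, seed = 3L)
  sizes <- sort(vapply(folds, function(f) n_trials(f$val), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(58L, 58L, 58L, 57L, 57L))
  # validation sets partition the index set
  all_idx <- sort(unlist(lapply(folds, `[[`, "val_idx")))
  expect_equal(all_idx, 1:288)
  for (f in folds)
    expect_length(intersect(f$train$trial_ids, f$val$trial_ids), 0L)
})

test_that("five trials give five singleton validation sets", {
  ts <- rand_trialset(n = 5L, C = 1L, T = 4L, seed = 2L)
  folds <- split_five_fold(ts, seed = 1L)
  expect_true(all(vapply(folds, function(f) n_trials(f$val), integer(1)) == 1L))
  expect_error(split_five_fold(rand_trialset(n = 4L, C = 1L, T = 4L)), "at least")
})

test_that("the split is deterministic under its seed", {
  ts <- rand_trialset(n = 37L, C = 1L, T = 4L, seed = 5L)
  a <- split_five_fold(ts, seed = 10L)
  b <- split_five_fold(ts, seed = 10L)
  expect_identical(lapply(a, `[[`, "val_idx"), lapply(b, `[[`, "val_idx"))
  c2 <- split_five_fold(ts, seed = 11L)
  expect_false(identical(lapply(a, `[[`, "val_idx"),
                         lapply(c2, `[[`, "val_idx")))
})

make_protocol_data <- function(effect = 2, seed = 5L, n_per_class = 10L) {
  sp <- synth_spec(n_trials_per_class = n_per_class, n_classes = 2L,
                   channels = 4L, samples = 250L, effect_size = effect,
                   noise_sigma = 0.5, seed = seed)
  train <- generate_trials(sp)
  sp$seed <- seed + 1000L
  test <- generate_trials(sp)
  list(train = train, test = test)
}

protocol_net <- function() network_config(4, 250, 2, f1 = 4L,
                                          kernels = c(25L, 17L, 9L),
                                          pool = 50L, depth = 1L, heads = 2L,
                                          ff_dim = 24L)

test_that("selected checkpoint attains the minimum logged validation loss", {
  dat <- make_protocol_data()
  folds <- split_five_fold(dat$train, seed = 1L)
  fr <- train_one_fold(folds[[1]]$train, folds[[1]]$val, dat$test,
                       protocol_net(), train_config(epochs = 8L,
                                                    batch_size = 16L,
                                                    seed = 2L),
                       augment_config(n_segments = 8L, seed = 2L))
  expect_equal(fr$best_val_loss, min(fr$val_loss))
  expect_equal(fr$best_epoch, which.min(fr$val_loss))  # earlier epoch on ties
  expect_true(all(is.finite(fr$train_loss)))
  expect_equal(sum(fr$confusion), n_trials(dat$test))
  expect_gte(fr$test_accuracy, 0); expect_lte(fr$test_accuracy, 100)
})

test_that("identical seeds reproduce a fold bit-for-bit", {
  dat <- make_protocol_data(seed = 9L)
  folds <- split_five_fold(dat$train, seed = 4L)
  args <- list(folds[[2]]$train, folds[[2]]$val, dat$test, protocol_net(),
               train_config(epochs = 3L, batch_size = 16L, seed = 7L),
               augment_config(n_segments = 4L, seed = 7L))
  a <- do.call(train_one_fold, args)
  b <- do.call(train_one_fold, args)
  expect_identical(a$probabilities, b$probabilities)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$val_loss, b$val_loss)
  expect_equal(a$test_accuracy, b$test_accuracy)
})

test_that("the leakage guard rejects overlapping train/validation subsets", {
  dat <- make_protocol_data()
  folds <- split_five_fold(dat$train, seed = 1L)
  overlapping <- subset_trials(dat$train, 1:10)   # shares ids with any fold
  expect_error(train_one_fold(dat$train, overlapping, dat$test,
                              protocol_net(),
                              train_config(epochs = 1L, seed = 1L)),
               "leakage")
})

test_that("run_subject aggregates five folds by arithmetic mean", {
  dat <- make_protocol_data(seed = 21L, n_per_class = 8L)
  rep5 <- run_subject(dat$train, dat$test, protocol_net(),
                      train_config(epochs = 2L, batch_size = 16L, seed = 3L),
                      augment_config(n_segments = 4L))
  expect_length(rep5$folds, 5L)
  expect_equal(rep5$mean_accuracy, mean(rep5$fold_accuracies))
  expect_equal(rep5$mean_kappa, mean(rep5$fold_kappas), tolerance = 1e-12)
  expect_equal(rep5$mean_confusion,
               Reduce(`+`, lapply(rep5$folds, `[[`, "confusion")) / 5)
  expect_equal(sum(rep5$mean_confusion), n_trials(dat$test))
  # geometry guard
  bad <- dat$test; bad$signals <- bad$signals[, 1:2, , drop = FALSE]
  bad$channel_names <- bad$channel_names[1:2]
  expect_error(run_subject(dat$train, bad, protocol_net(),
                           train_config(epochs = 1L)), "geometry")
})
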