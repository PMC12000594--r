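#' Configuration for segmentation-and-reconstruction augmentation
#'
#' S&R splits every training trial into `n_segments` contiguous time segments
#' and builds artificial trials by recombining same-position segments from
#' randomly drawn donor trials of one class, preserving the natural
#' progression of time (segment k only ever occupies slot k).
#'
#' @param n_segments number of time segments `N_s >= 1` (benchmark default 8).
#' @param n_augmented number of artificial trials `N_A >= 0` to generate;
#'   `NULL` (default) doubles the data, i.e. `N_A` = size of the training set.
#' @param class_conditional draw all donors of one artificial trial from a
#'   single class (default TRUE; cross-class mixing would be label-incoherent).
#' @param seed integer RNG seed for reproducible donor draws.
#' @return An `augment_config` object.
#' @export
augment_config <- function(n_segments = 8L, n_augmented = NULL,
                           class_conditional = TRUE, seed = 1L) {
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (!is.null(n_augmented) && n_augmented < 0L) stop("n_augmented must be >= 0")
  structure(list(n_segments = as.integer(n_segments),
                 n_augmented = if (is.null(n_augmented)) NULL else as.integer(n_augmented),
                 class_conditional = isTRUE(class_conditional),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Segment boundaries partitioning `[0, T)` into contiguous blocks
#'
#' Block sizes differ by at most one; the first `T mod n_segments` segments
#' receive the extra sample.
#'
#' @param T trial length in samples.
#' @param n_segments number of segments (must not exceed `T`).
#' @return integer matrix with columns `start`, `end` (1-based, inclusive).
#' @export
segment_boundaries <- function(T, n_segments) {
  if (n_segments > T) stop("n_segments exceeds trial length (empty segments)")
  base <- T %/% n_segments
  sizes <- rep(base, n_segments)
  extra <- T %% n_segments
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  cbind(start = c(1L, ends[-n_segments] + 1L), end = ends)
}

#' Segmentation-and-reconstruction (S&R) data augmentation
#'
#' Generates `n_augmented` artificial trials. For each artificial trial a
#' class is chosen (cycling over the classes present so the output is close
#' to balanced), then for each of the `n_segments` time slots a donor trial
#' of that class is drawn uniformly with replacement and its k-th segment is
#' copied into slot k. Output labels equal the donor class; augmented trials
#' carry `trial_ids = 0` to mark them as synthetic. Deterministic under
#' `cfg$seed`. Augmentation is meant for training folds only - never apply it
#' to validation or test data.
#'
#' @param train a non-empty `trialset` of training trials.
#' @param cfg an [augment_config()].
#' @return a `trialset` of artificial trials (possibly 0 rows).
#' @export
segment_reconstruct <- function(train, cfg) {
  stopifnot(inherits(cfg, "augment_config"))
  n <- n_trials(train)
  if (n == 0L) stop("cannot augment an empty trialset")
  d <- dim(train$signals)
  n_aug <- if (is.null(cfg$n_augmented)) n else cfg$n_augmented
  bounds <- segment_boundaries(d[3L], cfg$n_segments)
  classes <- sort(unique(train$labels))
  if (cfg$class_conditional) {
    m <- length(train$class_names)
    missing_cls <- setdiff(seq_len(m) - 1L, classes)
    if (length(missing_cls) > 0L)
      stop(sprintf("class(es) without trials under class-conditional S&R: %s",
                   paste(train$class_names[missing_cls + 1L], collapse = ", ")))
  }
  by_class <- lapply(classes, function(k) which(train$labels == k))
  names(by_class) <- as.character(classes)
  sig <- array(0, c(n_aug, d[2L], d[3L]))
  lab <- integer(n_aug)
  with_local_seed(cfg$seed, {
    for (i in seq_len(n_aug)) {
      if (cfg$class_conditional) {
        cls <- classes[((i - 1L) %% length(classes)) + 1L]
        pool <- by_class[[as.character(cls)]]
      } else {
        pool <- seq_len(n)
      }
      donors <- pool[sample.int(length(pool), cfg$n_segments, replace = TRUE)]
      if (!cfg$class_conditional) cls <- train$labels[donors[1L]]
      for (k in seq_len(cfg$n_segments)) {
        rng <- bounds[k, "start"]:bounds[k, "end"]
        sig[i, , rng] <- train$signals[donors[k], , rng]
      }
      lab[i] <- cls
    }
  })
  trialset(sig, lab, train$fs, train$channel_names, train$class_names,
           train$subject_id, paste0(train$session_tag, "+SR"),
           trial_ids = rep(0L, n_aug))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
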