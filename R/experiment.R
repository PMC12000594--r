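# Reproducible experiment runs: a single YAML configuration with three
# sections (data, model, train) drives import -> standardize -> augment ->
# train -> evaluate, and every run directory is self-describing (manifest +
# config snapshot + per-epoch loss logs + report).

.default_config <- function() list(
  data = list(
    source = "synthetic",          # synthetic | container | bci2a | bci2b
    train_path = NULL, test_path = NULL,
    label_path = NULL,
    t_start = 2, t_end = 6, channels_keep = NULL,
    synth = list(n_trials_per_class = 20L, n_classes = 2L, channels = 4L,
                 samples = 500L, fs = 250, rhythm_band = c(8, 12),
                 effect_size = 1, noise_sigma = 0.5)
  ),
  model = list(
    variant = "mscformer",
    f1 = 16L, kernels = c(85L, 65L, 45L), pool = 52L,
    depth = 5L, heads = 8L, ff_dim = NULL,
    conv_dropout = 0.5, encoder_dropout = 0.25, classifier_dropout = 0.25
  ),
  train = list(
    lr = 1e-3, beta1 = 0.5, beta2 = 0.999, batch_size = 288L,
    epochs = 1000L, weight_decay = 0, folds = 5L, seed = 1L,
    n_segments = 8L, n_augmented = NULL, augment = TRUE
  )
)

#' Default experiment configuration
#'
#' The full three-section (data/model/train) configuration with every
#' default; write it out, edit, and feed to [run_experiment()]. Unknown keys
#' in a user configuration are rejected.
#'
#' @param path optional file; when given the YAML is written there.
#' @return the configuration list, invisibly when written.
#' @export
default_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
    return(invisible(cfg))
  }
  cfg
}

.merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key `%s`", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key `%s` must be a section", full))
      defaults[[key]] <- .merge_config(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.load_experiment_data <- function(dc) {
  if (dc$source == "synthetic") {
    sp <- do.call(synth_spec, c(dc$synth, list(seed = 1L)))
    train <- generate_trials(sp)
    sp$seed <- 2L
    test <- generate_trials(sp)
    return(list(train = train, test = test))
  }
  if (dc$source == "container") {
    return(list(train = load_trialset(dc$train_path),
                test = load_trialset(dc$test_path)))
  }
  spec <- epoch_spec(dc$t_start, dc$t_end, dc$channels_keep)
  if (dc$source == "bci2a")
    return(list(train = load_bci_iv_2a(dc$train_path, spec = spec),
                test = load_bci_iv_2a(dc$test_path, dc$label_path, spec)))
  if (dc$source == "bci2b")
    return(list(train = load_bci_iv_2b(dc$train_path, spec = spec),
                test = load_bci_iv_2b(dc$test_path, dc$label_path, spec)))
  stop(sprintf("unknown data source `%s`", dc$source))
}

#' Run a configured experiment end to end
#'
#' Validates the configuration against the typed schema (unknown keys are
#' rejected with their path), loads or generates the data, runs the
#' five-fold protocol and writes a self-describing run directory: config
#' snapshot, manifest (seeds, dataset fingerprint, software version,
#' artifact paths), per-fold loss logs (CSV), per-fold checkpoints and the
#' evaluation report (JSON).
#'
#' @param config_path YAML configuration file, or a configuration list.
#' @param out_dir run directory to create.
#' @return list with `report` (an `eval_report`) and `manifest`.
#' @export
run_experiment <- function(config_path, out_dir = tempfile("mscrun")) {
  user <- if (is.character(config_path)) yaml::read_yaml(config_path)
          else config_path
  cfg <- .merge_config(user, .default_config())
  dat <- .load_experiment_data(cfg$data)
  mc <- cfg$model
  net_cfg <- network_config(
    channels = dim(dat$train$signals)[2L], samples = dim(dat$train$signals)[3L],
    n_classes = length(dat$train$class_names),
    f1 = mc$f1, kernels = unlist(mc$kernels), pool = mc$pool,
    depth = mc$depth, heads = mc$heads, ff_dim = mc$ff_dim,
    conv_dropout = mc$conv_dropout, encoder_dropout = mc$encoder_dropout,
    classifier_dropout = mc$classifier_dropout)
  tc <- cfg$train
  train_cfg <- train_config(lr = tc$lr, beta1 = tc$beta1, beta2 = tc$beta2,
                            batch_size = tc$batch_size, epochs = tc$epochs,
                            weight_decay = tc$weight_decay, seed = tc$seed,
                            folds = tc$folds)
  aug_cfg <- if (isTRUE(tc$augment))
    augment_config(n_segments = tc$n_segments, n_augmented = tc$n_augmented,
                   seed = tc$seed) else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- run_subject(dat$train, dat$test, net_cfg, train_cfg, aug_cfg,
                        variant = mc$variant)
  # artifacts
  fold_files <- character(length(report$folds))
  for (f in seq_along(report$folds)) {
    fr <- report$folds[[f]]
    loss_csv <- file.path(out_dir, sprintf("fold%d_loss.csv", f))
    utils::write.csv(data.frame(epoch = seq_along(fr$train_loss),
                                train_loss = fr$train_loss,
                                val_loss = fr$val_loss),
                     loss_csv, row.names = FALSE)
    ck <- file.path(out_dir, sprintf("fold%d_checkpoint.rds", f))
    save_checkpoint(fr$model, ck)
    fold_files[f] <- ck
  }
  fingerprint <- .trialset_fingerprint(dat$train)
  manifest <- list(
    config = cfg,
    seeds = list(base = tc$seed, folds = tc$seed + seq_len(tc$folds)),
    dataset_fingerprint = fingerprint,
    software_version = as.character(utils::packageVersion("mscformer")),
    fold_checkpoints = fold_files)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = report, manifest = manifest, out_dir = out_dir)
}

.trialset_fingerprint <- function(ts) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  save_trialset(ts, tmp)
  unname(tools::md5sum(tmp))
}

#' Serializable summary of an evaluation report
#'
#' @param report an `eval_report`.
#' @return plain list mirroring the per-subject result tables: per-fold and
#'   mean accuracy (percent), S.D., kappa, and the averaged confusion matrix.
#' @export
report_summary <- function(report) {
  list(mean_accuracy = report$mean_accuracy,
       sd_accuracy = report$sd_accuracy,
       mean_kappa = report$mean_kappa,
       fold_accuracies = report$fold_accuracies,
       fold_kappas = report$fold_kappas,
       best_epochs = vapply(report$folds, `[[`, 0L, "best_epoch"),
       mean_confusion = report$mean_confusion)
}

#' Export per-trial feature vectors at a pipeline stage
#'
#' For external embedding/plotting (e.g. t-SNE): `raw` flattens the input
#' trials, `conv` flattens the fused convolution tokens, `encoder_k` takes
#' the full token sequence after encoder layer `k`, and `final` the class
#' token after the last layer.
#'
#' @param model a trained `msc_model` (MSCFormer variant for encoder stages).
#' @param ts a `trialset` (standardize it first with the fold's statistics).
#' @param stage `"raw"`, `"conv"`, `"encoder_<k>"`, or `"final"`.
#' @return data.frame: `label` column plus one numeric column per feature.
#' @export
export_features <- function(model, ts, stage = "final") {
  n <- n_trials(ts)
  cfg <- model$cfg
  if (stage == "raw") {
    feats <- ts$signals
    dim(feats) <- c(n, cfg$channels * cfg$samples)
  } else if (stage == "conv") {
    fw <- model_forward(model, ts$signals, train = FALSE)
    feats <- fw$tokens
    dim(feats) <- c(n, token_length(cfg) * cfg$embed_dim)
  } else if (grepl("^encoder_[0-9]+$", stage)) {
    k <- as.integer(sub("encoder_", "", stage))
    if (k > cfg$depth)
      stop(sprintf("stage index %d exceeds encoder depth %d", k, cfg$depth))
    feats <- .encoder_stage(model, ts, k)
  } else if (stage == "final") {
    fw <- model_forward(model, ts$signals, train = FALSE)
    feats <- fw$encoder_out[, 1L, , drop = FALSE]
    dim(feats) <- c(n, cfg$embed_dim)
  } else stop(sprintf("unknown stage `%s`", stage))
  out <- as.data.frame(feats)
  names(out) <- sprintf("f%04d", seq_len(ncol(feats)))
  cbind(data.frame(label = ts$labels), out)
}

# forward truncated after encoder layer k; returns flattened sequences
.encoder_stage <- function(model, ts, k) {
  cfg <- model$cfg
  sub <- model
  sub$cfg$depth <- k
  # drop deeper layers' params so the forward stops at k
  keep <- suppressWarnings(
    !grepl("^l[0-9]+_", names(sub$params)) |
      as.integer(sub("^l([0-9]+)_.*$", "\\1", names(sub$params))) <= k)
  sub$params <- sub$params[keep]
  fw <- model_forward(sub, ts$signals, train = FALSE)
  enc <- fw$encoder_out
  n <- n_trials(ts)
  dim(enc) <- c(n, (token_length(cfg) + 1L) * cfg$embed_dim)
  enc
}
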