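# Trial extraction for the BCI Competition IV-2a and IV-2b benchmarks.
#
# Event codes used by the competition GDF files:
#   768        start of trial
#   769..772   cues: left hand, right hand, feet, tongue (2a); 769/770 (2b)
#   783        cue unknown (evaluation sessions)
#   1023       trial flagged as artifact-contaminated

.cue_codes <- c(769L, 770L, 771L, 772L, 783L)

#' Epoching window specification
#'
#' Defines the temporal segment cut from every trial, in seconds from trial
#' onset, and the channel subset to keep (EOG channels are excluded by
#' listing only EEG channels). The window is half-open in samples:
#' `[round(t_start * fs), round(t_start * fs) + (t_end - t_start) * fs)`.
#'
#' @param t_start,t_end window in seconds from trial onset; `t_end > t_start`.
#' @param channels_keep channel names to retain, in the desired output order.
#' @return An `epoch_spec` object.
#' @export
epoch_spec <- function(t_start, t_end, channels_keep) {
  if (t_end <= t_start)
    stop(sprintf("zero-length or negative epoch: t_start=%g, t_end=%g",
                 t_start, t_end))
  structure(list(t_start = t_start, t_end = t_end,
                 channels_keep = as.character(channels_keep)),
            class = "epoch_spec")
}

.epoch_recording <- function(rec, onsets, labels, spec, class_names,
                             subject_id = "", session_tag = "") {
  n_len <- (spec$t_end - spec$t_start) * rec$fs
  if (abs(n_len - round(n_len)) > 1e-9 || n_len <= 0)
    stop(sprintf("(t_end - t_start) * fs = %g is not a positive integer", n_len))
  n_len <- as.integer(round(n_len))
  missing_ch <- setdiff(spec$channels_keep, rec$channel_names)
  if (length(missing_ch) > 0L)
    stop(sprintf("unknown channel(s) %s; available: %s",
                 paste(missing_ch, collapse = ", "),
                 paste(rec$channel_names, collapse = ", ")))
  ch_idx <- match(spec$channels_keep, rec$channel_names)
  n <- length(onsets)
  if (length(labels) != n)
    stop(sprintf("label count mismatch: expected %d trials, found %d labels",
                 n, length(labels)))
  sig <- array(0, c(n, length(ch_idx), n_len))
  off <- as.integer(round(spec$t_start * rec$fs))
  for (i in seq_len(n)) {
    s0 <- onsets[i] + off          # onset is 1-based; off is a 0-based shift
    if (s0 + n_len - 1L > ncol(rec$signals))
      stop(sprintf("trial %d epoch [%d, %d) exceeds recording length %d",
                   i, s0, s0 + n_len, ncol(rec$signals)))
    sig[i, , ] <- rec$signals[ch_idx, s0:(s0 + n_len - 1L)]
  }
  trialset(sig, labels, rec$fs, spec$channels_keep, class_names,
           subject_id = subject_id, session_tag = session_tag)
}

.trial_onsets <- function(events) {
  on <- events$position[events$type == 768L]
  if (length(on) == 0L)  # fall back to cue events when no trial-start markers
    on <- events$position[events$type %in% .cue_codes]
  sort(on)
}

.labels_from_cues <- function(events, onsets) {
  cues <- events[events$type %in% .cue_codes, , drop = FALSE]
  cues <- cues[order(cues$position), , drop = FALSE]
  lab <- integer(length(onsets))
  for (i in seq_along(onsets)) {
    k <- which(cues$position >= onsets[i])
    if (length(k) == 0L) stop(sprintf("no cue event found for trial %d", i))
    code <- cues$type[k[1L]]
    if (code == 783L)
      stop("evaluation session with unknown cues: supply `label_path`")
    lab[i] <- code - 769L
  }
  lab
}

.read_label_file <- function(path, n_classes) {
  lab <- scan(path, what = numeric(), quiet = TRUE)
  lab <- as.integer(lab)
  if (any(lab < 1L) || any(lab > n_classes))
    stop(sprintf("label file '%s' contains classes outside 1..%d",
                 path, n_classes))
  lab - 1L   # competition labels are 1-based
}

#' Load a BCI Competition IV-2a session
#'
#' Reads one GDF session, locates the trial-start events, and cuts the epoch
#' defined by `spec` (the benchmark protocol uses 2-6 s at 250 Hz over the 22
#' EEG channels, giving per-trial matrices of shape (22, 1000)). The three EOG
#' channels are excluded by not listing them in `spec$channels_keep`. True
#' labels for the evaluation session (where cues carry the "unknown" code)
#' come from the competition's separate label file, passed explicitly.
#' Artifact-flagged trials are kept by default, matching the benchmark's 288
#' trials per session.
#'
#' @param session_path GDF file.
#' @param label_path optional plain-text numeric label file (classes 1..4);
#'   required for evaluation sessions.
#' @param spec an [epoch_spec()].
#' @param exclude_artifacts drop trials flagged with the artifact event code.
#' @return a `trialset` with 4 classes (left hand, right hand, feet, tongue).
#' @export
load_bci_iv_2a <- function(session_path, label_path = NULL, spec,
                           exclude_artifacts = FALSE) {
  rec <- read_gdf(session_path)
  onsets <- .trial_onsets(rec$events)
  class_names <- c("left_hand", "right_hand", "feet", "tongue")
  labels <- if (!is.null(label_path)) .read_label_file(label_path, 4L)
            else .labels_from_cues(rec$events, onsets)
  if (length(labels) != length(onsets))
    stop(sprintf("label count mismatch: expected %d trials, found %d labels",
                 length(onsets), length(labels)))
  keep <- rep(TRUE, length(onsets))
  if (exclude_artifacts) {
    bad <- rec$events$position[rec$events$type == 1023L]
    bounds <- c(onsets, ncol(rec$signals) + 1L)
    for (i in seq_along(onsets))
      if (any(bad >= onsets[i] & bad < bounds[i + 1L])) keep[i] <- FALSE
  }
  .epoch_recording(rec, onsets[keep], labels[keep], spec, class_names,
                   subject_id = tools::file_path_sans_ext(basename(session_path)),
                   session_tag = basename(session_path))
}

#' Load BCI Competition IV-2b sessions
#'
#' Reads one or more GDF sessions (the benchmark protocol concatenates
#' sessions 1-3 for training and 4-5 for testing), epochs each with `spec`
#' (3-7 s over the three bipolar channels, per-trial shape (3, 1000)) and
#' concatenates the trials in session order. All sessions must share one
#' sampling rate.
#'
#' @param session_paths character vector of GDF files, in session order.
#' @param label_paths optional character vector of label files (classes 1..2),
#'   parallel to `session_paths`; required for feedback-free evaluation
#'   sessions.
#' @param spec an [epoch_spec()].
#' @return a `trialset` with 2 classes (left hand, right hand).
#' @export
load_bci_iv_2b <- function(session_paths, label_paths = NULL, spec) {
  if (length(session_paths) == 0L) stop("empty session list")
  if (!is.null(label_paths) && length(label_paths) != length(session_paths))
    stop("label_paths must parallel session_paths")
  class_names <- c("left_hand", "right_hand")
  sets <- vector("list", length(session_paths))
  fs0 <- NULL
  for (i in seq_along(session_paths)) {
    rec <- read_gdf(session_paths[i])
    if (is.null(fs0)) fs0 <- rec$fs
    if (rec$fs != fs0)
      stop(sprintf("session '%s' has fs=%g, expected %g",
                   session_paths[i], rec$fs, fs0))
    onsets <- .trial_onsets(rec$events)
    labels <- if (!is.null(label_paths)) .read_label_file(label_paths[i], 2L)
              else .labels_from_cues(rec$events, onsets)
    sets[[i]] <- .epoch_recording(rec, onsets, labels, spec, class_names,
                                  session_tag = basename(session_paths[i]))
  }
  out <- concat_trialsets(sets)
  out$trial_ids <- seq_len(n_trials(out))
  out
}
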