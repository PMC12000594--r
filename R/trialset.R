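#' Epoched multi-channel EEG trials
#'
#' A `trialset` is the container every pipeline stage operates on: a 3-D
#' numeric array of `N` trials x `C` channels x `T` samples (microvolts),
#' integer class labels in `[0, M)`, the sampling rate and acquisition
#' metadata. Channel count and trial length are constant within one set.
#'
#' @param signals 3-D numeric array, `N x C x T`.
#' @param labels integer vector of length `N`, classes coded `0 .. M-1`.
#' @param fs sampling rate in Hz (`250` for both benchmark datasets).
#' @param channel_names character vector of length `C`.
#' @param class_names character vector of length `M`.
#' @param subject_id,session_tag free-form identification strings.
#' @param trial_ids optional integer provenance tags (one per trial); used by
#'   the training protocol to assert that augmentation and standardization
#'   never touch validation or test trials.
#' @return An object of class `trialset`.
#' @export
trialset <- function(signals, labels, fs, channel_names, class_names,
                     subject_id = "", session_tag = "", trial_ids = NULL) {
  if (length(dim(signals)) != 3L)
    stop("`signals` must be a 3-D array (trials x channels x samples)")
  storage.mode(signals) <- "double"
  labels <- as.integer(labels)
  if (is.null(trial_ids)) trial_ids <- seq_len(dim(signals)[1L])
  ts <- structure(list(
    signals = signals,
    labels = labels,
    fs = as.numeric(fs),
    channel_names = as.character(channel_names),
    class_names = as.character(class_names),
    subject_id = as.character(subject_id),
    session_tag = as.character(session_tag),
    trial_ids = as.integer(trial_ids)
  ), class = "trialset")
  validate_trialset(ts)
  ts
}

#' Validate the trialset invariants
#'
#' Checks the structural contract: label count matches trial count, every
#' label lies in `[0, M)`, channel names match the channel dimension and the
#' sampling rate is positive. Called by every constructor; exported so loaders
#' of external containers can re-assert the contract.
#'
#' @param ts a `trialset`.
#' @return `ts`, invisibly.
#' @export
validate_trialset <- function(ts) {
  d <- dim(ts$signals)
  if (d[1L] != length(ts$labels))
    stop(sprintf("label count (%d) does not match trial count (%d)",
                 length(ts$labels), d[1L]))
  m <- length(ts$class_names)
  if (d[1L] > 0L && (any(ts$labels < 0L) || any(ts$labels >= m)))
    stop(sprintf("labels must lie in [0, %d)", m))
  if (d[2L] != length(ts$channel_names))
    stop(sprintf("channel_names length (%d) does not match channel dim (%d)",
                 length(ts$channel_names), d[2L]))
  if (!is.finite(ts$fs) || ts$fs <= 0) stop("fs must be > 0")
  if (length(ts$trial_ids) != d[1L])
    stop("trial_ids length does not match trial count")
  invisible(ts)
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("trialset: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
  cat(sprintf("  trials/class: %s\n", paste(as.integer(tab), collapse = "/")))
  if (nzchar(x$subject_id))
    cat(sprintf("  subject: %s  session: %s\n", x$subject_id, x$session_tag))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$signals)

#' Number of trials in a trialset
#' @param ts a `trialset`.
#' @return integer trial count.
#' @export
n_trials <- function(ts) dim(ts$signals)[1L]

#' Subset a trialset by trial index
#'
#' @param ts a `trialset`.
#' @param idx integer trial indices (1-based).
#' @return a `trialset` with the selected trials, provenance tags preserved.
#' @export
subset_trials <- function(ts, idx) {
  trialset(ts$signals[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
           ts$channel_names, ts$class_names, ts$subject_id, ts$session_tag,
           trial_ids = ts$trial_ids[idx])
}

#' Concatenate trialsets along the trial dimension
#'
#' Geometry (channels, samples, sampling rate, class set) must agree; trials
#' keep their within-set order, sets are appended in argument order.
#'
#' @param ... `trialset` objects.
#' @return the concatenated `trialset`.
#' @export
concat_trialsets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "trialset"))
    sets <- sets[[1L]]
  if (length(sets) == 0L) stop("no trialsets to concatenate")
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (!identical(dim(s$signals)[2:3], dim(ref$signals)[2:3]))
      stop("trialsets differ in channel or sample dimension")
    if (s$fs != ref$fs) stop("trialsets differ in sampling rate")
    if (!identical(s$class_names, ref$class_names))
      stop("trialsets differ in class set")
  }
  n <- vapply(sets, n_trials, integer(1))
  d <- dim(ref$signals)
  sig <- array(0, c(sum(n), d[2L], d[3L]))
  off <- 0L
  for (s in sets) {
    if (n_trials(s) > 0L) sig[off + seq_len(n_trials(s)), , ] <- s$signals
    off <- off + n_trials(s)
  }
  trialset(sig, unlist(lapply(sets, `[[`, "labels")), ref$fs,
           ref$channel_names, ref$class_names, ref$subject_id,
           paste(unique(vapply(sets, `[[`, "", "session_tag")), collapse = "+"),
           trial_ids = unlist(lapply(sets, `[[`, "trial_ids")))
}

# --- portable single-file container ------------------------------------------
# Layout: magic line "MSCTRIAL1\n", 8-byte little-endian payload offset of the
# signal block, a JSON metadata record (dims, labels, fs, names, tags), then
# the raw signal array as little-endian float64 in R column-major order
# (trial index fastest). Doubles are written bit-exactly, so save -> load ->
# save is byte-identical.

.container_magic <- "MSCTRIAL1\n"

#' Save a trialset to the portable container format
#'
#' Single-file array bundle: a JSON metadata block followed by the raw
#' little-endian float64 signal array. The round trip is lossless (numeric
#' arrays bit-exact) and re-saving a loaded container reproduces the file
#' byte for byte.
#'
#' @param ts a `trialset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_trialset <- function(ts, path) {
  validate_trialset(ts)
  meta <- list(
    dims = dim(ts$signals),
    labels = ts$labels,
    fs = ts$fs,
    channel_names = ts$channel_names,
    class_names = ts$class_names,
    subject_id = ts$subject_id,
    session_tag = ts$session_tag,
    trial_ids = ts$trial_ids
  )
  hdr <- charToRaw(jsonlite::toJSON(meta, digits = NA, auto_unbox = FALSE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.container_magic), con)
  writeBin(length(hdr), con, size = 8L, endian = "little")
  writeBin(hdr, con)
  writeBin(as.vector(ts$signals), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a trialset from the portable container format
#'
#' @param path file written by [save_trialset()].
#' @return a `trialset`.
#' @export
load_trialset <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.container_magic)))
  if (!identical(magic, .container_magic))
    stop(sprintf("'%s' is not a trialset container (bad magic)", path))
  hlen <- readBin(con, "integer", 1L, size = 8L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                             simplifyVector = TRUE)
  for (f in c("dims", "labels", "fs", "channel_names", "class_names"))
    if (is.null(meta[[f]]))
      stop(sprintf("corrupt container: missing field `%s`", f))
  n <- prod(meta$dims)
  sig <- readBin(con, "double", n, size = 8L, endian = "little")
  if (length(sig) != n) stop("corrupt container: truncated signal block")
  trialset(array(sig, meta$dims), meta$labels, meta$fs, meta$channel_names,
           meta$class_names,
           subject_id = meta$subject_id %||% "",
           session_tag = meta$session_tag %||% "",
           trial_ids = meta$trial_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
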