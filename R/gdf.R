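# Minimal reader/writer for the GDF 2.x biosignal format (the distribution
# format of the BCI Competition IV recordings). Only the subset of the format
# needed for trial extraction is handled: the fixed 256-byte header (version,
# header length, record count, record duration, signal count), the
# field-blocked per-channel headers (label, physical/digital ranges, samples
# per record, data type) and the mode-1/mode-3 event table. Supported sample
# encodings: int16 (type 3), float32 (16), float64 (17). Everything else in
# the headers is preserved as opaque padding.

.gdf_dtype <- function(code) {
  switch(as.character(code),
         "3" = list(what = "integer", size = 2L, signed = TRUE),
         "16" = list(what = "double", size = 4L),
         "17" = list(what = "double", size = 8L),
         stop(sprintf("unsupported GDF sample type %s", code)))
}

#' Read a GDF 2.x recording (minimal subset)
#'
#' Parses continuous multi-channel signals and the event table from a GDF
#' file. All channels must share one sampling rate. Digital values are mapped
#' to physical units with the per-channel linear calibration.
#'
#' @param path GDF file path.
#' @return A list with `signals` (channels x samples matrix, physical units),
#'   `fs` (Hz), `channel_names`, and `events` (data.frame with 1-based sample
#'   `position`, integer `type`, and, for mode-3 tables, `channel` and
#'   `duration`).
#' @export
read_gdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop(sprintf("'%s': truncated GDF header", path))
  version <- rawToChar(hdr[1:8])
  if (!startsWith(version, "GDF"))
    stop(sprintf("'%s' is not a GDF file (version id '%s')", path, version))
  le <- function(raw, what, size, n = 1L, signed = TRUE)
    readBin(raw, what, n = n, size = size, endian = "little", signed = signed)
  hdr_blocks <- le(hdr[185:186], "integer", 2L, signed = FALSE)
  n_rec <- le(hdr[237:244], "integer", 8L)
  dur_num <- le(hdr[245:248], "integer", 4L)
  dur_den <- le(hdr[249:252], "integer", 4L)
  ns <- le(hdr[253:254], "integer", 2L, signed = FALSE)
  vh <- readBin(con, "raw", 256L * ns)
  fld <- function(off, width)  # field-blocked: all channels' copies adjacent
    lapply(seq_len(ns), function(i) vh[(off + (i - 1L) * width + 1L):(off + i * width)])
  labels <- vapply(fld(0L, 16L), function(r) trimws(rawToChar(r)), "")
  off_after_text <- ns * (16L + 80L + 6L) + ns * 2L  # label/transducer/physdim/physdimcode
  physmin <- readBin(vh[(off_after_text + 1L):(off_after_text + 8L * ns)],
                     "double", ns, endian = "little")
  physmax <- readBin(vh[(off_after_text + 8L * ns + 1L):(off_after_text + 16L * ns)],
                     "double", ns, endian = "little")
  digmin <- readBin(vh[(off_after_text + 16L * ns + 1L):(off_after_text + 24L * ns)],
                    "double", ns, endian = "little")
  digmax <- readBin(vh[(off_after_text + 24L * ns + 1L):(off_after_text + 32L * ns)],
                    "double", ns, endian = "little")
  off_pf <- off_after_text + 32L * ns + 68L * ns  # prefilter text + filter floats
  spr <- readBin(vh[(off_pf + 1L):(off_pf + 4L * ns)], "integer", ns,
                 size = 4L, endian = "little")
  dtyp <- readBin(vh[(off_pf + 4L * ns + 1L):(off_pf + 8L * ns)], "integer", ns,
                  size = 4L, endian = "little")
  rec_dur <- dur_num / dur_den
  fs <- spr / rec_dur
  if (length(unique(fs)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- fs[1L]
  # data records: channel-blocked within each record
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dt <- .gdf_dtype(dtyp[ch])
      x <- if (dt$what == "integer")
        readBin(con, "integer", spr[ch], size = dt$size, endian = "little",
                signed = TRUE)
      else readBin(con, "double", spr[ch], size = dt$size, endian = "little")
      scale <- (physmax[ch] - physmin[ch]) / (digmax[ch] - digmin[ch])
      sig[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        (x - digmin[ch]) * scale + physmin[ch]
    }
  }
  # event table (optional)
  events <- data.frame(position = integer(0), type = integer(0))
  et <- readBin(con, "raw", 8L)
  if (length(et) == 8L) {
    mode <- as.integer(et[1L])
    nev <- as.integer(et[2L]) + 256L * as.integer(et[3L]) + 65536L * as.integer(et[4L])
    pos <- readBin(con, "integer", nev, size = 4L, endian = "little")
    typ <- readBin(con, "integer", nev, size = 2L, endian = "little", signed = FALSE)
    events <- data.frame(position = pos, type = typ)
    if (mode == 3L) {
      events$channel <- readBin(con, "integer", nev, size = 2L,
                                endian = "little", signed = FALSE)
      events$duration <- readBin(con, "integer", nev, size = 4L, endian = "little")
    }
  }
  list(signals = sig, fs = fs, channel_names = labels, events = events)
}

#' Write a GDF 2.x recording (minimal subset)
#'
#' Counterpart of [read_gdf()], used to build synthetic GDF fixtures in tests
#' and examples; it emits the same header subset the reader parses. Signals
#' are stored as float64 with identity calibration, one data record.
#'
#' @param path output path.
#' @param signals channels x samples numeric matrix (physical units).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param events data.frame with 1-based `position` and integer `type`.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(path, signals, fs, channel_names,
                      events = data.frame(position = integer(0), type = integer(0))) {
  ns <- nrow(signals)
  stopifnot(length(channel_names) == ns)
  n_samp <- ncol(signals)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(n) writeBin(raw(n), con)
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  # fixed header
  writeBin(charToRaw(sprintf("%-8s", "GDF 2.20")), con)
  pad(184L - 8L)                          # patient/recording metadata unused
  wint(1L + ns, 2L)                       # header length in 256-byte blocks
  pad(236L - 186L)
  writeBin(1L, con, size = 8L, endian = "little")  # one data record
  wint(n_samp, 4L); wint(fs, 4L)          # record duration = n_samp / fs seconds
  wint(ns, 2L)
  pad(2L)                                 # -> 256-byte fixed header
  # channel headers, field-blocked
  for (nm in channel_names) writeBin(charToRaw(sprintf("%-16s", substr(nm, 1, 16))), con)
  pad(80L * ns)                            # transducer
  pad(6L * ns)                             # physical dimension
  pad(2L * ns)                             # physical dimension code
  writeBin(rep(0, ns), con, endian = "little")        # physmin
  writeBin(rep(1, ns), con, endian = "little")        # physmax
  writeBin(rep(0, ns), con, endian = "little")        # digmin
  writeBin(rep(1, ns), con, endian = "little")        # digmax
  pad(68L * ns)                            # prefilter text + filter settings
  wint(rep(n_samp, ns), 4L)                # samples per record
  wint(rep(17L, ns), 4L)                   # float64
  used <- 16L + 80L + 6L + 2L + 32L + 68L + 4L + 4L
  pad((256L - used) * ns)
  # one record, channel-blocked
  for (ch in seq_len(ns))
    writeBin(as.double(signals[ch, ]), con, endian = "little")
  # event table, mode 1
  nev <- nrow(events)
  writeBin(as.raw(c(1L, nev %% 256L, (nev %/% 256L) %% 256L, nev %/% 65536L)), con)
  writeBin(as.numeric(fs), con, size = 4L, endian = "little")
  if (nev > 0L) {
    wint(events$position, 4L)
    wint(events$type, 2L)
  }
  invisible(path)
}
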