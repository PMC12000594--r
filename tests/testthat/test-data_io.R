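test_that("trialset enforces its structural invariants", {
  sig <- array(0, c(3, 2, 4))
  expect_error(trialset(sig, labels = c(0L, 1L), fs = 250,
                        channel_names = c("a", "b"),
                        class_names = c("x", "y")),
               "label count")
  expect_error(trialset(sig, labels = c(0L, 1L, 2L), fs = 250,
                        channel_names = c("a", "b"),
                        class_names = c("x", "y")),
               "labels must lie")
  expect_error(trialset(sig, labels = c(0L, 1L, 0L), fs = 250,
                        channel_names = "a", class_names = c("x", "y")),
               "channel_names")
  expect_error(trialset(sig, labels = c(0L, 1L, 0L), fs = 0,
                        channel_names = c("a", "b"),
                        class_names = c("x", "y")),
               "fs must be")
  ts <- trialset(sig, labels = c(0L, 1L, 0L), fs = 250,
                 channel_names = c("a", "b"), class_names = c("x", "y"))
  expect_s3_class(ts, "trialset")
  expect_identical(dim(ts), c(3L, 2L, 4L))
})

test_that("container round trip is lossless and byte-stable", {
  ts <- rand_trialset(n = 5L, C = 3L, T = 17L, m = 2L, seed = 4L)
  f1 <- withr::local_tempfile()
  save_trialset(ts, f1)
  back <- load_trialset(f1)
  expect_identical(back$signals, ts$signals)       # bit-exact doubles
  expect_identical(back$labels, ts$labels)
  expect_identical(back$channel_names, ts$channel_names)
  expect_identical(back$class_names, ts$class_names)
  expect_identical(back$fs, ts$fs)
  f2 <- withr::local_tempfile()
  save_trialset(back, f2)                          # save -> load -> save
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("minimal trialsets and corrupt containers are handled", {
  ts <- trialset(array(c(1, 2, 3, 4), c(1, 1, 4)), labels = 0L, fs = 250,
                 channel_names = "only", class_names = c("a", "b"))
  f <- withr::local_tempfile()
  save_trialset(ts, f)
  expect_identical(load_trialset(f)$signals, ts$signals)
  # container with a metadata field removed must name the missing field
  raw <- readBin(f, "raw", file.size(f))
  hdr_len <- readBin(raw[11:18], "integer", size = 8L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(raw[19:(18 + hdr_len)]))
  meta$labels <- NULL
  new_hdr <- charToRaw(jsonlite::toJSON(meta))
  f3 <- withr::local_tempfile()
  con <- file(f3, "wb")
  writeBin(raw[1:10], con)
  writeBin(length(new_hdr), con, size = 8L, endian = "little")
  writeBin(new_hdr, con)
  writeBin(raw[(19 + hdr_len):length(raw)], con)
  close(con)
  expect_error(load_trialset(f3), "labels")
  expect_error(load_trialset(withr::local_tempfile(lines = "not a container")),
               "magic")
})

test_that("GDF round trip recovers signals, events and sampling rate", {
  f <- withr::local_tempfile()
  fx <- write_gdf_fixture(f)
  rec <- read_gdf(f)
  expect_equal(rec$fs, 250)
  expect_equal(rec$channel_names, c("EEG1", "EEG2"))
  expect_equal(rec$signals, fx$signals, tolerance = 1e-12)
  expect_equal(sum(rec$events$type == 768L), 8L)
})

test_that("2a loader epochs cue-marked trials to the requested window", {
  f <- withr::local_tempfile()
  fx <- write_gdf_fixture(f, n_trials = 8L,
                          labels = rep(c(1L, 2L, 3L, 4L), 2L))
  spec <- epoch_spec(0, 16 / 250, c("EEG1", "EEG2"))
  ts <- load_bci_iv_2a(f, spec = spec)
  expect_equal(n_trials(ts), 8L)
  expect_identical(dim(ts)[2:3], c(2L, 16L))
  expect_equal(ts$labels, fx$labels)
  expect_length(ts$class_names, 4L)
  # epoching is index-exact: trial i covers [onset, onset + 16)
  for (i in c(1L, 5L))
    expect_equal(ts$signals[i, , ],
                 fx$signals[, fx$onsets[i]:(fx$onsets[i] + 15L)])
  # container round trip of the loaded set is bit-identical
  fc <- withr::local_tempfile()
  save_trialset(ts, fc)
  expect_identical(load_trialset(fc)$signals, ts$signals)
})

test_that("2a loader validates labels, channels and window", {
  f <- withr::local_tempfile()
  write_gdf_fixture(f)
  expect_error(epoch_spec(2, 2, "EEG1"), "zero-length")
  spec <- epoch_spec(0, 16 / 250, c("EEG1", "NOPE"))
  expect_error(load_bci_iv_2a(f, spec = spec), "unknown channel")
  lf <- withr::local_tempfile(lines = as.character(c(1, 2, 3)))  # 3 labels, 8 trials
  expect_error(load_bci_iv_2a(f, lf, epoch_spec(0, 16 / 250, "EEG1")),
               "expected 8 trials, found 3")
})

test_that("2a channel order follows channels_keep", {
  f <- withr::local_tempfile()
  fx <- write_gdf_fixture(f)
  spec <- epoch_spec(0, 16 / 250, c("EEG2", "EEG1"))   # reversed
  ts <- load_bci_iv_2a(f, spec = spec)
  expect_identical(ts$channel_names, c("EEG2", "EEG1"))
  expect_equal(ts$signals[1, 1, ],
               fx$signals[2, fx$onsets[1]:(fx$onsets[1] + 15L)])
})

test_that("2b loader concatenates sessions in order and checks fs", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gdf_fixture(f1, n_trials = 4L, labels = c(1L, 2L, 1L, 2L))
  write_gdf_fixture(f2, n_trials = 4L, labels = c(2L, 2L, 1L, 1L))
  spec <- epoch_spec(0, 16 / 250, c("EEG1", "EEG2"))
  ts <- load_bci_iv_2b(c(f1, f2), spec = spec)
  expect_equal(n_trials(ts), 8L)
  expect_equal(ts$labels, c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L))  # session order
  expect_length(ts$class_names, 2L)
  expect_error(load_bci_iv_2b(character(0), spec = spec), "empty session")
  f3 <- withr::local_tempfile()
  write_gdf_fixture(f3, n_trials = 4L, fs = 125)
  expect_error(load_bci_iv_2b(c(f1, f3), spec = spec), "fs")
})
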