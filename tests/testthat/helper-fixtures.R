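# Shared fixtures, all built in code at test time.

# tiny architecture for fast training / gradient tests
tiny_net_config <- function(channels = 3L, samples = 40L, n_classes = 2L,
                            dropout = 0) {
  network_config(channels, samples, n_classes, f1 = 2L,
                 kernels = c(5L, 3L, 3L), pool = 10L, depth = 2L, heads = 2L,
                 ff_dim = 8L, conv_dropout = dropout, encoder_dropout = dropout,
                 classifier_dropout = dropout)
}

# small-but-learnable configuration used by protocol-level tests
small_net_config <- function(channels = 4L, samples = 500L, n_classes = 2L)
  network_config(channels, samples, n_classes, f1 = 4L,
                 kernels = c(25L, 17L, 9L), pool = 100L, depth = 1L,
                 heads = 2L, ff_dim = 24L)

# deterministic GDF recording with cue/trial events; returns file path
write_gdf_fixture <- function(path, n_trials = 8L, n_channels = 2L,
                              fs = 250, trial_len = 16L, gap = 40L,
                              labels = rep(c(1L, 2L), length.out = n_trials)) {
  total <- n_trials * gap + 100L
  set.seed(99)
  sig <- matrix(round(stats::rnorm(n_channels * total), 6), n_channels, total)
  onsets <- 50L + (seq_len(n_trials) - 1L) * gap
  events <- data.frame(
    position = as.integer(rbind(onsets, onsets + 2L)),
    type = as.integer(rbind(rep(768L, n_trials), 768L + labels)))
  write_gdf(path, sig, fs, paste0("EEG", seq_len(n_channels)), events)
  list(path = path, signals = sig, onsets = onsets, labels = labels - 1L)
}

rand_trialset <- function(n = 6L, C = 2L, T = 12L, m = 2L, seed = 1L) {
  set.seed(seed)
  trialset(array(stats::rnorm(n * C * T), c(n, C, T)),
           labels = rep(seq_len(m) - 1L, length.out = n), fs = 250,
           channel_names = paste0("ch", seq_len(C)),
           class_names = paste0("cls", seq_len(m)))
}
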