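#' Specification for synthetic motor-imagery-like EEG
#'
#' The generator emulates the spatial structure motor-imagery decoders
#' exploit: every channel carries a band-limited rhythm (default mu band,
#' 8-12 Hz at 250 Hz) in 1/f-shaped background noise, and each class
#' modulates the rhythm amplitude on its own designated channel subset
#' (channels `k * floor(C/M) .. (k+1) * floor(C/M) - 1` for class `k`,
#' 0-based, mimicking event-related desynchronization lateralization). The
#' band power on a class's designated channels is `1 + effect_size` times the
#' baseline, so `effect_size = 0` yields indistinguishable classes.
#'
#' @param n_trials_per_class trials per class.
#' @param n_classes 2 or 4.
#' @param channels channel count `C` (at least `n_classes`).
#' @param samples trial length `T`.
#' @param fs sampling rate (default 250 Hz).
#' @param rhythm_band two-element band `[f_lo, f_hi]` in Hz inside `(0, fs/2)`.
#' @param effect_size relative band-power increase on designated channels.
#' @param noise_sigma S.D. of the 1/f background noise (amplitude units are
#'   arbitrary; standardization removes scale).
#' @param seed generator seed.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n_trials_per_class = 20L, n_classes = 2L,
                       channels = 4L, samples = 500L, fs = 250,
                       rhythm_band = c(8, 12), effect_size = 1,
                       noise_sigma = 0.5, seed = 1L) {
  if (rhythm_band[1] <= 0 || rhythm_band[2] <= rhythm_band[1] ||
      rhythm_band[2] >= fs / 2)
    stop("rhythm_band must satisfy 0 < f_lo < f_hi < fs/2")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (channels < n_classes)
    stop(sprintf("need at least %d channels for %d class-specific subsets",
                 n_classes, n_classes))
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(channels), samples = as.integer(samples),
                 fs = fs, rhythm_band = rhythm_band,
                 effect_size = effect_size, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# 1/f-shaped noise via spectral shaping of white noise
.pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)               # two-sided frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic motor-imagery trial set
#'
#' Deterministic under `spec$seed`; labels are balanced and trials
#' class-interleaved. See [synth_spec()] for the signal model.
#'
#' @param spec a [synth_spec()].
#' @return a `trialset` with `n_trials_per_class * n_classes` trials.
#' @export
generate_trials <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  C <- spec$channels; T <- spec$samples; M <- spec$n_classes
  n <- spec$n_trials_per_class * M
  per <- C %/% M
  sig <- array(0, c(n, C, T))
  lab <- rep(seq_len(M) - 1L, length.out = n)
  tt <- seq_len(T) / spec$fs
  amp_gain <- sqrt(1 + spec$effect_size)   # power gain 1 + effect_size
  with_local_seed(spec$seed, {
    for (i in seq_len(n)) {
      cls <- lab[i]
      designated <- cls * per + seq_len(per)
      for (c in seq_len(C)) {
        f0 <- stats::runif(1, spec$rhythm_band[1], spec$rhythm_band[2])
        phase <- stats::runif(1, 0, 2 * pi)
        amp <- if (c %in% designated) amp_gain else 1
        x <- amp * sin(2 * pi * f0 * tt + phase)
        if (spec$noise_sigma > 0)
          x <- x + spec$noise_sigma * .pink_noise(T, spec$fs)
        sig[i, c, ] <- x
      }
    }
  })
  trialset(sig, lab, spec$fs,
           channel_names = sprintf("S%02d", seq_len(C)),
           class_names = paste0("class", seq_len(M) - 1L),
           subject_id = "synthetic", session_tag = "synthetic")
}

#' Tiny deterministic worked fixture
#'
#' An 8-trial, 2-channel, 16-sample trial set with small integer-valued
#' signals and two balanced classes, constructed arithmetically (no RNG) so
#' it is identical on every platform. Used for hand-checkable unit examples:
#' standardization arithmetic, S&R recombination enumeration and container
#' round trips.
#'
#' @return a `trialset`.
#' @export
make_worked_fixture <- function() {
  n <- 8L; C <- 2L; T <- 16L
  sig <- array(0, c(n, C, T))
  for (i in seq_len(n))
    for (c in seq_len(C))
      sig[i, c, ] <- (i * 7L + c * 3L + seq_len(T) * 5L) %% 11L - 5L
  trialset(sig, labels = rep(c(0L, 1L), each = 4L), fs = 250,
           channel_names = c("C3", "C4"),
           class_names = c("left_hand", "right_hand"),
           subject_id = "fixture", session_tag = "worked")
}

#' Band power via Welch-style periodogram averaging
#'
#' Mean power spectral density inside `band`, averaged over 50%%-overlapping
#' Hann-windowed segments. Used by tests as an independent oracle for the
#' generator's class-dependent rhythm modulation.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param band two-element frequency band in Hz.
#' @param seg_len segment length in samples.
#' @return mean band power (arbitrary units).
#' @export
band_power <- function(x, fs, band, seg_len = 128L) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  freqs <- (seq_len(seg_len) - 1L) * fs / seg_len
  keep <- freqs >= band[1] & freqs <= band[2]
  pw <- vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1L)] * win
    mean(Mod(stats::fft(seg))[keep]^2)
  }, 0)
  mean(pw)
}
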