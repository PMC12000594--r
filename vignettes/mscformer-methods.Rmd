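---
title: "Decoding motor-imagery EEG with a multi-scale convolutional Transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor-imagery EEG with a multi-scale convolutional Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscformer)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement without executing
it — produces measurable EEG signatures: event-related desynchronization and
synchronization of the mu (8–12 Hz) and beta rhythms over sensorimotor
cortex, lateralized by the imagined effector. A subject-specific MI decoder
maps a short multi-channel EEG trial to the imagined movement class. The two
standard benchmarks this package targets are the BCI Competition IV-2a set
(22 EEG channels, 250 Hz, four classes: left hand, right hand, feet, tongue;
the 2–6 s segment of each trial giving per-trial matrices of shape
(22, 1000)) and IV-2b (3 bipolar channels, two classes, 3–7 s segment,
(3, 1000)).

The difficulty is the usual one in EEG decoding: few trials per subject
(288 per 2a session), low signal-to-noise ratio, and strong inter-subject
variability. MSCFormer addresses it with three ideas: **multi-scale temporal
convolution** (three parallel CNN branches with different kernel lengths see
the signal at different temporal scales), **global attention** (a Transformer
encoder over the pooled feature tokens captures long-range dependencies that
convolutions miss), and **segmentation-and-reconstruction (S&R)
augmentation** to multiply the effective training set.

## Pipeline

### Preprocessing

Raw trials are used as cut — no band-pass filtering and no artifact
rejection. The only preprocessing is zero-mean standardization,

$$\tilde X_i = \frac{X_i - \mu}{\sigma},$$

with $\mu, \sigma$ the mean and population standard deviation of the
**training** signals, applied unchanged to validation and test trials so no
information flows backwards from held-out data. The default scope is
*global* (one scalar pair pooled over all trials, channels and samples):
the statistics describe "the raw EEG data" as a whole, and a per-channel
variant is available via `fit_standardizer(scope = "per_channel")` for data
whose channels differ grossly in gain. Fitting on the training fold and
applying everywhere is enforced by the training protocol itself.

A zero standard deviation (a constant signal) raises an error rather than
silently producing NaNs; an explicit `eps` argument regularizes the
denominator when a degenerate channel is expected.

### S&R augmentation

Each training trial is split into `n_segments` contiguous time segments
(default $N_s = 8$; when $T$ is not divisible the first $T \bmod N_s$
segments carry the extra sample). An artificial trial is assembled by
drawing, for every segment slot $k$, a donor trial of one fixed class
uniformly with replacement and copying its $k$-th segment — segments never
change temporal position, preserving the coarse temporal structure of the
trial. Recombination is class-conditional: the artificial trial inherits the
donors' common label, and cross-class mixing is rejected as
label-incoherent.

Two quantities are deliberate design choices rather than published values:
the number of artificial trials defaults to the size of the training fold
(doubling the data), and donors for different slots may coincide. Both are
configurable (`augment_config()`); the enumeration tests treat the donor
assignment space exhaustively on a small fixture, so the semantics are
pinned independently of these defaults. Augmentation applies to the four
training subsets of a fold only — never to validation or test data — and
augmented trials carry a provenance tag (`trial_ids = 0`) that the protocol
checks.

Standardization and S&R commute (both are per-sample affine maps composed
with a donor permutation), so the order of the two steps does not matter
once the statistics are fixed; the package fits the standardizer on the
original training subsets and augments the raw trials.

### The network

Each of the three convolution branches applies, in order: a temporal
convolution with $F_1 = 16$ filters of length $K_c \in \{85, 65, 45\}$
(length-preserving zero padding, so all branches emit $T$-length maps); a
depthwise spatial convolution of shape $(C, 1)$ with depth multiplier 1 —
one spatial filter per temporal map, no cross-map mixing and no bias;
batch normalization; ELU; average pooling with kernel and stride $P$
(ceil mode — the trailing short window averages its own length, giving
$T_p = \lceil T/P \rceil$ tokens, e.g. 84 tokens at $P = 12$ and 14 at
$P = 72$ for $T = 1000$); and dropout 0.5. Neither convolution carries a
bias term: the temporal output feeds the spatial convolution linearly and
the spatial output feeds batch normalization, which absorbs any offset.

The three $(F_1, T_p)$ maps are transposed and concatenated feature-wise
into tokens of width $F_2 = 3 F_1 = 48$. A learnable class token is
prepended and a learnable positional table of shape $(T_p + 1, F_2)$ added.
The encoder is a post-norm Transformer: $L = 5$ layers of multi-head
attention ($h = 8$ heads, $d_k = F_2/h = 6$) and a GELU feed-forward block
of width $4F_2 = 192$, each sublayer followed by residual addition **then**
layer normalization ($\mathrm{LN}(\mathrm{MHA}(x) + x)$,
$\mathrm{LN}(\mathrm{FFN}(y) + y)$). The Q/K/V and output projections are
bare weight matrices (no biases); the feed-forward linears carry biases.
Dropout 0.25 acts inside each sublayer and again before the final linear
classifier, which reads only the class-token embedding after layer $L$ and
applies softmax. Training minimizes the mean cross-entropy.

The MSNet ablation keeps the convolution module unchanged, flattens the
$T_p \times F_2$ token map to a vector and feeds the same
dropout-plus-linear classifier — it is a distinct head, not a depth-0
encoder, and the constructors enforce that distinction.

### Choosing the under-documented hyperparameters

The architecture table of the source publication is not machine-readable in
our copy, so the values not stated in its running text ($F_1$, the
feed-forward width, the default pooling size, bias conventions) were fixed
by requiring the instantiated models to reproduce the published
trainable-parameter counts. That requirement has no exact solution: the
four published counts are mutually inconsistent (the two ablation counts
imply token lengths whose difference contradicts the two full-network
counts under any shared convolution module — verified by exhaustive search
over $F_1$, feed-forward width, pooling, depth and every plausible bias
convention). The adopted configuration — $F_1 = 16$, feed-forward width
$192$, $P = 52$ for both benchmark geometries, projections without biases —
reproduces three of the four counts exactly (145.9 k and 144.9 k for the
full network, 5.3 k for the 3-channel ablation); the 22-channel ablation
computes to 8.1 k against a published 8.6 k, and the corresponding test is
left failing rather than papered over. A shared $P = 52$ is also consistent
with the published accuracies: the 2b headline equals the 2b pooling-sweep
peak at 52, while the 2a headline sits below the 2a sweep peaks, as one
expects when the default pooling is not the 2a optimum.

### Training protocol

Subject-specific five-fold cross-validation: the training session is
shuffled once (seeded) and split into five subsets whose sizes differ by at
most one (288 trials give validation sizes 58/58/58/57/57). For each fold,
the remaining four subsets plus their S&R-augmented copies form the
training pool; one epoch cycles once over the shuffled pool in batches
(default batch 288 — when the pool is smaller, an epoch is one full-pool
batch). Adam uses learning rate $10^{-3}$, $\beta_1 = 0.5$,
$\beta_2 = 0.999$; weight decay (L2, default 0.001 for the 3-channel task,
0 otherwise) applies to weight matrices but not to biases or normalization
parameters. After every epoch the validation loss is computed without
augmentation; the checkpoint with the lowest validation loss — the earlier
epoch on ties, preferring the more regularized model — is restored and
evaluated once on the held-out test session. Per-fold seeds are
`seed + fold` so folds are independent but reproducible; a non-finite
training loss aborts with diagnostics rather than silently corrupting the
trace. The subject-level report averages the five folds' test accuracy,
kappa and confusion matrices.

### Metrics

Accuracy is the confusion-matrix trace over its total, in percent. Cohen's
kappa is $(p_o - p_e)/(1 - p_e)$; $p_e$ defaults to the marginal-product
form, which equals the $1/M$ random-guess rate on the balanced benchmark
sessions (the uniform form is available explicitly, and the ambiguity is
immaterial there). Paired per-subject comparisons use the two-sided
Wilcoxon signed-rank test — exact null distribution up to $n = 25$, zero
differences dropped — with the conventional `**`/`*`/`n.s.` tiers at 0.01
and 0.05. ROC curves and AUC are provided for binary tasks only (pROC does
the curve construction; tests cross-check the AUC against the brute-force
pairwise Mann–Whitney probability).

## The synthetic generator

`generate_trials()` emulates the statistical structure MI decoders exploit,
without claiming biophysical realism: every channel carries a sinusoid with
random frequency inside the rhythm band (default 8–12 Hz) and random phase,
embedded in 1/f-shaped noise (spectrally shaped white noise, `noise_sigma`
S.D.); class $k$ multiplies the amplitude on its designated channel block
(channels $k\lfloor C/M \rfloor$ to $(k+1)\lfloor C/M \rfloor - 1$,
0-based) by $\sqrt{1 + \text{effect\_size}}$, so the band power ratio
between classes on a designated channel is exactly $1 + \text{effect\_size}$
and `effect_size = 0` is an exact null. Amplitude units are arbitrary —
standardization removes scale.

What passing tests on this generator do show: the full pipeline (epoching,
standardization, augmentation, optimization, checkpoint selection, metrics)
extracts a genuinely present band-power contrast, with accuracy rising in
the effect size. What they do not show: performance on real EEG, which adds
non-stationarity, artifacts, volume-conduction correlations between
channels and much weaker effects. The benchmark protocol is implemented and
tested end to end, but published benchmark accuracies are not reproduced
here — that requires the competition download and GPU-scale training.

The worked fixture (`make_worked_fixture()`) is an 8-trial, 2-channel,
16-sample set built arithmetically (no RNG) with small integer values, used
where a test wants hand-checkable numbers: standardization statistics, S&R
recombination enumeration, container round trips.

## Numerical and engineering choices

* **Problem sizes in tests.** Protocol-level tests run a reduced
  configuration (4 channels, 250–500 samples, $F_1 = 4$, kernels 25/17/9,
  one encoder layer, 25–50 epochs), chosen so the five-fold separability
  check trains in about a minute while still exercising every code path of
  the full architecture. The full benchmark geometry appears in tests only
  for shape and parameter-count assertions.
* **Gradients.** Forward and backward passes are hand-written in base R
  (batch-norm through batch statistics, softmax Jacobian in attention,
  exact-GELU derivative, layer-norm backward) and verified against central
  finite differences at $10^{-4}$ relative tolerance on random
  configurations.
* **Determinism.** Every stochastic step (weight init, dropout, batch
  order, augmentation draws, fold shuffle) runs under a locally scoped seed
  that restores the caller's RNG state; identical seeds give bit-identical
  fold results.
* **Batch norm** uses momentum 0.1 and $\varepsilon = 10^{-5}$ (biased
  variance for normalization, unbiased in the running estimate); layer norm
  uses $\varepsilon = 10^{-5}$. Both are recorded in the configuration
  object.
* **Ties.** Argmax decoding breaks probability ties toward the lower class
  index; validation-loss ties keep the earlier epoch.
* **Epoching** is index-exact: the window is
  $[\,\mathrm{round}(t_\mathrm{start} f_s),\ \mathrm{round}(t_\mathrm{start} f_s) + (t_\mathrm{end}-t_\mathrm{start}) f_s)$
  in 0-based samples, and a window whose length is not an integer number of
  samples is rejected. Trials flagged as artifact-contaminated are kept by
  default (the benchmark counts 288 trials per session); `exclude_artifacts`
  drops them. Whether the 2a cue timing is referenced to the trial-start or
  the cue event is not stated by the protocol text we follow; the loader
  anchors on the trial-start markers (the dataset's standard timing) and
  documents rather than hides that choice.
* **GDF support** is a minimal hand-written reader for the subset of GDF 2.x
  needed for trial extraction (fixed header, field-blocked channel headers,
  int16/float payloads with linear calibration, mode-1/3 event tables),
  because no installed R package parses GDF. The matching writer exists to
  build synthetic fixtures; it emits the same subset the reader consumes,
  so round-trip tests pin the container semantics, not conformance of
  third-party files.
* **The portable trial container** is a single file: a magic line, a JSON
  metadata block and the raw little-endian float64 array. Doubles are
  written bit-exactly; save→load→save is byte-identical, which the tests
  assert and the manifest fingerprint relies on.

## Known limitations

* The published benchmark accuracy tables are out of scope (no data
  download; CPU-scale budgets). The protocol is faithful; the numbers are
  not asserted.
* The 8.6 k published count for the 22-channel ablation cannot be met
  jointly with the other three counts; see above.
* Base-R training is practical for the reduced configurations used in
  testing and for small studies, not for 1000-epoch full-geometry runs.
* Multi-class ROC, cross-subject transfer, pre-norm encoder variants and
  frequency-domain augmentation are deliberately absent.
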