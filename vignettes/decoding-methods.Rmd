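---
title: "Decoding working-memory content from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory content from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmdecode)
```

## The problem

During a delayed-recognition trial a child encodes a stimulus (visual,
spatial or verbal), maintains it across a blank delay, and compares it
with a probe. The category of the maintained content is not observable
behaviourally, but it leaves a distributed voltage pattern across the
EEG montage. `wmdecode` implements the standard time-resolved
multivariate pattern analysis (MVPA) read-out of that pattern: a
shrinkage-regularised linear discriminant analysis (LDA) classifier is
trained on class-balanced pseudo-trials and its cross-validated accuracy
is tracked across the Baseline (-300–0 ms), Sensory (0–1000 ms) and
Delay (1000–3000 ms) windows, across fine time bins (temporal
generalization), across session halves, and across subjects.

Because suitable child EEG recordings are access-restricted, the package
ships a synthetic-data generator that emulates the study design and the
signal structure the analysis assumes, so that every stage of the
pipeline is verifiable end to end.

## The forward model

The generator plants, for each category $c$, a fixed unit-norm spatial
pattern $p_c \in \mathbb{R}^{64}$ and synthesizes

$$x(t) = \sum_{\text{trials } i} a \, s_i \, p_{c(i)} \, f(t - t_i) + \eta(t),$$

where $a$ is `amp_sensory`, $s_i$ the subject's SNR multiplier, $t_i$
the stimulus onset, and the envelope $f$ equals 1 during the Sensory
period and decays as $\exp(-(t - 1000)/\tau)$ through the Delay
(`delay_decay_tau_ms`). $\eta$ is spatially independent $1/f$ noise
(`noise_sd`, `noise_pink_exponent`). Key design choices:

* **Pattern geometry.** The visual and spatial patterns have cosine
  similarity 0.6 while the verbal pattern is orthogonal to both,
  constructed exactly via a square root of the $3 \times 3$ Gram
  matrix mapped through a random orthonormal basis. This encodes the
  classical domain split of working memory (visuo-spatial vs verbal)
  and makes visual and spatial memoranda mutually more confusable than
  either is with verbal content.
* **Amplitude and decay.** The defaults `amp_sensory = 3` uV and
  `delay_decay_tau_ms = 800` ms were calibrated once, on the
  epoch-level generation path at the package's standard calibration
  size (20 subjects, 60 trials per category, 30 CV iterations), so that
  the three windows reproduce the qualitative effect structure the
  analysis is designed to detect — Baseline at chance (33 %), Sensory
  around 55 %, Delay around 44 % — and were not revisited afterwards.
* **Noise.** `noise_sd = 10` uV of $1/f$ noise per channel is a
  realistic magnitude for bandpassed paediatric EEG and produces the
  pseudo-trial SNR regime in which averaging and shrinkage matter. On
  the continuous path the spectrum is flattened below `noise_floor_hz`
  (default 0.1 Hz): amplifier coupling and electrode half-cell
  potentials bound real drift power, and unbounded $1/f$ drift over a
  45-minute session would otherwise dominate the variance budget.
* **Subjects.** Ages are uniform over 84–152 months (the study's 7;0 to
  12;8 range); SNR multipliers are log-normal with spread
  `subject_snr_sd` (default 0.3), optionally modulated linearly by age
  (`age_effect`, default 0 — decoding independent of age). Behavioural
  responses are Bernoulli with per-subject accuracy (default 0.9,
  matching the post-exclusion group mean).
* **Artifacts.** Each trial receives, with probability `artifact_rate`,
  a 100-ms, ±200 uV square pulse on a random channel subset inside the
  epoch span, giving the ±150 uV rejection rule something real to
  remove.
* **Exact balancing.** Per-category trial counts and the 50 % probe
  match rate are enforced exactly per category (not in expectation), so
  the scheduler is testable sample by sample. ITIs are drawn uniformly
  from the 800–1200 ms grid in 50-ms steps; probe and response periods
  carry no category signal, so they cannot contaminate the epochs,
  which end before the probe.
* **A representational-change switch.** `rotate_at_offset = TRUE`
  replaces the Delay-period patterns with an independent set
  orthogonalized against the Sensory patterns — the generator for a
  code that rotates at stimulus offset, used to validate the temporal
  generalization analysis (block structure instead of full
  generalization).

Two generation paths exist. `synthesize_subject()` produces the full
continuous recording at 1000 Hz (default; the bundled configurations
use 500 Hz to halve memory) which then passes through the real
preprocessing chain. `synthesize_epochs()` is the epoch-level fast path
used for calibration studies: it generates the epochs an ideal
preprocessing would produce, with independent noise per epoch and no
filtering. The two differ in one documented respect: the idealized
sustained envelope is concentrated near 0 Hz, and the full chain's
1-Hz zero-phase highpass interacts with it in two ways that real,
broadband neural patterns suffer far less. First, attenuation: a 1-s
boxcar keeps only its spectral content above roughly 1 Hz (a
second-order zero-phase highpass passes ~6 % amplitude at 0.5 Hz but
~85 % at 1.5 Hz), so full-chain window accuracies are much lower at
the same `amp_sensory` and the Sensory–Delay gap is compressed.
Second, temporal smearing: zero-phase (forward–backward) filtering is
non-causal, so part of the stimulus response is displaced *backwards*
into the pre-stimulus window — the package's full chain faithfully
reproduces the known highpass-filter decoding artifact in which
spurious above-chance "baseline" decoding appears, a caveat documented
in the EEG decoding literature and checked for in careful empirical
work. Both effects are properties of the idealized DC-like envelope
meeting a real preprocessing chain, not implementation errors; the
calibration targets above refer to the epoch-level path, and
`scripts/acceptance.R` reports the two paths under separate names.

## Preprocessing

`bandpass_resample()` downsamples by an integer factor (zero-phase
windowed-sinc anti-alias lowpass, then subsampling), removes the DC
offset, and applies a second-order Butterworth bandpass (1–40 Hz)
forward and backward — 12 dB/octave roll-off per pass and no phase
shift. `epoch_trials()` cuts half-open [-300, 3000) ms epochs; all
window boundaries throughout the package are half-open so the three
analysis windows partition the epoch disjointly. No baseline-mean
subtraction is applied at epoching; demeaning happens inside the
classification pipeline. `reject_artifacts()` drops any trial exceeding
±150 uV on any channel and logs trial and channels. Subjects are
excluded when behavioural accuracy is at or below 50 % (inclusive) or
when at most `min_trials` clean trials remain (strictly more than 200
are required at full session length). Missing responses score as
incorrect — the conservative reading of "percentage of correct
responses" over all trials. Only the automatic amplitude criterion is
implemented; interactive cleaning (ICA-based ocular correction, visual
inspection, spline channel interpolation) is out of scope, and users
can supply pre-cleaned epochs instead.

## The decoding pipeline

Each cross-validation iteration performs, in order:

1. **Trial-level stratified split**: 2/3 training, 1/3 test, per class.
   Splitting at the single-trial level guarantees that no source trial
   contributes to both partitions through an average.
2. **Pseudo-trial averaging** within each partition independently:
   trials of a class are permuted and partitioned into groups of
   exactly 5; remainder trials are dropped (keeping pseudo-trial noise
   homogeneous); each group is averaged. Groups are re-drawn freshly on
   each of the (default 100) iterations.
3. **Stratified up-sampling** within each partition: minority classes
   are duplicated uniformly with replacement to the majority count.
4. **Demeaning** with training-partition column means only (applied to
   both partitions); the order split → average → up-sample → demean is
   chosen for information hygiene — whether the original analysis
   demeaned jointly over all trials is not stated, and the train-only
   choice is the stricter one.
5. **Shrinkage LDA**: pooled within-class covariance
   $\hat\Sigma = (1-\lambda) S + \lambda \,(\mathrm{tr}\,S/p)\, I$ with
   the Ledoit–Wolf analytic $\lambda$ by default (64 channels easily
   outnumber the pseudo-trials in a fold), empirical class priors, and
   affine discriminants $w_k = \hat\Sigma^{-1}\mu_k$,
   $b_k = -\tfrac12 \mu_k^\top \hat\Sigma^{-1} \mu_k + \log\pi_k$.
   Exact score ties break to the smallest class index and are logged.

Accuracy is the mean over iterations; confusion matrices are
row-normalised (true class × predicted class). Temporal generalization
averages each epoch into 50-ms (or 20-ms) bins of channel-mean
voltages, reuses one trial split and one pseudo-trial grouping across
all bins within an iteration, demeans each bin by its
training-partition means, then trains per bin and tests on every bin.
The same 100 × (2/3, 1/3) scheme is used for the window and the
generalization analyses — the original toolbox default for the latter
is not stated, so the scheme is configurable. Split-half analyses
partition by experimental block (1–4 vs 5–8); cross-decoding fits on
all pseudo-trials of the training half and evaluates on the test half,
re-drawing pseudo-trial groupings over iterations since the halves are
disjoint by construction.

## Group statistics

Per-window group inference uses one-sided one-sample t-tests against
the theoretical chance of 1/3 ("no meaningful values below chance"),
Bonferroni-corrected over the simultaneous tests — 3 windows for the
time-averaged analysis, all bins for time-resolved maps. Whether the
original window tests were corrected across the 3 windows is ambiguous;
both modes are available via `n_tests`. The subject-wise permutation
test shuffles each subject's trial labels independently, recomputes
each subject's mean accuracy, and uses the cross-subject mean as the
group statistic (the cited toolbox routine does not name its statistic;
the mean is the simplest exchangeable choice) with the add-one p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, which can never be
exactly zero. Inside permutations the CV iteration count defaults to 10
for tractability; the reduction is recorded in the result. The
Sensory-vs-Delay comparison is a paired right-tailed t-test, the
individual-differences check a Pearson correlation, and the age
analysis an OLS regression of accuracy on age with the F-test p-value,
each refusing degenerate inputs (zero variance, constant age) rather
than returning NaN.

## Numerical and interface choices

* One master seed drives everything; per-subject seeds are
  `seed + index`, unrelated units of work get seeds through an integer
  mixing step (`derive_seed()`, kept within 32-bit range), and —
  importantly — each unit (one subject's synthesis; one permutation's
  shuffle plus its cross-validation) draws all of its randomness
  sequentially from a *single* `set.seed()` stream. Splitting one unit
  across several streams whose seeds sit at fixed affine offsets
  produces measurably correlated Mersenne-Twister streams: in an early
  implementation this biased the subject-wise permutation null enough
  to skew group p-values on zero-signal cohorts. Identical seeds give
  bit-identical results.
* Configs are YAML (`default_config()` documents the schema); events
  tables are BIDS-style TSV; recordings are float32 binary with a JSON
  sidecar; results are tidy CSV plus a JSON run manifest with file
  hashes.
* The spec-level command-line surface is fulfilled by `run_pipeline()`
  (simulate → preprocess → decode → stats → report) plus
  `make_fixture()`; both are plain exported functions so they compose
  with R scripts.
* Degenerate inputs fail loudly: infeasible pattern-similarity Gram
  matrices, singular covariances at $\lambda = 0$, windows without
  samples, classes with fewer trials than the group size (named in the
  error), montage mismatches in cross-decoding.

## What the tests do and do not show

The test suite validates the pipeline at scaled-down study sizes chosen
as the package's calibration conditions: a full-size (384-trial)
20-subject zero-signal cohort for chance calibration; cohorts of 20
subjects with 60 trials per category and 30 CV iterations for
signal-recovery checks; 8-subject cohorts for confusability structure;
60 trials per category with 32 channels, 50-Hz epochs and 20 iterations
for the 50-replicate individual-differences studies (a size chosen so
the correlation test has its designed power); and 99-permutation runs
with 5 inner CV iterations on a fresh zero-signal cohort per replicate
for the permutation level checks — fresh cohorts because permutation
p-values recomputed on one dataset share its chance label–noise
alignment and are not informative replicates. Because
the generator is a minimal sufficient forward model — linear patterns,
stationary $1/f$ noise, no eye blinks, no volume-conduction structure,
no trial-to-trial latency jitter of the neural response — passing tests
demonstrate the correctness and calibration of the analysis code, not
that real paediatric EEG will yield any particular accuracy. Real-data
properties the generator deliberately omits: spatially correlated
noise, non-stationarity across a session (fatigue), and genuine
oscillatory structure; results on real recordings depend on those.

One empirically honest subtlety: cross-validated accuracy on a finite
null dataset has a small negative bias (train- and test-subset class
means anticorrelate within a fixed sample), about -0.8 percentage
points at 128 trials per category and larger at smaller sessions. The
chance-calibration tests therefore check group means against the CI of
1/3 rather than demanding per-subject equality, and single null
datasets can sit one to two points off chance in either direction.
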