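---
title: "Measuring population-level song variability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring population-level song variability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(songvar)
```

`songvar` measures how variable the song of a population is: every bird's
syllable repertoire becomes a density in acoustic-feature space, every
ordered pair of birds gets a Kullback–Leibler (K-L) divergence, and the
population-level distribution of those divergences is the object of
inference. This vignette explains each stage, its assumptions, the
parameters that matter, and the choices made where more than one
reasonable design existed.

## 1. Frame-wise features and syllable segmentation

`compute_features()` performs short-time analysis with a 9 ms Hann window
advanced in 1 ms steps (both configurable; values of this magnitude are
the norm for zebra finch song analysis, whose syllables last tens to a
couple of hundred milliseconds). Per frame it computes:

* **amplitude** (dB): `10 log10` of summed spectral power inside the
  analysis band (default 300 Hz to the lesser of 11 025 Hz and Nyquist).
  Silent frames sit at a configurable floor (−120 dB).
* **Wiener entropy** (unitless, ≤ 0): `log(geometric mean / arithmetic
  mean)` of the in-band power spectrum; 0 for a flat spectrum, strongly
  negative for tones. A single-frame periodogram is exponentially
  distributed around the true spectrum, which biases the raw statistic to
  about −0.58 even for white noise, so the spectrum is first smoothed
  across frequency (boxcar, 8 bins by default) — a multitaper-style
  variance reduction that restores the flat-spectrum limit.
* **mean frequency** (Hz): power-weighted mean of in-band frequencies.
* **FM** (degrees in \[0, 90\]): `atan` of the ratio of the RMS
  time-derivative to the RMS frequency-derivative of the log-power
  spectrogram (finite differences). Steady tones give ≈ 0, sweeps give
  large values.
* **AM** (1/s, signed): central difference of log total in-band power.
* **pitch and pitch goodness**: the normalized autocorrelation of the
  frame, corrected for the analysis window's own autocorrelation, is
  evaluated on a fine fractional-lag grid (0.25-sample spacing) via a
  cosine transform of the power spectrum. Integer-lag autocorrelation is
  too coarse for fundamentals above ~4 kHz, whose periods span only 4–5
  samples at 22.05 kHz. Because a periodic frame peaks at every multiple
  of its period, the estimator takes the *first* local maximum within 90%
  of the tallest in-band peak — the standard defence against octave-down
  errors. The lag grid extends below the in-band range so that the
  short-lag plateau of low-pitched frames (autocorrelation near 1 at lags
  much shorter than the period) is never itself mistaken for a peak.
  Goodness is the peak height in \[0, 1\]; frames below
  `goodness_floor = 0.3` are unvoiced: their pitch is `NA` and they are
  excluded from syllable pitch statistics.

`segment_syllables()` marks a frame voiced when amplitude ≥ the per-bird
floor **and** mean frequency lies in the configured band. Maximal voiced
runs separated by gaps shorter than `min_gap_ms` (default 5 ms) are
merged; a merged run survives if its voiced fraction is at least
`continuity_min` (default 0.9 — "continuity" is operationalized as the
voiced-frame fraction of the run). Boundaries are then refined to the
sub-frame position where linearly interpolated amplitude crosses the
floor. For a symmetric analysis window, a threshold 3.01 dB below a
syllable's plateau crosses at the half-energy point, i.e. at the true
boundary — which is why `suggest_thresholds()` places the floor one
half-energy drop below the upper amplitude quantile, emulating the
per-bird manual threshold setting that is standard practice. Thresholds
are per-bird (manifest overrides), since recording setups differ.

`summarize_syllable()` reduces a segment (≥ 2 frames; shorter intervals
are rejected, as a sample variance needs two points) to its duration and
13 parameters: means of amplitude, pitch, FM, *squared* AM, entropy,
goodness, mean frequency; variances of pitch, FM, entropy, goodness, mean
frequency and AM. The mixed convention (mean of AM², variance of AM) is
deliberate and documented — the feature set's customary list is
asymmetric in exactly this way, and where the convention is ambiguous we
take the variance of AM itself.

## 2. Noise removal

Two stages, mirroring how cage noise actually enters such recordings:

* `drop_short_syllables()`: anything strictly shorter than 20 ms is
  removed. The boundary is kept ("shorter than" is strict): a 20.0 ms
  syllable survives. Mechanical clicks are shorter than this; song
  syllables are not.
* `trimmed_cluster_filter()`: trimmed k-means on standardized syllable
  duration (by default; other feature columns can be added). Exactly
  `floor(α·n)` syllables are discarded — the joint choice of discard set
  and k-partition minimizes within-cluster squared distance, computed by
  concentration steps from 20 seeded restarts plus a deterministic
  quantile start. Defaults: α = 0.03 (older, quieter recordings can use
  0.01 via the per-population manifest setting), k = 2 (a main duration
  mode plus a residual-noise mode; k is configurable). An optional
  variance-scaled mode allows heteroscedastic clusters with the variance
  ratio clamped at `restr_factor` (default 50); the default objective is
  the plain squared-distance one, which is also what the package's
  exhaustive-search oracle verifies on small instances. Trimming is
  applied per bird. Tables too small for the configuration are passed
  through untouched with a warning, and every discarded record is logged
  with its reason (`short` / `trimmed`).

## 3. Repertoire divergence

For an ordered pair (template, target) and one of the 13 parameters,
`estimate_density()` bins each bird's (duration, parameter) values on a
32 × 32 grid whose edges span the pooled range of *both* birds (5%
padding), smooths with a small Gaussian kernel (σ = 1 bin), adds a
regularization floor ε = 10⁻⁶ per cell and renormalizes. `kl()` then
evaluates `Σ p log(p/q)` in nats. Choices worth stating:

* **Pair-pooled grids** rather than one global grid: each comparison then
  resolves the space the two birds actually occupy. A global grid would
  make distant pairs coarser; the pooled-grid convention keeps the
  discretization error roughly constant per pair. (Consequence: values
  are comparable across pairs as estimates of the continuous divergence,
  not as sums over a shared partition.)
* **The floor ε** bounds any single divergence at roughly
  `log(1/ε) ≈ 13.8` nats: non-overlapping repertoires saturate there.
* **Natural log** throughout; a degenerate axis (zero range) collapses to
  a single bin with a warning; birds with fewer than two retained
  syllables are excluded from matrices with a warning.
* Verified properties: zero iff identical, nonnegativity, asymmetry,
  agreement within 5% with the closed-form divergence of discretized
  Gaussians, and < 10% drift under grid doubling on smooth densities.

`pairwise_kl_matrices()` produces the full asymmetric matrix per
parameter (n(n−1) ordered pairs); `symmetrize()` averages the two
directions per unordered pair; `tutor_tutee_kl()` computes the averaged
bidirectional divergence per (tutee, tutor) pair.

## 4. Inference

`build_analysis_table()` stacks the within-population ordered pairs and
takes `log(max(value, 10⁻⁸))` per parameter (floored cells are counted
and reported). `pca_pc1()` (column-centred, unscaled, via `prcomp`)
extracts PC1, with the sign fixed so loadings sum positive — larger PC1
means larger overall divergence. Because all 13 measures are divergences
of the same pairs, they are strongly correlated and PC1 typically
captures the bulk of their variance; constant columns are dropped with a
warning.

`fit_variability()` fits

```
PC1 ~ Population + (1 | template bird) + (1 | target bird)
```

on the full-matrix rows. Each pairwise row reuses two birds, so template
and target random intercepts absorb the repeated-measures structure;
birds have globally unique identifiers, which realizes their nesting in
population. Estimation is restricted maximum likelihood with a weak
log-barrier penalty (weight 10⁻²) on the random-effect scale parameters,
optimized over `lme4`'s modular deviance function: variances cannot
collapse to zero, so fits are never singular — the role a weak prior over
random effects plays in Bayesian mixed-model fitting — while
well-identified estimates move negligibly. Population means and 95%
Wald intervals come from a cell-means REML refit; likelihood-ratio tests
(`likelihood_ratio_test()`, `compare_populations()`) always use ML
refits, with χ² floored at zero and degrees of freedom equal to the
parameter-count difference. Reported variance components come from REML.
No multiple-testing correction is applied: the package's tests are single
planned contrasts. Secondary operations: `anova_max_duration()` (one-way
ANOVA via `aov` on each bird's longest retained syllable) and
`mann_whitney_directed()` (midrank-tie U statistic; tie-corrected normal
approximation, or exact enumeration of labelings when both groups have at
most 8 values — the convention is that `U` counts pairs where the first
sample exceeds the second).

## 5. The synthetic generator

`generate_population()` draws a pool of population-level syllable
archetypes (each a value of duration plus the 13 parameters, from uniform
priors over plausible zebra-finch magnitudes: duration 30–250 ms, pitch
450–5500 Hz, entropy −4 to −0.5, and so on; all configurable). Each bird
perturbs its drawn archetypes with Gaussian between-bird noise — scaled
by the population's `dispersion`, the generator's song-variability dial —
and emits renditions on a round-robin schedule with Gaussian rendition
noise. The round-robin schedule makes the zero-noise limit exact: with
`dispersion = 0` and `rendition_noise = 0` all birds have identical
repertoires and pairwise divergence is exactly zero. Gaussian
perturbations keep closed-form divergence checks available; positive
parameters are clamped.

`generate_tutor_tutee()` models copying fidelity τ at the *rendition*
level: a fraction τ of a tutee's syllables are renditions of the tutor's
archetypes, the rest renditions of the tutee's own innovated archetypes
(fresh prior draws scattered by `innovation_dispersion`). The tutee's
syllable distribution is therefore the mixture
`τ·tutor + (1−τ)·innovation`, so the divergence from the tutor is
monotone decreasing in τ by convexity of K-L in its second argument —
τ = 1 reproduces the tutor up to rendition noise, τ = 0 is an unrelated
bird. The alternative design, interpolating archetype *positions* toward
the tutor, was evaluated and rejected: once archetype separations exceed
the density bandwidth the divergence saturates and the τ-ordering is no
longer reliable, whereas mixture weights remain visible to a density
divergence at any separation.

`render_waveform()` turns a repertoire into audio: each syllable is a
harmonic stack (fundamental at the syllable's mean pitch, three harmonics
halving in amplitude, partials above Nyquist dropped) under an amplitude
envelope with 0.5 ms raised-cosine edges, all syllables at equal RMS, with
50 ms silent gaps. Equal RMS is deliberate: it gives the per-bird
amplitude threshold a well-defined half-energy crossing at every true
boundary, so segmentation accuracy can be judged against exact ground
truth. `inject_noise()` adds broadband clicks (2–8 ms, strictly below
the 20 ms filter) and long outlier bouts (400–800 ms) into silent gaps at
syllable-matched RMS, appending to the recording when no interior gap is
long enough.

What the generator does **not** emulate: pitch contours and frequency
sweeps within syllables, amplitude variation across renditions,
reverberation or background hum, bout-level syntax, and any perceptual
realism. Passing the round-trip tests therefore demonstrates that the
measurement chain is self-consistent and recovers planted structure — not
that segmentation thresholds transfer to arbitrary field recordings,
where per-bird manual threshold setting remains the user's
responsibility.

## 6. Validation problem sizes

The package's own calibration experiments (in `tests/testthat/`) use
sizes chosen to exercise the study design while keeping the suite quick:
count structure at the design's colony sizes (4/10/8/7 and 5/10 birds,
giving 310 within-population ordered pairs; 10 + 8 tutees giving 18
tutor–tutee pairs); segmentation round trips over 20 rendered songs of 10
syllables; dispersion recovery over 20 replicates of three populations of
10 birds × 100 syllables at dispersion 1.0/1.5/2.0; and the
likelihood-ratio test's type-I error over 500 simulated null tables (3
populations × 10 birds with non-zero bird effects — the null of the model
as used). The trimmed-clustering oracle enumerates all discard sets on
instances of up to 12 points, where exhaustive search is exact.

## 7. Known limitations

* K-L values saturate near `log(1/ε)` for non-overlapping repertoires;
  comparisons among *highly* dissimilar pairs compress there.
* The mixed model assumes homoscedastic residuals across populations; the
  residuals/QQ methods are provided for checking, not enforced.
* The fixed-effect LRT relies on the χ² asymptotics in the number of
  birds, which is adequate at ~10 birds per population (verified by the
  type-I calibration) but should not be pushed to very small colonies.
* Segmentation assumes song well above the noise floor with stable
  per-bird levels; automatic threshold suggestion is a convenience, not a
  replacement for per-bird inspection.
* The trimmed filter clusters duration by default; pathological noise
  that mimics song durations requires adding feature columns to
  `trim_config()`.
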