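---
title: "Methods: speech rhythm, theta-band auditory-motor coupling, and comprehension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speech rhythm, theta-band auditory-motor coupling, and comprehension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Natural speech carries a quasi-periodic rhythm at the syllabic scale
(roughly 4-8 syllables per second in comfortable speech), and auditory
cortex theta oscillations (4-8 Hz) are thought to align to it. Speech-motor
regions (inferior precentral gyrus, inferior frontal gyrus, supplementary
motor area) are believed to exchange temporal predictions with auditory
cortex (posterior superior temporal gyrus) in the same band. This package
implements, as reusable and testable components, the analysis chain that
relates three quantities per sentence:

1. **Periodicity** of the syllable-nucleus train — how regular the
   inter-nucleus intervals are;
2. **Auditory-motor coupling** — theta-band statistical dependence between
   the two regions' source time courses;
3. **Comprehension** — word-overlap accuracy of a verbal repetition.

Because the real MEG/behavioral dataset is large and external, the package
ships a first-class synthetic-data module that generates all three layers
with known ground truth, so every stage of the chain is validated end to
end at desk scale.

## Periodicity: MAD of inter-nucleus intervals

For each sentence the syllable-nucleus times \(t_1 < \dots < t_k\) give
intervals \(\Delta_i = t_{i+1} - t_i\). Periodicity is quantified as the
median absolute deviation

\[\mathrm{MAD} = c \cdot \mathrm{median}_i\,
  \lvert \Delta_i - \mathrm{median}(\Delta)\rvert,\]

robust to outlier intervals. Larger MAD means less periodic timing. The
scale constant \(c\) defaults to 1.4826 (the Gaussian consistency constant
of `stats::mad`, the computation environment's default); whether the
original computation used the constant is not observable from reported
values, so `interval_mad(values, scale_constant = 1)` provides the unscaled
convention.

Syllabic rate and periodicity are naturally confounded (faster speech is
more periodic), so the analysis uses **residual MAD**: within each rate
condition, MAD is regressed by OLS on the empirical per-sentence rate
(nuclei per second over the train's span) and the residuals are kept. We
chose the empirical rate as the regressor because the condition label is
constant within a group, under which "fitting models per rate group" would
collapse to demeaning; that fallback is available as `mode = "demean"`.
OLS residuals are exactly mean-zero and rate-orthogonal per group, which
the tests assert to numerical precision.

`detect_nuclei()` is deliberately a *simplified* intensity-peak picker (a
smoothed envelope, greedy maxima under a 40 ms refractory interval, and a
2 dB flanking-dip requirement), not a reimplementation of voicedness-based
Praat scripts; it is validated against envelopes rendered from generated
trains (>= 95% recovery within 20 ms at 20 dB SNR) rather than against real
speech. Praat TextGrid point tiers and CSV nuclei files are the supported
real-data entry points.

## Coupling: Gaussian-copula mutual information

The coupling statistic between two multichannel region signals is mutual
information estimated by the Gaussian-copula method: each marginal is rank
transformed to normal scores (`copula_normalize`, ties broken by stable
input order), and MI is computed from Gaussian entropies of the joint
covariance (`mi_gg`), in bits, with the analytic digamma bias terms
subtracted. The estimator is a lower bound on true MI, exactly invariant to
strictly monotone marginal transforms, and is checked in the tests against
the closed form \(-\tfrac12\log_2(1-r^2)\) for bivariate Gaussians.

The front end mirrors source-space practice:

* **PCA denoising** per trial and parcel (`pca_reduce`), keeping the first
  3 components (about 90% of variance in typical parcel data).
* **Band-limited phase** (`band_phase`): a zero-phase FFT band filter
  (flat passband, raised-cosine edges) combined with the analytic signal,
  then per-sample unit normalization so only phase enters the estimator.
  We chose the FFT route over an IIR filter because a 2 Hz-wide order-4
  Butterworth at 100 Hz sampling has pole radius ~0.98 and long transients,
  while the FFT filter is exactly zero-phase and fast inside the surrogate
  loop. Samples within `1/bw` seconds of the epoch edges are flagged and
  excluded. The frequency grid (default theta centres 4-8 Hz in 1 Hz steps,
  2 Hz bandwidth) and the filter-Hilbert style front end are package
  choices; whether amplitude should be retained is genuinely open, so an
  amplitude-retaining mode sits behind `keep_amplitude`.
* **Delay scan** (`delay_gcmi`): the motor series is shifted against the
  auditory series over 0-300 ms in 10 ms steps; shifts are implemented by
  truncation, never circular wrap (wrap-around creates a seam that biases
  MI), and every delay uses the sample count of the largest delay so values
  are comparable across the grid. The headline value is extracted at 50 ms,
  where delay-resolved coupling plateaus.

## Surrogate normalization

Raw GCMI depends on epoch length, dimensionality, and autocorrelation, so
observed values are standardized against a within-trial null: the motor
region's series is cut into contiguous segments of 80% of the syllabic
cycle (160.0 ms at 5 Syl/s, 72.72 ms at 11 Syl/s), the segments are
permuted uniformly (N = 500 by default), and the statistic is recomputed
per iteration; then

\[z = \frac{\mathrm{GCMI}_{\mathrm{obs}} - \mathrm{mean(surrogates)}}
          {\mathrm{sd(surrogates)}}.\]

Two choices here deserve emphasis:

* **Shuffling happens on the raw (PCA-reduced) series, before the band
  filter.** Re-filtering after shuffling smooths the segment seams and
  restores the band's coherence time, so the surrogate statistic is
  exchangeable with the observed one under independence. Shuffling the
  phase series directly leaves surrogates with systematically broken
  autocorrelation and miscalibrates the z (we verified this empirically;
  with the raw-series convention the null z has mean ~0 and a ~5%
  exceedance rate at |z| > 1.96, which the acceptance tests assert).
* **Sign convention**: the z is (observed - surrogate mean)/sd, under which
  stronger-than-chance coupling is positive. A literal reading of the
  normalization as "subtracting the true values from the surrogate mean"
  would flip the sign of every reported positive coupling effect, so the
  convention above is used and recorded as an open question.
* Only the motor region is shuffled by default (one-sided shuffling already
  destroys cross-regional dependence); `shuffle_both = TRUE` provides the
  symmetric variant, since the original description is ambiguous.

Surrogate RNG streams are derived per (subject, trial, ROI pair, frequency)
from the master seed, so results are bit-reproducible and independent of
execution order. Trials too short to hold two segments at their rate's
segment length are skipped with a logged reason, not padded — padding would
inject artificial dependence.

## Comprehension scoring

Verbal recalls are scored as Ratcliff-Obershelp similarity between
tokenized reference and response: recursively find the longest matching
contiguous block, recurse on both flanks, and report \(2M/T\) (matched
tokens over total tokens). Ties in the longest block go to the earliest
start in the reference, then in the response, making scores deterministic;
no junk heuristics are applied because sentences are short and heuristics
change scores silently. Tokenization (lowercase, punctuation stripped,
whitespace split) is declared rather than inferred — the original
normalization is unreported. The scorer never exceeds the
dynamic-programming \(2\cdot\mathrm{LCS}/T\) bound, which the tests verify
exhaustively on short token lists.

## Statistical models

Responses bounded in \([0,1]\) (comprehension scores; min-max normalized
coupling z) are modelled with beta regression: \(y_i \sim
\mathrm{Beta}(\mu_i\phi, (1-\mu_i)\phi)\) with \(\mathrm{logit}(\mu_i) =
x_i^\top\beta\) and constant precision \(\phi\). Boundary values are nudged
inward by \(\varepsilon = \mathrm{median}(y)/n\) (full-vector median by
default; whether the original rule used per-condition medians is unstated,
so a `group` argument provides that variant). The likelihood is maximized
by BFGS on \((\beta, \log\phi)\) with an analytic gradient, started from a
least-squares fit on \(\mathrm{logit}(y)\); a monotone safeguard keeps the
starting values if the optimizer ever fails to improve. Rate can enter as
an orthonormal polynomial (degree <= 3) via `ortho_poly()` or
`stats::poly()` in formulas.

**Random effects are intentionally not estimated.** Crossed-random-effect
beta GLMMs need Laplace/AGQ machinery out of proportion to this package,
and conditional coefficients are not directly comparable to marginal ones
on the logit scale. The supported inference path is the fixed-effects ML
fit plus a cluster bootstrap over subjects (`cluster_bootstrap`), and
parameter-recovery tests default to `subject_sd = 0`. Likewise the reported
pseudo-R² values (squared correlation of logit(y) with the linear
predictor, and a likelihood-ratio variant) are not comparable to
marginal/conditional GLMM R². Simple slopes of periodicity at chosen rate
levels and their pairwise differences come from exact linear-combination
contrasts of the fitted coefficients (`slope_contrast`), with
delta-method SEs and optional bootstrap percentile intervals; multiple
comparisons are corrected by Benjamini-Hochberg FDR (`bh_fdr`).

## The synthetic-data generator

The generator emulates the study's three data layers under the
experimental conditions (rate conditions 5, 11, 14, 16, 17.5 Syl/s):

* **Syllable trains**: intervals \(1/\mathrm{rate} + N(0,
  \sigma_{\mathrm{jitter}})\), truncated below at 10% of the nominal
  interval so times stay strictly increasing. Per-condition jitter follows
  a coefficient of variation declining with rate
  (\(0.18\,(5/\mathrm{rate})^{0.35}\), log-normal sentence-to-sentence
  dispersion 0.5), reflecting that faster natural speech is more periodic;
  the published per-condition MAD distributions are graphical only, so
  these values are coverage choices, not fitted ones.
* **Neural trials**: two regions x 8 channels at 100 Hz; each channel is
  unit-variance \(1/f\) noise (spectral shaping of white noise — exact
  exponent control at \(O(n\log n)\)) plus a shared narrowband theta
  component (6 Hz, 4 Hz bandwidth — the full theta width) weighted randomly
  across channels, giving the characteristic 1/f spectrum with a theta
  bump. The motor region's theta component is the auditory one delayed by
  50 ms and scaled by the coupling strength, mixed with an independent
  theta component so total power is constant; coupling 0 yields fully
  independent regions. Coupling is injected only into the theta component
  (the analysed band); `broadband_coupling = TRUE` shares the 1/f
  background too. Epochs default to 6 s — a realistic slow-condition
  sentence epoch, and long enough that the theta-averaged delay scan
  localizes the lag to one 10 ms grid step.
* **Behavior**: beta-distributed scores from a logit-linear model with
  optional subject intercepts (SD 0.3 by default).

`simulate_cohort()` ties the layers together: true coupling strength rises
with syllabic rate and with the sentence's within-condition aperiodicity
(its standard-normal log-jitter deviation — the decorrelated quantity that
residual MAD estimates), while generated comprehension falls with rate,
rises with residual MAD, and carries a negative rate x periodicity
interaction. The default generating coefficients were fixed once, at the
design stage, to produce effects a 57-subject study would plausibly carry
down to an 80-trial desk-scale cohort (e.g. comprehension near 85% at
5 Syl/s falling to ~30% at 17.5 Syl/s; coupling strength 0.33-0.57 across
rates); a design-stage power check confirmed the four effect directions are
recoverable, and the defaults have not been revisited since.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen for a laptop-class machine:
GCMI closed-form agreement at n = 50,000; null-calibration over 200
uncoupled trials with 200 surrogates each; lag recovery over 50 coupled
trials; beta-regression recovery at n = 3,000 (type-I over 300 replicates
of n = 300); and 20 end-to-end cohorts of 80 trials (16 per rate condition,
40 surrogates per trial x frequency). `scripts/acceptance.R` recomputes the
same quantities at moderately reduced replicate counts and records the size
used alongside each value.

Degenerate inputs are explicit errors, not silent results: constant columns
in the copula step, singular covariance blocks in `mi_gg` (the offending
block is named), constant vectors in min-max normalization, all-zero
responses in the boundary adjustment, epochs shorter than three cycles in
`band_phase`, and non-integer sample shifts in the delay scan.

## Known limitations

* The synthetic generator does not emulate sensor-space MEG, head models,
  beamforming, artifacts, or real acoustic waveforms; passing tests show
  the *pipeline* is correct and calibrated, not that real data meet its
  assumptions.
* The GCMI bias correction assumes independent samples; narrowband phase
  series are strongly autocorrelated, so raw bias-corrected values on
  short epochs remain positively biased. All inference therefore goes
  through the surrogate z, which shares the autocorrelation between
  observed and null. Independence sanity checks on the generator
  accordingly thin samples beyond the band's coherence time.
* Fixed-effects-plus-bootstrap inference attenuates nothing under
  `subject_sd = 0` but is conservative, and coefficients are marginal, not
  conditional.
* The Ratcliff-Obershelp greedy recursion can fall below the LCS optimum on
  adversarial orderings; it is the field's standard scorer and is kept as
  specified, with the bound documented and tested.
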