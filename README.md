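# rhythmcoupling

Speech rhythm periodicity, theta-band auditory–motor coupling, and
comprehension — an R toolkit for the analysis chain that links the three.

## Who this is for

Researchers in auditory cognitive neuroscience who have, per sentence/trial:

* syllable-nucleus timings (from a CSV, a Praat TextGrid point tier, or
  detected from a PCM WAV amplitude envelope),
* source-localized region time series (samples × voxels at a known sampling
  rate; e.g. pSTG and a speech-motor parcel),
* verbal-recall transcripts and reference sentences,

and who want to quantify how syllabic-level periodicity and rate relate to
theta-band (4–8 Hz) auditory–motor coupling and comprehension.

## What it computes

**Periodicity.** For intervals Δᵢ between successive syllable nuclei,
`interval_mad()` computes MAD = c·median|Δᵢ − median(Δ)| (c = 1.4826 by
default). `residualize_mad()` removes, within each rate condition, the OLS
dependence of MAD on empirical syllabic rate, yielding a periodicity
measure decorrelated from rate.

**Coupling.** `mi_gg()` implements bias-corrected Gaussian-copula mutual
information, I(X;Y) = ½log₂[det Σₓ det Σ_y / det Σ_xy] on rank-Gaussianized
marginals — a robust lower-bound MI estimator. The pipeline around it:
per-trial PCA denoising to 3 components (`pca_reduce`), zero-phase
band-limited phase extraction (`band_phase`), a 0–300 ms delay scan
(`delay_gcmi`), and surrogate normalization: segments of 80% of the
syllabic cycle are shuffled (N = 500 by default) and
z = (GCMI_obs − mean(surr))/sd(surr) (`segment_shuffle`, `surrogate_z`,
`run_trial_coupling`).

**Comprehension.** `sequence_similarity()` scores recalls as
Ratcliff–Obershelp word-sequence overlap, 2M/T (matched tokens over total
tokens).

**Statistics.** `beta_regression_fit()` fits beta regressions with logit
link by maximum likelihood (boundary handling via `boundary_adjust()`,
ε = median(y)/n; GCMI responses via `minmax_normalize()`), with
`cluster_bootstrap()` for subject-clustered uncertainty, `slope_contrast()`
for simple slopes at chosen rate levels, polynomial rate terms
(`ortho_poly`), and `bh_fdr()` for FDR correction.

**Synthetic ground truth.** `gen_syllable_train()`, `gen_coupled_trial()`
(1/f background + lag-coupled narrowband theta), `gen_behavior()`
(beta-distributed scores from a logit-linear model), and
`simulate_cohort()` for a full joined study with known effect directions.

## Worked example

```r
library(rhythmcoupling)

# a 5 Syl/s sentence with 20 ms interval jitter
tr <- gen_syllable_train(syllable_train_spec(rate = 5, jitter_sd = 0.02,
                                             n_syllables = 20, seed = 7))
interval_mad(nuclei_intervals(tr))
#> [1] 0.0251

# one trial of two-region data, coupling 0.8 at a 50 ms lag
trial <- gen_coupled_trial(coupled_signal_spec(coupling_strength = 0.8,
                                               lag = 0.05, seed = 7))
res <- run_trial_coupling(trial, rate = 5,
                          pipeline_config(n_surrogates = 100, seed = 1))
res$z_table
#>   freq_hz gcmi_bits   z_gcmi
#> 1       4 0.9646798 1.636417
#> 2       5 1.2978535 3.408642
#> 3       6 1.1645147 3.060396
#> 4       7 0.9389401 1.278807
#> 5       8 1.3098818 3.883574
res$theta_mean_z
#> [1] 2.65

g <- subset(res$grid, freq_hz == 6)
g$delay_ms[which.max(g$gcmi_bits)]
#> [1] 50

sequence_similarity(tokenize("Der Hund lief schnell weg"),
                    tokenize("der Hund lief weg"))
#> [1] 0.8888889
```

The MAD (0.0251 s) sits near the generating jitter SD, as a consistent
scale estimator should. The per-frequency z-scores standardize observed
GCMI (in bits) against 100 segment-shuffle surrogates; `theta_mean_z`
averages them over 4–8 Hz, and values near 2.6 indicate coupling well
above chance. The delay scan peaks at the injected 50 ms lag. The
similarity 8/9 reflects one dropped token out of the nine tokens across
both sequences. Runtime for the coupling call is a few seconds (100
surrogates across five frequency bands).

## Layout

* `R/` — implementation (synthetic data, periodicity, scoring, GCMI,
  pipeline, statistics)
* `tests/testthat/` — unit, property, and end-to-end validation suites
* `vignettes/methods.Rmd` — the model and design choices in detail
* `scripts/acceptance.R` — the reproduction script above
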