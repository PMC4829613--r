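---
title: "Spontaneous-EEG normalization of laser-evoked magnitudes: methods and design"
author: "lepnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spontaneous-EEG normalization of laser-evoked magnitudes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepnorm)
```

## The problem

Cross-individual pain prediction trains a model on one group of people and
applies it to a new person, because the new person — often a patient who
cannot self-report — contributes no pain ratings. Its accuracy is limited by
inter-individual variability in evoked EEG magnitudes: skull thickness,
cortical geometry and electrode impedance scale one person's whole EEG up or
down relative to another's. Crucially, those factors scale the *spontaneous*
(pre-stimulus) EEG by the same amount as the *evoked* (post-stimulus)
response. The spontaneous magnitude distribution of an individual can
therefore serve as that individual's own yardstick, and it requires no
painful stimulation and no rating to estimate.

## The model

Each epoched trial is split at stimulus onset into a spontaneous segment
(−0.5 s to 0 s) and an evoked segment (0 s to +0.5 s), each reduced to a
root-mean-square magnitude,

$$\mathrm{RMS} = \sqrt{\tfrac{1}{K}\sum_{k=1}^{K} x_k^2},$$

written $RMS_S$ and $RMS_P$ for the two segments. For each individual, the
evoked magnitude of trial $i$ is normalized as a z-score of that
individual's spontaneous distribution,

$$nRMS_P(i) = \frac{RMS_P(i) - \mu(RMS_S)}{\sigma(RMS_S)},$$

with $\mu$ and $\sigma$ the mean and sample SD of $RMS_S$ over all of the
individual's trials. If an individual-specific factor $a > 0$ multiplies all
of a person's samples, it multiplies $RMS_P$, $\mu$ and $\sigma$ alike and
cancels exactly — this invariance, verified to $10^{-9}$ in the test suite,
is the entire mechanism of the method. Two alternative modes
(`divide_mean`, `subtract_mean`) are provided for comparison; only
`zscore` has the full invariance.

The rating–response relationship is characterized by two models fitted to
per-rating-level mean magnitudes of each individual: a single global line,
and a two-piecewise model with independent OLS lines below and above the
pinprick-pain threshold NRS = 4 (no continuity constraint — the two
segments are separate regressions, so the pooled MSE can never exceed the
global-line MSE). Prediction proceeds in two stages under
leave-one-individual-out cross-validation:

1. a one-feature Gaussian equal-variance LDA classifies each held-out trial
   as low pain (NRS ≤ 4) or high pain (NRS > 4); with equal priors the
   decision boundary is the midpoint of the class means, and with empirical
   priors (the default) it shifts by $s^2\log(\pi_L/\pi_H)/(m_H-m_L)$;
2. an OLS regression $R_i = \alpha\,\mathrm{feature}(i) + c$, trained on the
   training individuals' *true* high-pain trials, predicts ratings for
   held-out trials that stage 1 labelled high-pain (and, separately, for
   truly high-pain trials), scored by mean absolute error.

The held-out individual's normalization baseline uses only their
spontaneous segments, so no rating information from the held-out person is
ever consumed — the scenario the method is designed for.

## The synthetic cohort generator

No public dataset with this design exists, so the package ships a
first-class generator (`simulateCohort`) that emulates the study's
statistical structure and makes every downstream stage testable:

* **Design**: 34 individuals; laser energies from 1 J in 0.25 J steps up to
  a per-individual maximum drawn uniformly on 3.75–4.5 J (12–15 levels);
  10 pulses per level, i.e. 120–150 trials per individual, delivered in
  randomized order.
* **Shared scale factor**: each individual carries a log-normal factor
  $s_j$ (median 1, log-SD `scale_spread` = 0.4) multiplying *both* the
  spontaneous noise SD and the evoked amplitude. This single shared factor
  is what induces the cross-individual correlation between spontaneous and
  evoked magnitudes; setting `scale_spread = 0` removes it, and with it the
  correlation. We deliberately added no second, independent jitter on the
  baseline noise SD, so that disabling scale sharing cleanly collapses the
  correlation.
* **Background activity**: Gaussian white noise filtered with the same
  zero-phase 1–30 Hz Butterworth band-pass used in preprocessing (so the
  simulated and preprocessed spectra match), rescaled by the filter's noise
  gain so the process SD equals $s_j \times$ `noise_sd` (default 10 µV, a
  typical band-limited Cz magnitude). Each segment is cut from the middle
  of a padded filtered stretch, away from edge transients.
* **Evoked response**: a biphasic waveform — negative lobe peaking at
  200 ms, positive lobe at 350 ms, Gaussian-windowed, confined to the
  post-stimulus window — with peak amplitude
  $s_j\,(b + m\,\max(0, r - 4)) + \varepsilon$, floored at 0, where
  $b$ = `evoked_base` (8 µV), $m$ = `evoked_slope` (6 µV per NRS unit,
  with mild log-normal inter-individual jitter) and
  $\varepsilon \sim N(0, 2\,\mu V)$ is trial jitter. The amplitude, not the
  waveform shape, carries the signal; any smooth biphasic shape would do.
* **Ratings**: the latent rating is `sensitivity` × energy plus
  $N(0, 0.8)$ noise, rounded half-up and clipped to 0–10. Sensitivity is
  calibrated per individual so the maximum energy yields an expected rating
  of 8, mirroring the energy-calibration procedure the design stipulates.
  Integer ratings mean rating-0 trials occur at low energies; they are kept
  in the container, fall into no descriptive pain bin, and count as
  low-pain in classification.

What the generator does *not* emulate: habituation and inter-stimulus
effects, skin-temperature drift, attention, ocular artifacts, sex
differences, multi-channel structure. Consequently, passing tests show the
statistical machinery behaves as designed under the assumed generative
model; they do not certify performance on recorded EEG, where additional
variance sources (and a weaker evoked signal-to-noise ratio) compress the
raw-versus-normalized performance gap.

```{r cohort}
cfg <- cohortConfig(n_individuals = 6, sampling_rate = 250, seed = 42)
cohort <- simulateCohort(cfg)
cohort
```

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `scale_spread` | 0.4 | log units | inter-individual magnitude spread; 0 disables scale sharing |
| `noise_sd` | 10 | µV | baseline spontaneous SD before scaling |
| `evoked_base` | 8 | µV | evoked peak amplitude at/below the break |
| `evoked_slope` | 6 | µV / NRS | amplitude growth above the break |
| `trial_noise_sd` | 2 | µV | trial-to-trial amplitude jitter |
| `rating_noise_sd` | 0.8 | NRS | latent rating noise |
| `break_point` | 4 | NRS | low/high-pain boundary (pinprick threshold) |
| `sampling_rate` | 1000 | Hz | recording rate; 250 Hz is used in tests since every statistic operates on RMS and is rate-insensitive |

## Numerical and design choices

* **Filter realization**: order-4 Butterworth applied forward and backward
  (`signal::filtfilt`), i.e. zero phase and a squared magnitude response.
  The band contract is behavioural (passband gain within 5 % at mid-band,
  > 20 dB one octave out) rather than a specific realization.
* **Epoch convention**: half-open — the stimulus sample begins the
  post-stimulus segment. The pre-stimulus mean is subtracted from the whole
  epoch (baseline correction).
* **Baseline SD divisor**: sample SD ($n-1$). With 120–150 trials per
  individual the choice is numerically immaterial; the unbiased convention
  is standard.
* **MSE divisor**: $n$, not $n-p$ — the model comparison is descriptive,
  and the nested-model inequality (piecewise ≤ global) holds exactly under
  this convention.
* **Threshold search**: candidate cuts are midpoints of consecutive
  distinct sorted feature values plus one cut below the minimum and one
  above the maximum; accuracy ties break toward the smallest cut, making
  the output deterministic.
* **Variance comparison**: the raw and normalized parameters live on
  different scales (µV versus z-units), so alongside the variance-ratio
  F-test (two-sided p by doubling the one-tailed tail, capped at 1) the
  package reports coefficient-of-variation diagnostics, labelled as an
  extension.
* **Normality diagnostic**: one-sample KS test of the standardized sample
  against N(0,1) with parameters estimated from the data, which inflates
  p-values (Lilliefors effect). It is a recorded diagnostic; no trial is
  excluded on its outcome.
* **Stage-2 training set**: the training individuals' *true* high-pain
  trials (their labels are known at training time) — the
  information-maximizing choice. Predicted ratings are clipped to [0, 10].
* **LDA priors**: empirical class frequencies by default; `priors =
  "equal"` reproduces the exact midpoint boundary.
* **Degenerate inputs**: tiny cohorts complete with notices — analyses
  whose preconditions fail (fewer than 3 individuals for paired tests or
  variance ratios, bins with fewer than 2 represented individuals) are
  skipped or returned as NULL rather than aborting the pipeline.

## Problem sizes

Unit tests use 6-individual cohorts; cohort-level properties and the
acceptance script use the full design (34 individuals, ~4400 trials) at
250 Hz, which simulates in well under a minute. The generator's defaults
are the study conditions; nothing in the test suite tunes them.

## Worked pass through the pipeline

```{r pipeline}
records <- normalizeFeatures(buildFeatureTable(cohort))
head(records, 3)

anovaFByLevel(records, "rms_p")[, c("bin", "f_stat")]
```

A full run over every stage, writing delimited tables and a manifest:

```{r run, eval = FALSE}
res <- runPipeline(cohortConfig(sampling_rate = 250, seed = 1),
                   out_dir = "results")
res$prediction_summary
```

## Known limitations

* The two-stage predictor is deliberately one-dimensional; no
  multivariate or time-frequency features.
* The break point is fixed a priori at NRS = 4; the package does not
  estimate it.
* Synthetic evoked amplitudes are generated from the rating (not from the
  energy directly), so the generator encodes the flat-then-linear
  rating-response rule by construction; tests of that shape are tests of
  recovery, not of discovery.
* Real EEG contains artifacts the pipeline does not remove (ICA is out of
  scope); inputs are assumed preprocessed to the band-passed, epoched
  stage.
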