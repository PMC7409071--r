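---
title: "Quantifying circadian rest-activity disruption from tele-monitored wearable data"
author: "circarest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circadian rest-activity disruption from tele-monitored wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circarest)
```

## The problem

Cancer patients with a damped or fragmented circadian rest-activity rhythm
have worse symptoms, quality of life and survival than patients whose rest
is consolidated at night. A week of minute-resolution chest accelerometry
and skin temperature, a sleep diary, wrist light exposure, and salivary
cortisol and melatonin panels are enough to quantify that disruption and to
ask which of its correlates are actionable. `circarest` implements the full
analysis chain: data ingestion and off-body artifact removal, the dichotomy
index with its 97.5% classification threshold, a 3-state hidden Markov model
of rest-activity, least-squares spectral rhythm estimation, one- and
two-harmonic cosinor models, dim light melatonin onset (DLMO), and an AICc
all-subsets regression that screens candidate determinants of the index.

Because no raw recordings are distributable, the package ships a
first-class synthetic-cohort generator whose two phenotypes — *robust* and
*disrupted* — reproduce the qualitative contrasts the analysis is designed
to detect. Every stage is exercised end to end on those cohorts.

## The dichotomy index and its classification

For a window of recording, let the *out-of-bed* pool be every non-missing
minute outside the diary in-bed intervals and let $m$ be the median
activity count of that pool. The dichotomy index is

$$ I<O = 100 \times \frac{\#\{\text{in-bed minutes with count} < m\}}
{\#\{\text{non-missing in-bed minutes}\}} . $$

Three reading rules matter and are fixed here: the inequality is strict
(ties count as *not* below, so a subject whose nocturnal counts equal the
daytime median scores 0, not 100); a single pooled median is used per
window rather than per-day medians; and the classification over the first
72 h is *low* when $I<O \le 97.5$ and *high* above it, with the boundary
value itself classified low. In-bed intervals come from the diary when one
exists; otherwise the HMM rest windows stand in (flagged in the report).
Daytime naps remain in the out-of-bed pool. A bed-bound subject with a
zero out-of-bed median receives $I<O = 0$ with a degeneracy flag rather
than an arbitrary 100.

## The rest-activity hidden Markov model

Activity is aggregated to 5-min means and modelled on the
$\log(\text{count}+1)$ scale with Gaussian emissions in three states
ordered by location: inactive/rest (IA), moderately active (MA), highly
active (HA). Fitting is Baum–Welch EM to a relative log-likelihood change
of $10^{-6}$ (500 iterations cap), with 5 restarts — the first from evenly
spaced emission quantiles, the rest from randomly drawn data centres —
keeping the best likelihood. Emission SDs are floored at 0.05 on the log
scale: repeated values (e.g. all-zero bins) otherwise attract singular
zero-variance components. A state holding under 1% of posterior mass, or
whose location has collapsed onto a neighbour, triggers a flagged 2-state
refit.

The decoded path is global (Viterbi); per-bin posteriors come from the
forward–backward recursion; missing bins carry no emission term and their
posteriors are propagated through the chain. Derived quantifiers:

* **P1-1** — the IA→IA transition probability. Under the harmonic model
  (below) both the raw matrix entry and its 24-h time average are
  reported, since either reading is defensible.
* **Mid-levels** — back-transformed MA and HA emission locations in
  acc/min.
* **Center-of-rest** — circular mean clock time of IA bins weighted by IA
  posterior.
* **Rhythm index (RI)** — only the endpoints of this index are published
  (1 for a perfectly regular, fully certain daily rest block; 0 for no
  consistent rest). The definition used here, recorded in output metadata
  as `jaccard-posterior-v1`, is the mean Jaccard overlap of the IA bin
  sets on the 24-h clock grid over all day pairs, multiplied by the mean
  IA posterior of IA bins. It is exactly 1 at the published upper
  endpoint and indistinguishable from a shuffled-path null at the lower
  one, which is what the tests assert.
* **Sleep windows** — per noon-to-noon study day, the longest maximal IA
  run intersecting the nocturnal span 22:01–07:00 gives onset, wake and
  duration; the sample SD of durations across days is the
  *sleep-duration-variability* covariate of the determinant analysis.

With `harmonic = TRUE` the transition logits gain the first two harmonics
of the 24-h clock through a per-row multinomial-logit parameterisation, so
rows remain stochastic at every clock time; the M-step maximises the
expected complete-data log-likelihood of each row by BFGS. Modulating
transitions rather than emissions is what produces periodic state
probabilities while leaving the meaning of the states fixed.

All per-day quantities use a noon-to-noon day axis so nocturnal sleep is
never split across days. Timestamps are timezone-naive local clock times,
because every quantity of interest (acrophase, DLMO, night span) is a
clock-time quantity.

## Spectral estimation and r24

Hourly aggregated series (bins over 50% missing are dropped, then
linearly interpolated; over 30% interpolation attaches a warning) enter a
least-squares periodogram on a 6–30 h grid at 0.1 h steps: per period, a
sinusoid plus intercept is fitted and the spectrum value is the variance
explained. A least-squares periodogram rather than an FFT is used because
the series are short (168 points), interpolated, and the period grid is
continuous. The dominant period is the argmax (ties resolve to the
smaller period and are logged); amplitude and acrophase come from the fit
at that period.

90% confidence intervals are produced by residual resampling of the
dominant-period fit with full re-estimation over the grid per resample.
Significance compares the observed peak with the 95th percentile of peak
heights of scrambled surrogates, where the scramble is a random
permutation of the hourly values. A Fourier phase-randomized surrogate is
*not* suitable here: it preserves the power spectrum and with it the very
peak under test. Permutation assumes exchangeability, so a strongly
autocorrelated but arrhythmic series can still exceed the cutoff at some
arbitrary period — the temperature classifier therefore additionally
requires the dominant period to fall within $24 \pm 2$ h before calling a
rhythm circadian.

r24, the autocorrelation at 24-h lag, is the Pearson correlation of the
hourly series with itself shifted one day, computed on pairs with both
members present; the resolution (hourly, matching the spectral input) is
recorded in the output.

## Cosinor models

Chest temperature is smoothed by a centred 1-h moving average over
non-missing minutes (partial windows at the series boundaries are
excluded — a truncated window is not a centred average), collapsed to a
per-clock-minute averaged 24-h profile, and fitted with the two-harmonic
model

$$ y(t) = M + a_1 \sin\tfrac{2\pi t}{24} + b_1 \cos\tfrac{2\pi t}{24}
        + a_2 \sin\tfrac{2\pi t}{12} + b_2 \cos\tfrac{2\pi t}{12} + e(t). $$

The acrophase is the clock time at which the *full* fitted curve is
maximal on a 1-min grid, not the phase of the 24-h component alone. Note
that the moving average attenuates each harmonic by a known gain
(≈ 0.997 at 24 h, ≈ 0.988 at 12 h); the exactness tests compare against
the analytically attenuated coefficients.

Salivary cortisol is fitted on raw sample times with the single-24-h
harmonic model; panels need at least 9 of the 12 protocol samples over
2 days. Rhythm significance is the zero-amplitude F-test at
$\alpha = 0.05$.

Intervals: mesor and amplitude use *estimate ± t(df) × bootstrap SE*
(residual bootstrap on the temperature profile, case bootstrap over
cortisol samples, 500 seeded resamples by default). A plain percentile
interval for a non-negative amplitude from 12 samples measurably
undercovers (about 84–86% at nominal 90% in our simulations, against
about 92% for the t-form); the circular acrophase keeps the percentile
form, wrapped around the estimate.

A temperature rhythm is classified **physiologic** when the spectral peak
is significant, the dominant period is within $24 \pm 2$ h and the
cosinor acrophase falls in the closed nocturnal span 22:01–07:00 (both
boundaries inclusive, interval wrapping midnight); **abnormal** when
rhythmic but failing period or phase; **arrhythmic** when not
significant.

## DLMO

The individual melatonin threshold is mean + 2 sample SD (n−1) of the
earliest run of 3 consecutive samples that ends at or before the start of
the first sustained rise and whose coefficient of variation is below
0.33. "Sustained rise" is operationalised as two successive increases
totalling more than 25% of the run mean (both parameters are exposed in
the configuration). When no qualifying run exists the group-pooled
threshold — mean + 2 SD of all qualifying baseline values in that group,
one threshold per group — substitutes, and the pooled-vs-individual
agreement is validated by Pearson correlation on subjects with both.
DLMO is the linearly interpolated time of the first crossing from at or
below to above the threshold that stays above for all later samples;
first-sample-above and never-crossing panels return explicit undetermined
flags. Dim-light validity requires a mean below 50 lux over the 30 min
before each sample with no minute above 4× the cutoff; invalid flanking
samples flag, but do not void, a crossing.

## The synthetic cohort

`generate_subject()` draws, per subject: a diary (retiring/rising times
with phenotype-specific day-to-day SDs), a 5-min 3-state chain whose
transition rows are multiplicatively tilted towards IA inside the diary
bed span and towards MA/HA in the diurnal span, minute-level lognormal
counts per state (IA median near 0 acc/min), a two-harmonic temperature
rhythm with AR(1) noise (φ = 0.95, σ = 0.04 °C), a light series dim
after 19:00, a 12-sample cortisol panel on a 3-h daytime grid over two
days, and a 6-sample hourly evening melatonin panel from 19:00 following
baseline + fold × baseline × logistic rise with midpoint 30 min after the
true onset. The rise is deliberately sharp relative to the hourly
sampling (logistic scale 0.02 h): a shallow rise places the tiny
baseline-derived threshold deep in the convex foot of the curve, where
hourly linear interpolation reads the crossing 20–25 min early; a sharp
rise keeps the crossing adjacent to the midpoint so the true onset is
recoverable to within the sampling half-interval. Off-body spans (10–40 min, about one per day) decay the
temperature exponentially towards 21 °C and mask activity, retaining a
truth mask so span detection can be scored.

Phenotype defaults were calibrated once and frozen: robust subjects have
a strong in-bed tilt (night-tilt ≈ 4 on the log scale), regular diaries
(SD ≈ 0.3 h) and a nocturnal temperature acrophase; disrupted subjects
have a weak tilt (≈ 1.2), irregular diaries (SD ≈ 1.1–1.2 h), damped and
phase-scattered temperature rhythms, earlier melatonin onset and low
exercise propensity. Under these defaults the 72-h index exceeds 97.5%
for ≈ 99% of robust subjects and falls at or below it for ≈ 98% of
disrupted ones, and the cohort medians (≈ 99.6 vs ≈ 90.7%) sit close to
the published group medians. What the generator does *not* emulate:
activity count quantisation artifacts of real accelerometers, sensor
drift, diary misreporting, daytime napping structure, or covariate
correlations beyond phenotype — so passing tests demonstrate correctness
of the estimators under the stated model, not robustness to every
property of field recordings.

Two design points in the recovery experiments deserve a note. First, the
reference truth for HMM parameter recovery (`example_hmm_truth()`) uses
balanced state occupancy and emissions separated by several SDs: with an
absolute ±0.05 tolerance on transition entries, a state visited only a
few hundred times would fail that tolerance from sampling noise alone
even with the states known. Second, "recovering the predictor pair" in
the determinant-selection experiment means both true predictors appear
in the minimal-AICc model: with eight decoy candidates, demanding the
selected set equal the true pair exactly is unattainable by construction,
since minimal-AICc selection admits one spurious decoy in roughly three
quarters of replicates at any noise level.

## Two-sided Fisher tests

Software differs on what "two-sided" means for Fisher's exact test.
`fisher_exact_2x2()` implements both common definitions: `"minlike"`
(sum of probabilities of all tables no more likely than the observed,
the `fisher.test` convention, and the package default) and `"doubling"`
(twice the smaller one-sided tail, capped at 1). On 2×2 tables with
moderate counts the two can differ at the reported precision, so the
convention is always carried in the result.

## Problem sizes and reproducibility

The shipped analysis scripts and the acceptance study use a 58-subject,
7-day cohort; recovery studies use 100 replicates of 2016-bin series
(HMM), 200 noisy panels (bootstrap coverage), and 100 replicates each for
the spectral, DLMO and selection experiments, with cohort-level
resampling reduced to 100–200 draws per subject — sizes chosen so the
whole study re-runs interactively on a single core while leaving the
pass/fail margins wide. Every stochastic step takes an explicit seed, and
re-running any stage with unchanged inputs reproduces its outputs
exactly. The repository is organised as a workflow: the numbered scripts
under `analysis/` narrate the study (simulation, rest-activity,
rhythms/hormones, determinants) while every computation lives in the
package, where the test suite exercises it; those scripts plus the
exported functions are the package's interface, so there is no separate
command-line wrapper.

## Known limitations

* The RI definition and the harmonic transition parameterisation are
  this package's explicit substitutes for choices the original methods
  literature leaves unstated; both are flagged in output metadata.
* The permutation significance test assumes exchangeability; strongly
  autocorrelated arrhythmic series inflate low-frequency peaks (guarded
  by the period window in the classifier, but visible in raw
  `significant` flags).
* Temperature-profile bootstrap intervals are conditional on the
  averaged profile; smoothing-induced residual autocorrelation makes
  them slightly liberal.
* DLMO under hourly sampling is only determined to the sampling
  half-interval, and shallow physiological rises would bias the
  interpolated crossing early; sub-hourly sampling around the expected
  onset would remove both effects.
* A baseline run is rejected when an earlier sample lies well below the
  run level (a completed-rise plateau is not a baseline); panels whose
  rise finishes between the first two samples therefore fall back to
  the pooled threshold.
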