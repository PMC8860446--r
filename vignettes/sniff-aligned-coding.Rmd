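---
title: "Sniff-aligned analysis of rate and temporal odor codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sniff-aligned analysis of rate and temporal odor codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In awake rodents, odor sampling is organized by the respiration cycle
(~300 ms in the mouse). Cortical olfactory areas respond to odors within a
fraction of a single sniff, which raises two linked questions: what feature
of population activity carries odor *identity* (which odorant), and what
carries odor *intensity* (how concentrated)? A recurring answer in lateral
entorhinal cortex (LEC) and downstream hippocampal CA1 is a dissociation:
identity is carried by *which cells increase their firing rate* early after
odor inhalation (a rate/ensemble code), while intensity is carried by *when*
that early response peaks — peak latencies shift earlier and cells fire more
synchronously as concentration rises (a temporal code). Testing such claims
requires a fairly long chain of analysis: detecting inhalation onsets from a
nasal pressure signal, aligning trials to the first inhalation of odor,
estimating firing-rate time courses, classifying units as odor-activated,
measuring selectivity, assembling pseudopopulations for geometry and
decoding, extracting peak-time statistics, and scoring two-alternative
forced-choice (2AFC) behavior with signal-detection methods.

`sniffcode` implements that chain as a tested, seed-deterministic pipeline,
together with a synthetic-data generator that produces recordings with the
same statistical structure and *known ground truth*, so that every stage can
be validated by parameter recovery rather than by eye.

## The generator: what it emulates

`generator_config()` describes a passive odor-exposure session: 11 odors at
four relative concentrations (0.25, 0.33, 0.50, 1.00), 25 repetitions per
condition plus blank trials, ~300-ms respiration cycles with Gaussian
period jitter, and 1-s odor pulses triggered at the exhalation phase so that
the first inhalation of odor is a well-defined alignment point. Units come
in classes that differ in their temporal coding:

* **fan-like** — early responses (72 ms at full concentration) whose
  latency is concentration *invariant*;
* **pyramidal-like** — slightly later responses (78 ms) whose latency
  shifts *earlier* with concentration (−10 ms per doubling by default);
* **ca1-like** — later still (106 ms), latency-shifting but with no rate
  gain, mimicking a purely temporal intensity code;
* **untuned** — never odor-responsive; these units exercise the
  false-positive behavior of every test downstream.

Each responsive unit–odor pair fires as an inhomogeneous Poisson process:
baseline plus a Gaussian bump in time (the field does not provide a
parametric rate model for these responses; the Gaussian bump is a stand-in
chosen to produce smooth, peaked spike-density functions). Spike times are
sampled by thinning: candidates are drawn homogeneously at the rate
ceiling and retained with probability rate/ceiling, which is exact for any
bounded rate function and fully seed-controlled.

Concentration enters through log-linear ("per-doubling") laws anchored at
the highest concentration `c_max`:

* latency: `latency(c) = latency_mean + shift * log2(c / c_max)` — with a
  negative shift, responses move earlier as concentration rises;
* amplitude: `amplitude(c) = amplitude * gain^log2(c / c_max)` — a gain
  slightly above 1 gives the weak rate growth that makes intensity hard to
  decode from rates;
* across-cell latency dispersion:
  `sd(c) = latency_sd * shrink^log2(c / c_max)` — a shrink factor below 1
  makes the population fire more synchronously at higher concentrations,
  which is the substrate of the pairwise peak-time-difference analyses.

Anchoring at `c_max` was chosen because the class latencies are defined at
full concentration; it also makes between-class synchrony behave correctly
(a latency-shifting class converges onto a latency-invariant class from
above as concentration rises).

The response probability default (0.14 per unit–odor) was calibrated once
so that roughly half of the units respond to two or more of 11 odors,
the ensemble-overlap regime these analyses assume. The per-class unit
counts default to a desk-scale population (40 fan-like, 40 pyramidal-like,
20 untuned); all counts are configurable.

What the generator does **not** emulate: slow drift and unit instability,
bursting and refractoriness, correlated (shared) noise across units,
sniff-to-sniff state changes, adaptation across repetitions, and LFP.
Passing tests therefore show that the *analysis chain* is correct and
calibrated, not that real recordings satisfy its assumptions; in
particular, decoding accuracies on synthetic data with independent Poisson
noise should be read as upper bounds relative to data with shared noise.

## Event detection and alignment

Inhalation onsets are descending zero crossings of the Gaussian-smoothed
(5-ms SD), mean-subtracted pressure signal, accepted through a Schmitt
trigger whose hysteresis defaults to 10% of the signal SD; crossing times
are linearly interpolated between samples. A constant trace yields an empty
onset list rather than an error. Trials are aligned to the earliest onset
at or after odor onset (`t0`); trials whose odor pulse contains no
inhalation are flagged invalid, never silently dropped. All analysis
windows are half-open `[a, b)` in seconds, with `t = 0` at `t0`; the
default raster window `[-0.10, 0.30)` covers one sniff cycle.

Phototagged units (optogenetically identified cell classes) are detected
from LED pulse trains: a unit is tagged when its firing rate in the first
5 ms after pulse onset exceeds the 10-ms pre-pulse baseline (paired
one-sided t-test across pulses) *and* its first-spike latency SD is at most
2 ms. The 5-ms window follows standard phototagging practice; the 2-ms
jitter ceiling quantifies "consistent latency", which is otherwise a
qualitative criterion.

## Single-unit statistics

Spike-density functions (SDFs) convolve spike trains with a unit-area
Gaussian kernel (SD 10 ms) on a 1-ms grid and average across trials.
Kernel mass truncated at the window edges is *not* renormalized; rates
within roughly 3 SD of an edge are biased low, which is documented rather
than corrected because every comparison in the pipeline uses equal windows.

A unit–odor pair is *activated* when its mean windowed rate under odor
exceeds the blank-trial rate in a paired t-test, pairing trials by
presentation order. The test is one-sided (greater): "significantly
increased" is a directional hypothesis, and the one-sided form makes the
null calibration land at the nominal level (the acceptance suite verifies
~5% activated pairs at `alpha = 0.05` on amplitude-zero data). No
multiple-comparison correction is applied, mirroring the conventional
p < 0.05 per-pair criterion; an FDR layer can be added downstream if
wanted. The default early analysis window is `[0.050, 0.100)` s, where
odor-evoked firing peaks; the late window `[0.200, 0.300)` s captures the
tail of the cycle.

Lifetime sparseness over a unit's mean rate changes `r_j` across `N` odors
is

$$S = \frac{1 - (\sum_j r_j / N)^2 / (\sum_j r_j^2 / N)}{1 - 1/N},$$

with negative `r_j` clipped to zero first; `S = 1` for a perfectly
selective unit and `S = 0` for a uniform responder. An all-zero (clipped)
vector returns `NA` — the statistic is undefined there, and silently
returning 0 would fabricate a "nonselective" unit.

Rank-ordered peak maps use odd/even trial cross-validation: peak times are
estimated on odd-indexed trials and the displayed (row-normalized) matrix
comes from even-indexed trials, so a diagonal ridge cannot arise from
sorting noise.

## Population geometry and decoding

Pseudopopulations concatenate units across recordings and match trials
within condition by seeded random pairing (identity for a single
recording). PCA is fitted over units after per-unit mean centering,
*without* variance scaling: the rate-code claims rest on rate magnitudes,
and z-scoring would erase them. By default PCA observations are
per-condition trial-averaged SDF vectors in 1-ms bins (per-trial
observations are available); discriminability is the mean Euclidean
distance between condition trajectories in the first three components,
averaged (unweighted) over the requested condition pairs —
`condition_pairs()` selects identity pairs (same concentration, different
odor) or intensity pairs (same odor, different concentration).

Decoding uses a linear SVM in a one-vs-one scheme with repeated stratified
20% holdout; regularization constant 1 (no value is conventionally
reported for this analysis, and results are insensitive at these scales).
Features are per-unit mean rates in a window, or binary activation
indicators thresholded at the unit's *training-split* mean — fitting the
threshold on the training data only prevents test-set leakage, which is
easy to introduce silently in "binary ensemble" decoders. Classes are
balanced by seeded subsampling before each split. Sliding-window decoding
advances a 50-ms window in 5-ms steps by default.

## Temporal-code statistics

Peak time is the earliest time of the maximum of the trial-averaged SDF in
the search window (`[0, 0.300)` s by default); the earliest-tie rule makes
the estimate deterministic. Concentration trends are Spearman rank
correlations pooled over cell–odor pairs; because Spearman depends only on
ranks, log versus linear concentration scaling is irrelevant. A constant
variable yields an explicit `NA` ("undefined"), never a silent 0. Note
that with many pairs sharing each concentration value, rank ties bound
|rho| well below 1 even for perfectly monotone data — the per-pair
regression in `latency_shift_estimate()` is the quantitative
parameter-recovery tool, and the pooled rho is the effect-direction
summary.

Population synchrony is the mean absolute peak-time difference over
unordered pairs of responding cells, computed within odor and then
averaged across odors (pooling across odors would mix odor tuning into
what is meant as a synchrony measure; both modes are available).
`cross_population_synchrony()` restricts pairs to one cell from each of
two classes, the analysis that shows class-to-class synchronization as
concentration rises.

## Behavior

2AFC sessions are scored as cumulative-response signal detection: at each
time `t`, a trial has responded toward side A if its first lick was at or
before `t` and chose A; hit and false-alarm rates are cumulative
probabilities with unresponded-by-`t` trials kept in the denominators, and
`d'(t) = z(HR) - z(FAR)` with the log-linear correction (add 0.5 to counts,
1 to totals) so perfect rates stay finite. The discrimination onset is the
earliest time where `d'` across sessions beats a session-wise
label-shuffled null (paired t-test per step) for at least three
consecutive 25-ms steps; the run-length requirement suppresses isolated
significant bins, at the cost of a one-to-two-step delay in the reported
onset. LED (optogenetic silencing) effects are paired t-tests of percent
correct across sessions.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: hand
evaluations of the sparseness formula (including the negative-clipping
rule), closed-form Gaussian kernel peaks, brute-force pair enumeration for
distances and synchrony, numerically inverted normal quantiles for `d'`,
and binomial/permutation nulls for every significance machinery. The
calibration and recovery suites run the whole chain on generated sessions:
1100 unit–odor pairs for the activation-test null, 100 units per class and
25 trials per condition for latency-shift recovery (tolerance ±3 ms,
roughly a third of the SDF kernel SD), and the full default population for
the identity-versus-intensity decoding contrast. The synchrony-direction
check uses a construction with the latency dispersion programmed to shrink
strongly (SD 20 ms at full concentration, ×0.6 per doubling, response
latency centred mid-cycle and activation tested over the whole cycle so
that window selection does not truncate the latency distribution), because
the direction of the effect — not its size — is the property under test;
pairs must be significantly activated at every concentration to enter.
These sizes keep the default suite to a few minutes on one core while
leaving each assertion's noise floor well below its tolerance.

## Known limitations

* The onset detector assumes a single-channel, roughly zero-centred
  pressure signal; strong baseline drift would require detrending first.
* SDF edge bias (no kernel renormalization) makes rates within ~30 ms of
  window edges conservative.
* The generator's independent-Poisson noise ignores shared variability;
  decoder accuracies transfer to real data only qualitatively.
* `dprime_onset` calibrates its null by label shuffling within session;
  with very few trials per session the shuffled null is itself noisy and
  the onset estimate conservative.
* Dense tensors are held in memory; at 1-ms resolution with many hundreds
  of units, prefer windowed (single-bin) tensors for decoding.
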