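---
title: "Auditory frequency tagging with fpas: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory frequency tagging with fpas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpas)
```

# The paradigm

Fast periodic auditory stimulation (FPAS) presents short sounds
back-to-back at a fixed base rate (1/SOA; 4 Hz for 250-ms sounds, 7.8125 Hz
for 128-ms sounds), with a category of interest — human voices — occupying
every third slot, i.e. appearing at a *target* (oddball) rate of one third
of the base rate. A brain that discriminates the periodic category from the
other sounds *and* generalizes across its exemplars produces EEG power at
the target frequency and its harmonics; processing common to all sounds
appears at the base rate and its harmonics. Because the response is pinned
to known frequencies, detection reduces to asking whether specific spectral
bins stand out from their immediate neighbours — no condition subtraction is
needed.

`fpas` implements the full chain: stimulus engineering (equalization,
ramping, frequency-bin scrambling, sequence assembly), EEG preprocessing,
the frequency-domain statistics, electrode/ROI group inference, behavioral
d′ scoring, and a synthetic generator that produces EEG, audio and
behavioral data with recorded ground truth so that every stage can be
validated end to end.

# Stimulus engineering

All clips are RMS-equalized and given 10-ms linear onset/offset ramps.
Control stimuli are produced by **frequency-bin scrambling**
(`scrambleFrequencyBins`): the clip's FFT is partitioned into 200-Hz bins
and, within each bin, the component magnitudes and the phases are permuted
by two independent random permutations over the positive frequencies, after
which conjugate symmetry is enforced and the waveform is re-synthesized.
Independent permutations were chosen because they destroy residual
magnitude–phase alignment (and hence harmonic structure) more thoroughly
than a shared permutation, which is the stated purpose of the manipulation;
DC and the Nyquist component stay in place because real signals constrain
them. The per-bin power — hence the coarse spectral envelope — is preserved
*exactly* (a permutation cannot change a bin's power), which the tests
check to 1e-6 relative after the round trip through the inverse FFT.

The original temporal envelope is then re-imposed: the envelope is the
magnitude of the analytic signal smoothed by a zero-phase 50-Hz low-pass
(both cutoff and method are package choices; the operation is only
specified as "apply the original envelope"), and the scrambled waveform is
multiplied by the ratio of original to scrambled envelope with the
denominator floored at 0.1% of its maximum, then re-equalized to the input
RMS.

`buildSequence` concatenates equal-duration clips so that every third slot
is vocal, applies 2-s linear fade-in/out gain ramps, and embeds six
attentional targets (clips attenuated by an RMS factor of 12.5) at
pseudo-random non-fade positions with a minimum spacing of 2 s. Non-vocal
exemplars are drawn from a shuffled bag without immediate repetition,
refilling when exhausted; vocal slots are drawn uniformly. Each seed yields
a fresh, fully reproducible order.

## Acoustic profiling

Matched-set designs (voices vs instruments) are verified with three
estimators:

* `pitchEstimate` — normalized autocorrelation over the whole clip,
  searched between 75 and 600 Hz (the conventional speech range). The
  autocorrelation is evaluated at *fractional* lags exactly through its
  spectral representation, because the true period is rarely an integer
  number of samples and wide-band harmonic stacks have autocorrelation
  peaks only a couple of samples wide; the best peak's sub-multiple lags
  are preferred when they carry a peak of comparable height, which removes
  subharmonic (octave-down) errors. Aperiodic input is flagged unvoiced at
  a peak correlation below 0.3.
* `hnrEstimate` — HNR = 10·log10(r/(1−r)) dB, where r is the peak
  normalized autocorrelation: r estimates the periodic fraction of signal
  power, so r/(1−r) is the harmonic-to-noise power ratio. Values are
  capped at 60 dB where r approaches 1. On harmonic tones with noise mixed
  at a known power ratio the estimator is accurate to well under 2 dB.
* `spectralCentroid` — the amplitude-weighted mean frequency of the
  single-sided magnitude spectrum.

# Preprocessing

The chain mirrors standard steady-state practice: a zero-phase
(forward–backward) order-4 Butterworth band-pass at 0.1–100 Hz — zero-phase
because cross-channel phase must be preserved for topographies, at the cost
of a doubled effective magnitude order; an FFT multinotch at 50/100/150 Hz
with a 0.5-Hz width (bins inside the notch are zeroed with a one-bin linear
taper); downsampling to 256 Hz implemented as a zero-phase anti-alias
low-pass plus integer-factor decimation, which preserves in-band amplitudes
to well under 1% (polyphase resampling was measured at ~2.5% amplitude
error on a 10-Hz probe and rejected; non-integer ratios are therefore not
supported); epoching into 69-s windows (2 s before fade-in onset, 3 s after
fade-out); linear interpolation of bad channels from their k = 3–4 nearest
neighbours on the unit sphere; and average re-referencing.

**Integer-cycle resegmentation** trims each epoch to the longest duration
containing a whole number of target cycles (`integerCycleDuration`):
60 s exactly for the 4-Hz design (80 cycles of 1.333 Hz) and 59.904 s for
the 7.8125-Hz design (156 cycles of 2.6042 Hz). Cycle arithmetic is done
in seconds; the cut is realized as `round(duration × rate)` samples, since
59.904 s is not a whole number of samples at 256 Hz. With integer-cycle
epochs and no windowing, spectral leakage at the frequencies of interest
is identically zero, which is why the FFT uses a plain rectangular window.

# Frequency-domain statistics

Epochs are averaged in the time domain (non-phase-locked activity averages
out as 1/√N in amplitude), then transformed to single-sided amplitude
spectra scaled so a bin-centred sinusoid of amplitude A reads A at its bin;
the resolution is 1/duration = 0.0167 Hz for 60-s epochs.

Every statistic is local: a bin is compared against flanking "noise" bins,
which makes the test robust to the strong frequency dependence of EEG
noise (high below 1 Hz and in the 8–13 Hz alpha band). Two baseline
conventions coexist and are both exposed through `baselineConfig`:

* **min/max-dropped** (used for group-level z-scores): 12 candidate bins
  per side after skipping the bin adjacent to the target; each side's
  minimum and maximum are discarded, leaving 10 + 10 = 20 baseline bins.
  The description "20 bins, excluding the adjacent bins and the local
  minimum and maximum" does not balance arithmetically unless the extremes
  are dropped per side from a 12-bin candidate window, which is the
  reading implemented.
* **adjacent-only** (used for baseline subtraction, SNR spectra and the
  individual-subject test): 10 bins per side after skipping the adjacent
  bin.

The group decision statistic is z = (amplitude − baseline mean)/baseline
SD, thresholded at 2.32 (p < 0.01, one-tailed) for group-level harmonic
selection and 1.64 (p < 0.05) for single subjects.

## A caveat the tests make explicit

Because the baseline mean and SD are *estimated from 20 bins*, the z
statistic is not standard normal under the null: z/√(1 + 1/20) follows a
t distribution with roughly 19 degrees of freedom, so the true exceedance
probability of z > 2.32 is about 0.018 for Gaussian bins — and slightly
higher (≈ 0.021) for averaged Rayleigh-distributed amplitude bins, and
higher still (≈ 0.055) under the min/max-dropped convention, whose trimmed
SD underestimates the noise spread. The package implements the statistic
as the field defines it and the test suite asserts the *actual* null
exceedance bands derived from this analysis; the nominal 0.01 level should
be read as a labelling convention, not a calibrated false-positive rate.
Harmonic *selection* is affected only mildly (an extra noise-level harmonic
occasionally enters the sum, which adds ≈ 0 after baseline subtraction).

## Quantification

The response is quantified by **baseline-subtracted amplitudes summed over
the significant harmonics** (`significantHarmonics`, `harmonicTopography`):
harmonics of the target frequency are walked in order, skipping any
frequency that is an integer multiple of the base rate (where the oddball
response is masked by the common response), and the walk stops at the first
retained harmonic whose z fails the threshold ("consecutive significant
harmonics"). Channel pooling for the selection step is the mean across
channels of the grand-averaged spectrum — the simplest reading of "pooled
all channels together". Summing baseline-subtracted bins means
noise-level harmonics contribute ≈ 0 on average, so over-inclusive
harmonic sets are harmless.

Baseline-subtracted amplitudes systematically *underestimate* the injected
amplitude when the noise floor is non-negligible: the measured peak is
|A + n| ≈ A for A ≫ σ, yet the subtraction removes the full floor mean
E|n|. The recovery tests therefore operate in the regime the quantification
assumes (per-harmonic z > 10, reached with 16 averaged sequences in the
synthetic cohort), where the residual bias is below 5%.

The **individual-subject test** (`individualSignificance`) chunks 23-bin
windows centred on each group-significant harmonic from the channel-pooled
spectrum, sums them element-wise, and z-scores the centre against the 20
flanking bins (excluding the two adjacent) — the response accumulates
linearly across windows while the noise grows as its square root.

**SNR spectra** divide each bin by its adjacent-only baseline mean; ROI
SNR at the target frequency grows as √N with the number of averaged
sequences, which the tests verify within 20%.

# Group and behavioral inference

Electrode-level inference uses one-tailed paired t tests per electrode
(standard > scrambled) with p-values multiplied by the number of electrodes
(Bonferroni; multiplication and alpha-division are equivalent at
threshold, and the multiplied form is emitted because it keeps one number
per electrode). One-sample and Welch tests accept either raw samples
(delegated to `stats::t.test`) or printed summary statistics (closed
forms), and Cohen's d for one-sample designs is mean/SD = t/√n. The
Mann–Whitney procedure reports both the U statistic and the rank-sum W
convention, since software conventions differ. The outlier rule excludes
values beyond 3 SD of the full-sample mean in a single pass — the
statistics are deliberately not recomputed after exclusion.

Behavioral sensitivity is d′ = Φ⁻¹(hit rate) − Φ⁻¹(false-alarm rate) under
the equal-variance Gaussian model. Extreme rates are made interior either
by clipping to [1/(2N), 1 − 1/(2N)] (default) or by the log-linear rule
(count + 0.5)/(N + 1). Exact enumeration over the binomial distribution of
hit/false-alarm counts (the oracle frozen into the tests) shows that at
n = 40/40 the clip rule inflates recovered d′ by ≈ +0.06 near d′ = 2 while
the log-linear rule is unbiased to ≈ −0.01 there; at d′ ≈ 4 *both* rules
compress the estimate (−0.08 clip, −0.22 log-linear) because perfect hit
counts dominate. Recovery claims are therefore made with the log-linear
rule in the regime where the enumeration shows it is unbiased.

# The synthetic generator

`simulateEpoch` builds an epoch as phase-locked sinusoids at chosen
harmonic multiples of the base and target rates (the target's default
multiples 1, 2, 4, 5 skip those coinciding with the base rate, where the
oddball response is unobservable) times per-channel topography weights,
plus Gaussian noise synthesized in the frequency domain with expected
amplitude `noiseScale · f^−exponent` per channel (independent channels)
and a Gaussian alpha bump at 8–13 Hz. `noiseScale` is calibrated in the
units of the single-epoch amplitude spectrum (µV at 1 Hz), so
signal-to-floor ratios can be read off directly.

Defaults are the study conditions: 4 Hz base / 1.333 Hz target, two base
harmonics and four target harmonics with geometrically decaying amplitudes
(0.6·0.7^k and 0.25·0.7^k µV — realistic steady-state magnitudes), target
topography focused on the right superior-temporal electrodes TP8h, CP6,
C6, T8 so that ROI code paths are exercised by name, 128 channels at
512 Hz, `noiseScale` 0.08 µV with exponent 0.7 and an 0.05-µV alpha bump —
giving a single-sequence ROI target SNR of ≈ 5 and a 13-to-16-of-16
individual detection regime comparable to real recordings.
`simulateCohort` adds truncated-normal multiplicative amplitude jitter
(SD 0.2) and per-subject phases, and emits a ledger of every subject's
true amplitudes for recovery scoring.

The generator reproduces the *statistical* structure the analysis assumes
— stationary 1/f + alpha Gaussian noise, perfectly periodic responses,
independent channels. It does not emulate artifacts (blinks, movement),
spatially correlated noise, volume-conduction topographies or non-
stationarity, so green recovery tests certify the analysis chain, not
robustness to real-world contamination.

Synthetic audio corpora pair formant-shaped harmonic complexes
(f0 ~ N(220, 7²) Hz, HNR ~ N(21, 2.5²) dB — the published voice set
statistics) with either instrument-like harmonic tones drawn from the
*same* f0/HNR distributions (`matched = TRUE`, making pitch/HNR group
tests null by construction while the spectral envelope still differs) or
inharmonic noise-bed clips with a high spectral centroid and no pitch
(`matched = FALSE`).

# Problem sizes used by tests and the acceptance script

Simulation-based checks run at 64 Hz sampling with 60-s epochs (the design
frequencies stay exact on this grid; all response and noise content lies
below 32 Hz), 16-subject cohorts, one epoch per condition for the
100-replicate contrast study and 16 epochs per subject for amplitude
recovery, 5000 simulated observers for d′ recovery, and ≥ 10⁴ spectral
bins for null calibration. These sizes were chosen so the full validation
runs comfortably on a laptop while keeping every Monte-Carlo margin well
clear of its threshold. For electrode-recovery scoring the injected target
topography uses a zero background (response strictly confined to the four
ROI electrodes), so "recovered" can be scored as exact set equality between
the injected and the Bonferroni-significant electrodes; the generator's
default keeps a small 0.15 background weight, which is the more realistic
spread.

# Known limitations

* The scrambling reapplies the envelope by ratio with a floored
  denominator; for clips with near-silent stretches the floor dominates
  and the local envelope match degrades.
* `welchT` from summaries reproduces printed t values only to input
  rounding (e.g. 1.58 vs a printed 1.56 when means/SDs are given to one
  decimal).
* The BDF writer quantizes to 1/256 µV over a ±32.8 mV physical range.
* d′ estimates at n = 40 compress above d′ ≈ 4 under any extreme-rate
  correction (see the enumeration above); comparisons between conditions
  whose true d′ both exceed 4 will be attenuated.
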