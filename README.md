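# fpas — fast periodic auditory stimulation analysis

`fpas` is an R package for **auditory frequency-tagging (oddball
steady-state) experiments**: paradigms in which short sounds are presented
at a fixed base rate (e.g. 4 Hz) with a category of interest — human
voices — embedded periodically at a sub-rate (every third sound,
1.333 Hz). A brain response at the sub-rate and its harmonics indexes
category discrimination-plus-generalization directly, without subtracting
conditions. The package serves EEG researchers who want to build such
stimulation sequences, preprocess the recordings, and quantify the
periodic responses with the field's spectral statistics.

## What it computes

For an epoch resegmented to a whole number of target cycles (so leakage at
the tagged frequencies is zero), the single-sided amplitude spectrum has
resolution 1/duration. Each bin *f* is scored against its local
neighbourhood:

- **z(f) = (A(f) − mean of 20 flanking bins) / SD of those bins**, the
  frequency-tagging significance statistic (group threshold z > 2.32,
  p < 0.01 one-tailed; individual threshold z > 1.64);
- **baseline-subtracted amplitude** A(f) − baseline mean, summed over the
  consecutive significant harmonics of the target rate (base-rate
  multiples excluded) to give the per-electrode response topography in µV;
- **SNR(f) = A(f) / baseline mean**, for visualization and for tracking
  the √N gain from averaging N stimulation sequences;
- an **individual-subject test** that sums 23-bin chunks centred on each
  group-level harmonic and z-scores the centre against 20 flanking bins;
- electrode-wise **paired contrasts with Bonferroni correction** over 128
  electrodes, ROI averages, Welch and one-sample t tests (raw or printed
  summary statistics), Spearman correlation, Mann–Whitney U, a 3-SD
  outlier rule, and **d′** for the voice-detection behavior.

Around this sit a stimulus-engineering module (RMS equalization, 10-ms
ramps, 200-Hz frequency-bin scrambling that preserves per-bin power while
destroying harmonicity, sequence assembly with attenuated attentional
targets), an EEG preprocessing chain (zero-phase 0.1–100 Hz Butterworth,
FFT multinotch at 50/100/150 Hz, decimation to 256 Hz, epoching,
neighbour interpolation, average reference), acoustic profiling (pitch,
HNR, spectral centroid) for matched stimulus sets, and a synthetic
EEG/audio/behavior generator with recorded ground truth.

## Worked example

Simulate a subject with the default ground truth (4 Hz base, 1.333 Hz
voice rate, response focused over right superior-temporal electrodes),
average four 60-s sequences, and quantify the voice-selective response:

```r
library(fpas)

labs <- defaultLayout()$label                      # 128-channel cap
gt   <- ssepGroundTruth(channels = labs)           # known ground truth
ep   <- averageEpochs(lapply(1:4, function(i)
          simulateEpoch(gt, duration = 60, rate = 64, epochSeed = i)))
sp   <- amplitudeSpectrum(ep)

hr <- significantHarmonics(sp, fundamental = 4/3, exclude = 4)
hr
#> HarmonicResponse at 1.333 Hz: 4/5 significant harmonics
#>   1.333 Hz (z=12.61*), 2.667 Hz (z=23.61*), 5.333 Hz (z=57.01*),
#>   6.667 Hz (z=32.78*), 9.333 Hz (z=0.56)

roiAverage(summedAmplitude(hr), roiVoice())
#> [1] 0.589
```

The walk over target harmonics finds the four injected harmonics
significant (their channel-pooled z-scores are printed; the star marks
z > 2.32) and stops at the first noise-level harmonic (9.333 Hz,
z = 0.56). Multiples of the 4-Hz base rate (4 and 8 Hz) were skipped
because the oddball response is masked there. The summed
baseline-subtracted amplitude averaged over the voice ROI (TP8h, CP6, C6,
T8) is 0.589 µV — the per-subject quantity used for group inference. The
same subject passes the individual-subject chunk test (z = 27.34 > 1.64),
and the ROI SNR at 1.333 Hz is ≈ 13.

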