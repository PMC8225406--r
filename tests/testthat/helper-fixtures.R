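# Shared fixtures, all built in code.

toneClip <- function(freq, rate = 16000, dur = 0.25, amp = 1,
                     category = "nonvocal", id = "tone") {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  audioClip(amp * sin(2 * pi * freq * t), rate, category, id)
}

harmonicClip <- function(f0, rate = 16000, dur = 0.25, nHarm = 15,
                         noiseSd = 0, seed = 1, category = "vocal",
                         id = "harm") {
  set.seed(seed)
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- 0
  for (k in seq_len(nHarm))
    if (k * f0 < rate / 2)
      x <- x + sin(2 * pi * k * f0 * t + runif(1, 0, 2 * pi)) / k^0.3
  if (noiseSd > 0) x <- x + rnorm(length(t), sd = noiseSd)
  audioClip(x, rate, category, id)
}

# pool of equal-length random clips for sequence assembly
clipPool <- function(nVocal, nNonvocal, rate = 8000, soa = 0.25, seed = 1) {
  set.seed(seed)
  n <- round(soa * rate)
  mk <- function(id, cat) audioClip(rnorm(n, sd = 0.1), rate, cat, id)
  list(vocal = lapply(seq_len(nVocal), function(i)
         mk(sprintf("v%02d", i), "vocal")),
       nonvocal = lapply(seq_len(nNonvocal), function(i)
         mk(sprintf("n%02d", i), "nonvocal")))
}

# small channel set with the voice-ROI labels present
testLabels <- function(n = 8) {
  stopifnot(n >= 4)
  c("TP8h", "CP6", "C6", "T8", "Cz", "Oz", "T7", "Pz")[seq_len(n)]
}

testTopo <- function(labels = testLabels(), focus = roiVoice(),
                     background = 0.15) {
  defaultTargetTopography(labels, focus = focus, background = background)
}

# ground truth on a small montage; noiseScale 0 gives the no-noise limit
testGroundTruth <- function(labels = testLabels(), noiseScale = 0.08,
                            alphaAmp = 0.05, targetAmps = 0.25 * 0.7^(0:3),
                            background = 0.15, ...) {
  ssepGroundTruth(channels = labels, targetAmps = targetAmps,
                  baseTopo = defaultBaseTopography(labels,
                                                   background = background),
                  targetTopo = testTopo(labels, background = background),
                  noiseScale = noiseScale, alphaAmp = alphaAmp, ...)
}

# amplitude spectrum object from a plain matrix (for hand-built cases)
specFromMatrix <- function(A, resolution = 0.1,
                           labels = paste0("ch", seq_len(nrow(A)))) {
  new("AmplitudeSpectrum", freqs = (seq_len(ncol(A)) - 1) * resolution,
      amplitude = A, resolution = resolution, channelLabels = labels)
}

# per-200-Hz-bin power of a waveform (independent oracle for scrambling)
binPower <- function(x, rate, binWidth = 200) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * rate / n
  lo <- seq(0, rate / 2 - binWidth, by = binWidth)
  vapply(lo, function(l) sum(P[f >= l & f < l + binWidth & f < rate / 2]),
         numeric(1))
}
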