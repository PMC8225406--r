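#' @include AllClasses.R stimgen.R layout.R
NULL

#' SSEPGroundTruth: known composition of a simulated steady-state epoch
#'
#' Everything the simulator injects: harmonic amplitudes and scalp
#' topographies for the base and target (oddball) responses, and the noise
#' model (1/f-shaped background plus an alpha-band bump). Harmonic phases
#' are drawn once from \code{phaseSeed} so the periodic components are
#' phase-locked across epochs while the noise is independent.
#'
#' @slot baseFreq Hz (default 4).
#' @slot targetFreq Hz (default baseFreq/3).
#' @slot baseAmps per-harmonic amplitudes of the base response (uV).
#' @slot targetAmps per-harmonic amplitudes of the target response (uV).
#' @slot baseMultiples,targetMultiples integer multiples of the respective
#'   fundamental carrying those amplitudes. The target default (1, 2, 4, 5)
#'   skips multiples coinciding with the base rate, where the oddball
#'   response is masked by the much larger common response.
#' @slot baseTopo,targetTopo named per-channel weights multiplying the
#'   amplitudes.
#' @slot noiseExponent 1/f slope of the noise amplitude spectrum.
#' @slot noiseScale expected noise spectral amplitude at 1 Hz for one epoch
#'   (uV).
#' @slot alphaAmp extra noise amplitude in the alpha band (uV).
#' @slot alphaBand Hz pair.
#' @slot phaseSeed integer seed fixing the harmonic phases.
#' @export
setClass("SSEPGroundTruth",
  representation(baseFreq = "numeric", targetFreq = "numeric",
                 baseAmps = "numeric", targetAmps = "numeric",
                 baseMultiples = "integer", targetMultiples = "integer",
                 baseTopo = "numeric", targetTopo = "numeric",
                 noiseExponent = "numeric", noiseScale = "numeric",
                 alphaAmp = "numeric", alphaBand = "numeric",
                 phaseSeed = "integer"))

setValidity("SSEPGroundTruth", function(object) {
  msg <- character()
  if (any(object@baseAmps < 0) || any(object@targetAmps < 0))
    msg <- c(msg, "harmonic amplitudes must be >= 0")
  if (length(object@baseMultiples) != length(object@baseAmps) ||
      length(object@targetMultiples) != length(object@targetAmps))
    msg <- c(msg, "one multiple per harmonic amplitude required")
  if (!identical(names(object@baseTopo), names(object@targetTopo)))
    msg <- c(msg, "base and target topographies must share channel names")
  if (!all(is.finite(object@baseTopo)) || !all(is.finite(object@targetTopo)))
    msg <- c(msg, "topography weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Default oddball-response topography
#'
#' Weight 1 on the right superior-temporal voice ROI (TP8h, CP6, C6, T8,
#' where available) and a small uniform background elsewhere, so ROI code
#' paths are exercised by name.
#'
#' @param labels channel labels.
#' @param focus labels carrying the response (default \code{roiVoice()}).
#' @param background weight elsewhere (default 0.15).
#' @return named numeric weights.
#' @export
defaultTargetTopography <- function(labels, focus = roiVoice(),
                                    background = 0.15) {
  w <- stats::setNames(rep(background, length(labels)), labels)
  w[intersect(focus, labels)] <- 1
  w
}

#' Default base-response topography (central/occipital peak)
#'
#' @param labels channel labels.
#' @param background weight off the peak (default 0.15).
#' @return named numeric weights.
#' @export
defaultBaseTopography <- function(labels, background = 0.15) {
  defaultTargetTopography(labels,
    focus = c("Cz", "CPz", "Pz", "POz", "Oz"), background = background)
}

#' Construct an SSEPGroundTruth
#'
#' Defaults emulate the study conditions: a 4 Hz base rate with the oddball
#' every third stimulus (1.333 Hz), two base harmonics and four target
#' harmonics with geometrically decaying amplitudes (ratio 0.7), the target
#' focused over right superior-temporal electrodes, and 1/f + alpha
#' background noise giving a single-epoch ROI SNR of roughly 3-4 at the
#' target frequency.
#'
#' @param channels channel labels (default: the shipped 128-channel
#'   layout).
#' @param baseFreq,targetFreq stimulation rates (Hz).
#' @param baseAmps,targetAmps harmonic amplitudes (uV).
#' @param baseTopo,targetTopo named per-channel weights.
#' @param noiseExponent,noiseScale,alphaAmp,alphaBand noise model (see
#'   class slots).
#' @param phaseSeed seed for the fixed harmonic phases.
#' @return an \linkS4class{SSEPGroundTruth}.
#' @export
ssepGroundTruth <- function(channels = defaultLayout()$label,
                            baseFreq = 4, targetFreq = baseFreq / 3,
                            baseAmps = 0.6 * 0.7^(0:1),
                            targetAmps = 0.25 * 0.7^(0:3),
                            baseMultiples = seq_along(baseAmps),
                            targetMultiples = c(1L, 2L, 4L, 5L,
                                                7L, 8L)[seq_along(targetAmps)],
                            baseTopo = defaultBaseTopography(channels),
                            targetTopo = defaultTargetTopography(channels),
                            noiseExponent = 0.7, noiseScale = 0.08,
                            alphaAmp = 0.05, alphaBand = c(8, 13),
                            phaseSeed = 1L) {
  new("SSEPGroundTruth", baseFreq = baseFreq, targetFreq = targetFreq,
      baseAmps = baseAmps, targetAmps = targetAmps,
      baseMultiples = as.integer(baseMultiples),
      targetMultiples = as.integer(targetMultiples),
      baseTopo = baseTopo, targetTopo = targetTopo,
      noiseExponent = noiseExponent, noiseScale = noiseScale,
      alphaAmp = alphaAmp, alphaBand = alphaBand,
      phaseSeed = as.integer(phaseSeed))
}

setMethod("show", "SSEPGroundTruth", function(object) {
  cat(sprintf("SSEPGroundTruth: base %.4g Hz (%d harmonics), target %.4g Hz (%d harmonics), %d channels\n",
              object@baseFreq, length(object@baseAmps), object@targetFreq,
              length(object@targetAmps), length(object@baseTopo)))
})

## expected single-epoch noise amplitude spectrum (uV) at frequencies f
.noiseAmplitude <- function(gt, f) {
  a <- gt@noiseScale * pmax(f, 0.1)^(-gt@noiseExponent)
  if (gt@alphaAmp > 0) {
    c0 <- mean(gt@alphaBand); s0 <- diff(gt@alphaBand) / 4
    a <- a + gt@alphaAmp * exp(-0.5 * ((f - c0) / s0)^2)
  }
  a
}

## multichannel noise whose expected single-sided amplitude spectrum is
## ampFun(f): complex Gaussian coefficients scaled per bin, then a real
## inverse FFT per channel
.shapedNoise <- function(nch, n, rate, ampFun) {
  hi <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  pos <- 2:hi
  np <- length(pos)
  f <- (pos - 1) * rate / n
  s <- ampFun(f) * n / (2 * sqrt(pi / 2))
  Z <- matrix(complex(real = stats::rnorm(np * nch),
                      imaginary = stats::rnorm(np * nch)),
              np, nch) * (s / sqrt(2))
  X <- matrix(0i, n, nch)
  X[pos, ] <- Z
  X[n - pos + 2L, ] <- Conj(Z)
  t(Re(stats::mvfft(X, inverse = TRUE) / n))
}

#' Simulate one steady-state EEG epoch
#'
#' Phase-locked sinusoids at the base and target harmonics (amplitudes and
#' topographies from the ground truth, phases fixed by \code{phaseSeed})
#' plus spectrally shaped Gaussian noise (amplitude proportional to
#' f^-exponent, plus an alpha-band bump), independent across channels and
#' epochs.
#'
#' @param gt an \linkS4class{SSEPGroundTruth}.
#' @param duration epoch duration in seconds; must be a whole number of
#'   target cycles.
#' @param rate sampling rate in Hz (default 512).
#' @param epochSeed optional seed for this epoch's noise; when \code{NULL}
#'   the current RNG stream is used.
#' @return an \linkS4class{Epoch} (channels = names of the topographies).
#' @export
simulateEpoch <- function(gt, duration = 60, rate = 512, epochSeed = NULL) {
  stopifnot(is(gt, "SSEPGroundTruth"))
  if (abs(duration * gt@targetFreq - round(duration * gt@targetFreq)) > 1e-6)
    stop("duration must contain a whole number of target cycles")
  n <- round(duration * rate)
  labs <- names(gt@baseTopo)
  nch <- length(labs)
  t <- (seq_len(n) - 1L) / rate

  ## fixed harmonic phases
  old <- .Random.seed.save(); set.seed(gt@phaseSeed)
  phiB <- stats::runif(length(gt@baseAmps), 0, 2 * pi)
  phiT <- stats::runif(length(gt@targetAmps), 0, 2 * pi)
  .Random.seed.restore(old)

  sigB <- numeric(n); sigT <- numeric(n)
  for (k in seq_along(gt@baseAmps))
    sigB <- sigB + gt@baseAmps[k] *
      sin(2 * pi * gt@baseMultiples[k] * gt@baseFreq * t + phiB[k])
  for (k in seq_along(gt@targetAmps))
    sigT <- sigT + gt@targetAmps[k] *
      sin(2 * pi * gt@targetMultiples[k] * gt@targetFreq * t + phiT[k])
  mat <- outer(gt@baseTopo, sigB) + outer(gt@targetTopo, sigT)

  if (gt@noiseScale > 0 || gt@alphaAmp > 0) {
    if (!is.null(epochSeed)) {
      old <- .Random.seed.save()
      on.exit(.Random.seed.restore(old), add = TRUE)
      set.seed(epochSeed)
    }
    mat <- mat + .shapedNoise(nch, n, rate, function(f) .noiseAmplitude(gt, f))
  }
  epoch(mat, rate, labs, t0 = 0)
}

#' Simulate a cohort with per-subject variability
#'
#' For every subject and condition, the condition's ground-truth target
#' amplitudes are scaled by a subject factor (truncated normal around 1)
#' and the harmonic phases are jittered, then \code{nEpochs} epochs are
#' simulated. The returned ledger records every subject's true amplitudes
#' for recovery scoring.
#'
#' @param conditions named list of \linkS4class{SSEPGroundTruth}.
#' @param nSubjects number of subjects (default 16).
#' @param nEpochs epochs per subject and condition (default 4).
#' @param duration,rate epoch parameters.
#' @param ampJitterSd SD of the multiplicative subject amplitude factor
#'   (default 0.2; factors are truncated at 0.1).
#' @param phaseJitterSd SD (radians) of per-subject phase offsets.
#' @param seed master seed; the whole cohort is reproducible.
#' @return list with \code{epochs[[subject]][[condition]]} (lists of
#'   \linkS4class{Epoch}) and \code{ledger} (data.frame: subject,
#'   condition, harmonic frequency, true amplitude).
#' @export
simulateCohort <- function(conditions, nSubjects = 16, nEpochs = 4,
                           duration = 60, rate = 512, ampJitterSd = 0.2,
                           phaseJitterSd = 0.2, seed = 1L) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  epochs <- vector("list", nSubjects)
  ledger <- list()
  for (s in seq_len(nSubjects)) {
    epochs[[s]] <- list()
    fac <- max(0.1, 1 + stats::rnorm(1, 0, ampJitterSd))
    subjPhaseSeed <- sample.int(.Machine$integer.max, 1)
    for (cn in names(conditions)) {
      gt <- conditions[[cn]]
      gts <- initialize(gt,
        targetAmps = gt@targetAmps * fac,
        phaseSeed = if (phaseJitterSd > 0) subjPhaseSeed else gt@phaseSeed)
      epochs[[s]][[cn]] <- lapply(seq_len(nEpochs), function(e)
        simulateEpoch(gts, duration, rate))
      if (length(gt@targetAmps))
        ledger[[length(ledger) + 1L]] <- data.frame(
          subject = s, condition = cn,
          harmonic = gt@targetFreq * gt@targetMultiples,
          trueAmp = gts@targetAmps)
    }
  }
  list(epochs = epochs, ledger = do.call(rbind, ledger))
}

## one harmonic-complex or noise clip with ramps and RMS equalization
.synthClip <- function(rate, duration, f0, hnrDb, envelope, id, category) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1L) / rate
  if (is.finite(f0)) {
    nh <- max(3L, min(30L, floor(rate / 2 / f0) - 1L))
    x <- numeric(n)
    for (k in seq_len(nh))
      x <- x + envelope(k * f0) * sin(2 * pi * k * f0 * t +
                                      stats::runif(1, 0, 2 * pi))
    sigP <- mean(x^2)
    noiseP <- sigP / 10^(hnrDb / 10)
    x <- x + stats::rnorm(n, sd = sqrt(noiseP))
  } else {
    ## inharmonic/noisy: a dominant noise bed with sparse random partials,
    ## aperiodic in the pitch range
    x <- stats::rnorm(n, sd = 1)
    for (f in stats::runif(8, 500, 5000))
      x <- x + 0.4 * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  clip <- audioClip(x, rate, category, id)
  applyRamps(rmsEqualize(clip, 0.1), 0.010)
}

#' Simulate a vocal / non-vocal audio corpus
#'
#' Vocal-like clips are harmonic complexes (f0 ~ N(220, 7^2) Hz) with a
#' formant-shaped spectral envelope and an HNR drawn from N(21, 2.5^2) dB.
#' With \code{matched = TRUE}, the non-vocal clips are instrument-like
#' harmonic tones whose f0 and HNR are drawn from the same distributions
#' (so pitch/HNR group comparisons are null by construction), differing
#' only in spectral envelope. With \code{matched = FALSE}, non-vocal clips
#' are inharmonic tone clusters over noise with a much higher spectral
#' centroid and no pitch.
#'
#' @param nVocal,nNonvocal clip counts.
#' @param matched match f0 and HNR distributions across categories?
#' @param seed RNG seed.
#' @param rate sampling rate (Hz, default 16000).
#' @param clipDuration seconds per clip (default 0.25).
#' @return list of \linkS4class{AudioClip} (vocal first).
#' @export
simulateAudioCorpus <- function(nVocal, nNonvocal, matched = FALSE,
                                seed = 1L, rate = 16000,
                                clipDuration = 0.25) {
  stopifnot(nVocal >= 1, nNonvocal >= 1)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  formant <- function(f)
    0.05 + exp(-0.5 * ((f - 500) / 150)^2) +
      0.7 * exp(-0.5 * ((f - 1500) / 180)^2) +
      0.4 * exp(-0.5 * ((f - 2500) / 250)^2)
  bright <- function(f) (f / 220)^(-0.5)
  out <- list()
  for (i in seq_len(nVocal))
    out[[length(out) + 1L]] <- .synthClip(
      rate, clipDuration, f0 = stats::rnorm(1, 220, 7),
      hnrDb = stats::rnorm(1, 21, 2.5), envelope = formant,
      id = sprintf("v%02d", i), category = "vocal")
  for (i in seq_len(nNonvocal)) {
    if (matched)
      out[[length(out) + 1L]] <- .synthClip(
        rate, clipDuration, f0 = stats::rnorm(1, 220, 7),
        hnrDb = stats::rnorm(1, 21, 2.5), envelope = bright,
        id = sprintf("n%02d", i), category = "nonvocal")
    else
      out[[length(out) + 1L]] <- .synthClip(
        rate, clipDuration, f0 = NA_real_, hnrDb = NA_real_,
        envelope = NULL, id = sprintf("n%02d", i), category = "nonvocal")
  }
  out
}

#' Simulate an equal-variance Gaussian observer
#'
#' Evidence on voice-absent trials ~ N(0, 1) and on voice-present trials
#' ~ N(d', 1); the observer answers "yes" when evidence exceeds
#' d'/2 + criterion (criterion 0 = unbiased).
#'
#' @param trueDprime the observer's sensitivity.
#' @param criterion response bias (default 0).
#' @param trials trial data.frame with a logical \code{voice_present}
#'   column.
#' @param seed RNG seed.
#' @return logical response vector ("yes" = voice heard).
#' @export
simulateObserver <- function(trueDprime, criterion = 0, trials, seed = 1L) {
  stopifnot(is.data.frame(trials), "voice_present" %in% names(trials))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  ev <- stats::rnorm(nrow(trials), mean = ifelse(trials$voice_present,
                                                 trueDprime, 0))
  ev > trueDprime / 2 + criterion
}
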