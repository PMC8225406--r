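#' @include AllClasses.R
NULL

#' Root-mean-square of a waveform
#'
#' @param x numeric waveform or an \linkS4class{AudioClip}.
#' @return scalar RMS.
#' @export
rms <- function(x) {
  if (is(x, "AudioClip")) x <- x@samples
  sqrt(mean(x^2))
}

.withSamples <- function(clip, samples) {
  initialize(clip, samples = as.numeric(samples))
}

#' Equalize a clip to a target RMS
#'
#' Rescales the waveform by a single factor so its root-mean-square equals
#' \code{targetRms}; used to equalize all stimuli in overall energy before
#' sequence assembly.
#'
#' @param clip an \linkS4class{AudioClip} with nonzero energy.
#' @param targetRms desired RMS (positive).
#' @return the rescaled clip.
#' @examples
#' clip <- audioClip(rnorm(1000), 8000)
#' rms(rmsEqualize(clip, 0.1))
#' @export
rmsEqualize <- function(clip, targetRms) {
  stopifnot(is(clip, "AudioClip"), targetRms > 0)
  r <- rms(clip)
  if (r == 0)
    stop("cannot RMS-equalize an all-zero clip")
  .withSamples(clip, clip@samples * (targetRms / r))
}

#' Apply onset/offset amplitude ramps
#'
#' Multiplies the first and last \code{ramp} seconds by a linear 0 to 1
#' (resp. 1 to 0) envelope, leaving the interior untouched; 10-ms ramps
#' prevent clicks at sound boundaries.
#'
#' @param clip an \linkS4class{AudioClip}.
#' @param ramp ramp duration in seconds; \code{2 * ramp} must not exceed the
#'   clip duration.
#' @return the ramped clip. The first and last samples are exactly zero.
#' @export
applyRamps <- function(clip, ramp = 0.010) {
  stopifnot(is(clip, "AudioClip"), ramp >= 0)
  n <- length(clip@samples)
  nr <- round(ramp * clip@rate)
  if (nr == 0) return(clip)
  if (2 * nr > n)
    stop("ramps longer than the clip: 2*ramp must be <= duration")
  env <- rep(1, n)
  up <- seq(0, 1, length.out = nr)
  env[seq_len(nr)] <- up
  env[n - seq_len(nr) + 1L] <- up
  .withSamples(clip, clip@samples * env)
}

#' Amplitude envelope of a clip
#'
#' Magnitude of the analytic signal (FFT Hilbert transform), smoothed with a
#' zero-phase low-pass Butterworth filter at \code{cutoff} and clamped to be
#' nonnegative. This is the envelope reapplied after frequency-bin
#' scrambling.
#'
#' @param clip an \linkS4class{AudioClip}.
#' @param cutoff smoothing low-pass cutoff in Hz (must be below Nyquist).
#' @return nonnegative numeric envelope, same length as the clip.
#' @export
extractEnvelope <- function(clip, cutoff = 50) {
  stopifnot(is(clip, "AudioClip"), cutoff > 0, cutoff < clip@rate / 2)
  x <- clip@samples
  n <- length(x)
  if (all(x == 0)) return(numeric(n))
  ## analytic signal: zero negative frequencies, double positive ones
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  bf <- signal::butter(4, cutoff / (clip@rate / 2), type = "low")
  env <- signal::filtfilt(bf, env)
  pmax(env, 0)
}

#' Scramble a clip within fixed-width frequency bins
#'
#' Takes the FFT of the waveform, partitions the positive frequencies into
#' bins of \code{binWidth} Hz, and within each bin applies two independent
#' random permutations: one to the component magnitudes and one to the
#' phases. Conjugate symmetry is then enforced so the inverse transform is
#' real; DC and Nyquist are left untouched. This preserves the per-bin power
#' (hence the coarse spectral content) while destroying harmonic structure.
#' When \code{applyEnvelope} is \code{TRUE}, the original clip's temporal
#' envelope is imposed on the scrambled waveform (ratio of envelopes with a
#' floored denominator) and the result is re-equalized to the input RMS.
#'
#' @param clip an \linkS4class{AudioClip}.
#' @param binWidth bin width in Hz (default 200); must be below Nyquist.
#' @param seed integer seed making the scramble reproducible.
#' @param applyEnvelope impose the original temporal envelope afterwards?
#'   Use \code{FALSE} to inspect the raw spectral scramble, whose per-bin
#'   power equals the input's exactly.
#' @param envelopeCutoff low-pass cutoff (Hz) for envelope extraction.
#' @return the scrambled \linkS4class{AudioClip}.
#' @examples
#' clip <- audioClip(sin(2 * pi * 1000 * seq(0, 0.25 - 1/16000, by = 1/16000)),
#'                   16000)
#' scr <- scrambleFrequencyBins(clip, binWidth = 200, seed = 1)
#' @export
scrambleFrequencyBins <- function(clip, binWidth = 200, seed = NULL,
                                  applyEnvelope = TRUE,
                                  envelopeCutoff = 50) {
  stopifnot(is(clip, "AudioClip"), binWidth > 0)
  rate <- clip@rate
  if (binWidth >= rate / 2)
    stop("binWidth must be smaller than the Nyquist frequency")
  x <- clip@samples
  n <- length(x)
  if (n / rate * binWidth < 2)
    stop("clip too short: need at least 2 Fourier components per bin")
  if (!is.null(seed)) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(seed)
  }
  X <- stats::fft(x)
  ## positive-frequency indices, excluding DC (1) and Nyquist (n/2+1 if even)
  hi <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  pos <- 2:hi
  f <- (pos - 1) * rate / n
  bin <- floor(f / binWidth)
  mag <- Mod(X[pos]); ph <- Arg(X[pos])
  for (b in unique(bin)) {
    i <- which(bin == b)
    if (length(i) > 1) {
      mag[i] <- mag[i][sample.int(length(i))]
      ph[i] <- ph[i][sample.int(length(i))]
    }
  }
  X[pos] <- mag * exp(1i * ph)
  X[n - pos + 2L] <- Conj(X[pos])
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  out <- .withSamples(clip, y)
  if (applyEnvelope) {
    envOrig <- extractEnvelope(clip, envelopeCutoff)
    envScr <- extractEnvelope(out, envelopeCutoff)
    floorv <- 1e-3 * max(envScr)
    y <- y * envOrig / pmax(envScr, floorv)
    out <- .withSamples(clip, y)
    r0 <- rms(clip)
    if (r0 > 0 && rms(out) > 0) out <- rmsEqualize(out, r0)
  }
  out
}

#' Attenuate a clip for use as an attentional target
#'
#' Divides the waveform so the output RMS equals the input RMS divided by
#' \code{factor}; sequence targets are played at a lower volume (factor
#' 12.5) and listeners respond to them in the orthogonal detection task.
#'
#' @param clip an \linkS4class{AudioClip}.
#' @param factor RMS attenuation factor (> 1; \code{1} is the identity).
#' @return the attenuated clip.
#' @export
attenuateTarget <- function(clip, factor = 12.5) {
  stopifnot(is(clip, "AudioClip"), factor >= 1)
  .withSamples(clip, clip@samples / factor)
}

## save/restore .Random.seed so seeded operations don't disturb the caller's
## RNG stream
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
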