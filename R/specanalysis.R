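#' @include AllClasses.R
NULL

#' Average epochs in the time domain
#'
#' Sample-wise mean across epochs. Responses phase-locked to the
#' stimulation add coherently while non-phase-locked EEG averages out
#' (noise power divided by the number of epochs).
#'
#' @param epochs list of \linkS4class{Epoch} with identical channels,
#'   length and rate.
#' @return the mean \linkS4class{Epoch}.
#' @export
averageEpochs <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  e1 <- epochs[[1]]
  for (ep in epochs) {
    if (!identical(dim(channelData(ep)), dim(channelData(e1))) ||
        samplingRate(ep) != samplingRate(e1) ||
        !identical(channelLabels(ep), channelLabels(e1)))
      stop("epochs must share channels, length and rate")
  }
  acc <- Reduce(`+`, lapply(epochs, channelData))
  initialize(e1, data = acc / length(epochs))
}

#' Single-sided amplitude spectrum of an epoch
#'
#' FFT per channel with single-sided scaling: a bin-centred sinusoid of
#' amplitude A yields spectral amplitude A at its bin. The frequency
#' resolution is 1/duration (0.0167 Hz for a 60-s epoch). No window is
#' applied: integer-cycle resegmentation makes leakage zero at the
#' frequencies of interest.
#'
#' @param ep an \linkS4class{Epoch}.
#' @return an \linkS4class{AmplitudeSpectrum} with bins from 0 Hz to the
#'   Nyquist frequency.
#' @export
amplitudeSpectrum <- function(ep) {
  stopifnot(is(ep, "Epoch"))
  mat <- channelData(ep)
  n <- ncol(mat)
  nb <- floor(n / 2) + 1L
  A <- t(Mod(stats::mvfft(t(mat)))[seq_len(nb), , drop = FALSE]) / n
  scale <- rep(2, nb)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nb] <- 1
  A <- sweep(A, 2L, scale, `*`)
  res <- samplingRate(ep) / n
  new("AmplitudeSpectrum", freqs = (seq_len(nb) - 1L) * res, amplitude = A,
      resolution = res, channelLabels = channelLabels(ep))
}

#' Pool channels of a spectrum
#'
#' Mean across channels, the pooling used before group-level harmonic
#' selection and the individual-subject test.
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @return a one-channel \linkS4class{AmplitudeSpectrum} labelled "pooled".
#' @export
poolChannels <- function(spec) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  new("AmplitudeSpectrum", freqs = spec@freqs,
      amplitude = matrix(colMeans(spec@amplitude), nrow = 1),
      resolution = spec@resolution, channelLabels = "pooled")
}

## per-side candidate offsets (positive; mirrored for the left side)
.candOffsets <- function(cfg) {
  extra <- if (cfg@dropExtremes == "minmax") 2L else 0L
  cfg@skipAdjacent + seq_len(cfg@nSide + extra)
}

## baseline mean/sd for every bin at once; NA where the window does not fit.
## Per side: running sum/sumsq/min/max over the candidate offsets, dropping
## each side's min and max in "minmax" mode so nSide bins per side remain.
.baselineAll <- function(A, cfg) {
  nb <- ncol(A); nc <- nrow(A)
  off <- .candOffsets(cfg)
  reach <- max(off)
  lo <- min(off)
  if (cfg@dropExtremes == "none") {
    ## contiguous candidate windows: O(1) per bin via cumulative sums
    cs1 <- cbind(0, t(apply(A, 1L, cumsum)))
    cs2 <- cbind(0, t(apply(A^2, 1L, cumsum)))
    winSum <- function(cs, from, to) {
      ## sum over columns (i+from)..(i+to) for every centre i, NA at edges
      out <- matrix(NA_real_, nc, nb)
      ctr <- seq_len(nb)
      ok <- ctr + from >= 1L & ctr + to <= nb
      out[, ok] <- cs[, ctr[ok] + to + 1L] - cs[, ctr[ok] + from]
      out
    }
    s1 <- winSum(cs1, lo, reach) + winSum(cs1, -reach, -lo)
    s2 <- winSum(cs2, lo, reach) + winSum(cs2, -reach, -lo)
  } else {
    sideStats <- function(sign) {
      s1 <- s2 <- matrix(0, nc, nb)
      mn <- matrix(Inf, nc, nb); mx <- matrix(-Inf, nc, nb)
      for (o in off) {
        idx <- seq_len(nb) + sign * o
        ok <- idx >= 1L & idx <= nb
        v <- matrix(NA_real_, nc, nb)
        v[, ok] <- A[, idx[ok], drop = FALSE]
        s1 <- s1 + v; s2 <- s2 + v^2
        mn <- pmin(mn, v); mx <- pmax(mx, v)
      }
      list(s1 = s1 - mn - mx, s2 = s2 - mn^2 - mx^2)
    }
    L <- sideStats(-1L); R <- sideStats(+1L)
    s1 <- L$s1 + R$s1
    s2 <- L$s2 + R$s2
  }
  nbl <- 2L * cfg@nSide
  m <- s1 / nbl
  v <- pmax(s2 - nbl * m^2, 0) / (nbl - 1L)
  ## invalidate edge bins where any candidate fell outside the grid
  bad <- c(seq_len(min(reach, nb)), (nb - reach + 1L):nb)
  bad <- unique(bad[bad >= 1L & bad <= nb])
  m[, bad] <- NA_real_; v[, bad] <- NA_real_
  list(mean = m, sd = sqrt(v))
}

## baseline mean/sd at selected bins only (sparse companion of .baselineAll)
.baselineBins <- function(A, bins, cfg) {
  nb <- ncol(A)
  off <- .candOffsets(cfg)
  reach <- max(off)
  m <- sdm <- matrix(NA_real_, nrow(A), length(bins))
  for (j in seq_along(bins)) {
    b <- bins[j]
    if (b - reach < 1L || b + reach > nb) next
    side <- function(sign) {
      v <- A[, b + sign * off, drop = FALSE]
      if (cfg@dropExtremes == "minmax")
        v <- t(apply(v, 1L, function(x) sort(x)[2:(length(x) - 1L)]))
      v
    }
    bl <- cbind(side(-1L), side(+1L))
    m[, j] <- rowMeans(bl)
    sdm[, j] <- apply(bl, 1L, stats::sd)
  }
  list(mean = m, sd = sdm)
}

.binIndex <- function(spec, freq) {
  idx <- as.integer(round(freq / spec@resolution)) + 1L
  if (idx < 1L || idx > length(spec@freqs) ||
      abs(spec@freqs[idx] - freq) > spec@resolution / 2 + 1e-9)
    stop(sprintf("frequency %.6g Hz is not on the bin grid", freq))
  idx
}

#' Local baseline of one spectral bin
#'
#' Mean and standard deviation of the flanking "noise" bins of a target
#' bin, as configured by a \linkS4class{BaselineConfig} (the bin itself and
#' its immediate neighbours are never part of their own baseline).
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @param bin bin index (1-based) or use \code{freq}.
#' @param cfg a \linkS4class{BaselineConfig}.
#' @param freq alternatively, the bin's frequency in Hz.
#' @return list with per-channel \code{mean} and \code{sd} (uV).
#' @export
localBaseline <- function(spec, bin = NULL, cfg = baselineConfig(),
                          freq = NULL) {
  stopifnot(is(spec, "AmplitudeSpectrum"), is(cfg, "BaselineConfig"))
  if (is.null(bin)) bin <- .binIndex(spec, freq)
  reach <- max(.candOffsets(cfg))
  nb <- ncol(spec@amplitude)
  if (bin - reach < 1L || bin + reach > nb)
    stop("bin too close to the spectrum edge for the baseline window")
  bl <- .baselineBins(spec@amplitude, bin, cfg)
  list(mean = bl$mean[, 1], sd = bl$sd[, 1])
}

#' z-score of a spectral bin against its local baseline
#'
#' z = (amplitude - baseline mean) / baseline SD, the significance
#' statistic of frequency tagging (z > 2.32 for p < 0.01 one-tailed at the
#' group level; z > 1.64 for p < 0.05 at the individual level).
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @param freq frequency in Hz (must lie on the bin grid within half a
#'   resolution step).
#' @param cfg a \linkS4class{BaselineConfig}; group-level selection uses
#'   \code{dropExtremes = "minmax"}.
#' @param pool pool channels (mean spectrum) before scoring?
#' @return per-channel z (a single value when pooled). A zero baseline SD
#'   yields \code{Inf}/\code{NaN}, flagged by a warning.
#' @export
zscoreAt <- function(spec, freq, cfg = baselineConfig(dropExtremes = "minmax"),
                     pool = FALSE) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  if (pool) spec <- poolChannels(spec)
  bin <- .binIndex(spec, freq)
  bl <- localBaseline(spec, bin, cfg)
  if (any(bl$sd == 0, na.rm = TRUE))
    warning("zero baseline SD: z is infinite/undefined at some channels")
  (spec@amplitude[, bin] - bl$mean) / bl$sd
}

#' z-score spectrum (all bins)
#'
#' Vectorized \code{\link{zscoreAt}} over every bin; edge bins where the
#' baseline window does not fit are \code{NA}.
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @param cfg a \linkS4class{BaselineConfig}.
#' @return channels x bins matrix of z values.
#' @export
zscoreSpectrum <- function(spec, cfg = baselineConfig(dropExtremes = "minmax")) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  bl <- .baselineAll(spec@amplitude, cfg)
  (spec@amplitude - bl$mean) / bl$sd
}

#' Subtract the local baseline from a spectrum
#'
#' Per bin and channel, amplitude minus the local-baseline mean, so
#' noise-level bins contribute approximately zero to harmonic sums and
#' frequency bands with different noise levels become comparable. Edge
#' bins are \code{NA}.
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @param cfg a \linkS4class{BaselineConfig}; the quantification convention
#'   is adjacent-bins-only (\code{dropExtremes = "none"}), the default.
#' @return a baseline-corrected \linkS4class{AmplitudeSpectrum} (values may
#'   be negative).
#' @export
baselineSubtract <- function(spec, cfg = baselineConfig()) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  bl <- .baselineAll(spec@amplitude, cfg)
  initialize(spec, amplitude = spec@amplitude - bl$mean)
}

#' SNR spectrum
#'
#' Per-bin amplitude divided by the local-baseline mean; 1 means
#' noise-level, the paper-style visualization of response strength.
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @param cfg a \linkS4class{BaselineConfig} (adjacent-only default).
#' @return an \linkS4class{SNRSpectrum}; bins with zero or undefined
#'   baseline are \code{NA}.
#' @export
snrSpectrum <- function(spec, cfg = baselineConfig()) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  bl <- .baselineAll(spec@amplitude, cfg)
  snr <- spec@amplitude / bl$mean
  snr[!is.finite(snr)] <- NA_real_
  new("SNRSpectrum", freqs = spec@freqs, snr = snr,
      channelLabels = spec@channelLabels)
}

#' Retained harmonic frequencies of a fundamental
#'
#' Integer multiples of \code{fundamental}, excluding any frequency that is
#' (within tolerance) an integer multiple of a frequency in \code{exclude}
#' (base-rate responses are excluded from the target-rate harmonic count).
#'
#' @param fundamental Hz.
#' @param nHarmonics number of multiples to walk.
#' @param exclude frequencies (Hz) whose integer multiples are skipped.
#' @param tol frequency matching tolerance (Hz).
#' @return numeric vector of retained harmonic frequencies.
#' @export
harmonicFrequencies <- function(fundamental, nHarmonics, exclude = numeric(),
                                tol = 1e-6) {
  f <- fundamental * seq_len(nHarmonics)
  if (length(exclude)) {
    skip <- vapply(f, function(fi) {
      any(vapply(exclude, function(e) {
        k <- round(fi / e)
        k >= 1 && abs(fi - k * e) <= tol
      }, logical(1)))
    }, logical(1))
    f <- f[!skip]
  }
  f
}

#' Select consecutive significant harmonics and sum the response
#'
#' Walks the harmonics of \code{fundamental} on the channel-pooled
#' spectrum, skipping base-rate multiples, and flags each retained harmonic
#' as significant when its local-baseline z exceeds \code{zThresh}
#' (default 2.32, p < 0.01 one-tailed). The walk stops at the first
#' non-significant retained harmonic ("consecutive significant
#' harmonics"). The per-channel response is the baseline-subtracted
#' amplitude summed over the significant harmonics (the topography
#' vector).
#'
#' @param spec a (grand-average) multichannel \linkS4class{AmplitudeSpectrum}.
#' @param fundamental target frequency in Hz (on the bin grid).
#' @param zThresh significance threshold (default 2.32).
#' @param exclude frequencies whose multiples are skipped (the base rate).
#' @param maxHarmonics cap on retained harmonics walked.
#' @param cfg baseline configuration for the z-scores (min/max-dropped
#'   convention by default).
#' @param subtractCfg baseline configuration for the summed amplitudes
#'   (adjacent-only convention by default).
#' @return a \linkS4class{HarmonicResponse}.
#' @export
significantHarmonics <- function(spec, fundamental, zThresh = 2.32,
                                 exclude = numeric(), maxHarmonics = 50,
                                 cfg = baselineConfig(dropExtremes = "minmax"),
                                 subtractCfg = baselineConfig()) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  pooled <- poolChannels(spec)
  reachHz <- max(.candOffsets(cfg)) * spec@resolution
  fmax <- max(spec@freqs) - reachHz
  cand <- harmonicFrequencies(fundamental, floor(fmax / fundamental),
                              exclude, tol = spec@resolution / 2)
  cand <- cand[cand <= fmax]
  if (length(cand) > maxHarmonics) cand <- cand[seq_len(maxHarmonics)]
  kept <- numeric(0); zs <- numeric(0); sig <- logical(0)
  for (f in cand) {
    z <- suppressWarnings(zscoreAt(pooled, f, cfg))
    kept <- c(kept, f); zs <- c(zs, z)
    s <- is.finite(z) && z > zThresh
    sig <- c(sig, s)
    if (!s) break
  }
  summed <- harmonicTopography(spec, kept[sig], subtractCfg)
  new("HarmonicResponse", fundamental = fundamental, harmonics = kept,
      z = zs, significant = sig, summedAmplitude = summed)
}

#' Sum a corrected spectrum over harmonic bins
#'
#' Per-channel sum of (baseline-subtracted) amplitudes at the listed
#' harmonic frequencies; the resulting named vector is the topography of
#' the periodic response. Including noise-level harmonics adds
#' approximately zero.
#'
#' @param corrected an \linkS4class{AmplitudeSpectrum}, normally from
#'   \code{\link{baselineSubtract}}.
#' @param harmonics frequencies (Hz) on the bin grid; empty gives zeros.
#' @return named per-channel numeric vector (uV).
#' @export
sumHarmonics <- function(corrected, harmonics) {
  stopifnot(is(corrected, "AmplitudeSpectrum"))
  out <- numeric(nrow(corrected@amplitude))
  names(out) <- corrected@channelLabels
  for (f in harmonics)
    out <- out + corrected@amplitude[, .binIndex(corrected, f)]
  out
}

#' Per-channel baseline-subtracted response summed over harmonics
#'
#' Equivalent to \code{sumHarmonics(baselineSubtract(spec, cfg), harmonics)}
#' but evaluating the local baseline only at the harmonic bins, which is
#' much cheaper on long spectra.
#'
#' @param spec an \linkS4class{AmplitudeSpectrum}.
#' @param harmonics frequencies (Hz) on the bin grid; empty gives zeros.
#' @param cfg a \linkS4class{BaselineConfig} (adjacent-only default).
#' @return named per-channel numeric vector (uV).
#' @export
harmonicTopography <- function(spec, harmonics, cfg = baselineConfig()) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  out <- numeric(nrow(spec@amplitude))
  names(out) <- spec@channelLabels
  if (!length(harmonics)) return(out)
  bins <- vapply(harmonics, function(f) .binIndex(spec, f), integer(1))
  bl <- .baselineBins(spec@amplitude, bins, cfg)
  out[] <- rowSums(spec@amplitude[, bins, drop = FALSE] - bl$mean)
  out
}

#' Individual-subject significance by chunk summation
#'
#' The single-subject test: extract a window of \code{2 * halfWidth + 1}
#' bins centred on each listed harmonic from the channel-pooled spectrum,
#' sum the windows element-wise, and z-score the centre value against the
#' \code{2 * nSide} flanking bins (excluding the bins immediately adjacent
#' to the centre). Summing windows accumulates the response across
#' harmonics while the noise grows only as its square root.
#'
#' @param spec the subject's \linkS4class{AmplitudeSpectrum} (channels are
#'   pooled internally).
#' @param harmonics harmonic frequencies (Hz) significant at the group
#'   level.
#' @param halfWidth bins on each side of the centre (default 11).
#' @param zThresh significance threshold (default 1.64, p < 0.05
#'   one-tailed).
#' @param skipAdjacent adjacent bins excluded from the baseline (default 1).
#' @return list with \code{z}, \code{significant}, and the summed
#'   \code{window}.
#' @export
individualSignificance <- function(spec, harmonics, halfWidth = 11,
                                   zThresh = 1.64, skipAdjacent = 1) {
  stopifnot(is(spec, "AmplitudeSpectrum"), length(harmonics) >= 1)
  pooled <- poolChannels(spec)
  A <- pooled@amplitude[1, ]
  nb <- length(A)
  w <- 2L * as.integer(halfWidth) + 1L
  acc <- numeric(w)
  for (f in harmonics) {
    bin <- .binIndex(pooled, f)
    if (bin - halfWidth < 1L || bin + halfWidth > nb)
      stop(sprintf("harmonic %.6g Hz lacks a %d-bin margin", f, halfWidth))
    acc <- acc + A[(bin - halfWidth):(bin + halfWidth)]
  }
  centre <- halfWidth + 1L
  offs <- setdiff(seq_len(w), centre + (-skipAdjacent):skipAdjacent)
  base <- acc[offs]
  delta <- acc[centre] - mean(base)
  z <- if (delta == 0) 0 else delta / stats::sd(base)
  list(z = z, significant = is.finite(z) && z > zThresh, window = acc)
}
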