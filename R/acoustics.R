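#' @include AllClasses.R
NULL

## autocorrelation machinery with exact fractional-lag evaluation: the raw
## autocorrelation of the zero-padded signal is band-limited, so
## ac(tau) = (1/m) sum_k |X_k|^2 cos(2 pi k tau / m) holds for any real tau.
## Normalization uses the energies of the two overlapping segments
## (interpolated linearly between integer lags).
.autocorState <- function(x) {
  n <- length(x)
  m <- stats::nextn(2 * n, 2)
  P <- Mod(stats::fft(c(x, rep(0, m - n))))^2
  list(n = n, m = m, Phalf = P[2:(m / 2)], P0 = P[1], Pny = P[m / 2 + 1],
       e = cumsum(x^2))
}

.acAt <- function(st, taus) {
  k <- seq_along(st$Phalf)
  ang <- outer(k, taus) * (2 * pi / st$m)
  (st$P0 + 2 * colSums(st$Phalf * cos(ang)) +
     st$Pny * cos(pi * taus)) / st$m
}

.rAt <- function(st, taus) {
  ac <- .acAt(st, taus)
  lo <- floor(taus); fr <- taus - lo
  Efun <- function(lag) {
    lag <- pmin(pmax(lag, 0), st$n - 1)
    E1 <- st$e[st$n - lag]
    E2 <- st$e[st$n] - ifelse(lag == 0, 0, st$e[pmax(lag, 1)])
    E1 * E2
  }
  den <- sqrt((1 - fr) * Efun(lo) + fr * Efun(lo + 1L))
  ifelse(den > 0, ac / den, 0)
}

#' Estimate the fundamental frequency of a clip
#'
#' Autocorrelation pitch tracking over the whole clip: the normalized
#' autocorrelation is evaluated for lags covering \code{[fmin, fmax]}, the
#' strongest peak is refined by windowed-sinc interpolation, and sub-multiple
#' lags of comparable height are preferred to guard against subharmonic
#' errors. Aperiodic input
#' (peak correlation below \code{voicingThreshold}) is flagged as unvoiced.
#'
#' @param clip an \linkS4class{AudioClip}; must last at least three periods
#'   of \code{fmin}.
#' @param fmin,fmax search range in Hz (default 75-600, the conventional
#'   speech range).
#' @param voicingThreshold minimum normalized autocorrelation for a voiced
#'   decision (default 0.3).
#' @return a list with \code{f0} (Hz, \code{NA} when unvoiced), \code{voiced}
#'   (logical) and \code{r} (peak normalized autocorrelation).
#' @examples
#' t <- seq(0, 0.25 - 1/16000, by = 1/16000)
#' clip <- audioClip(sin(2 * pi * 220 * t) + 0.5 * sin(2 * pi * 440 * t), 16000)
#' pitchEstimate(clip)$f0
#' @export
pitchEstimate <- function(clip, fmin = 75, fmax = 600,
                          voicingThreshold = 0.3) {
  stopifnot(is(clip, "AudioClip"), fmin > 0, fmax > fmin,
            fmax < clip@rate / 2)
  x <- clip@samples - mean(clip@samples)
  n <- length(x)
  minLag <- max(2L, floor(clip@rate / fmax))
  maxLag <- ceiling(clip@rate / fmin)
  if (n < 3 * maxLag)
    stop("clip too short: need at least 3 periods of fmin")
  if (all(x == 0))
    return(list(f0 = NA_real_, voiced = FALSE, r = 0))
  st <- .autocorState(x)
  r <- .rAt(st, seq_len(maxLag))
  idx <- minLag:maxLag
  ## refine a peak near `centre` on a fine fractional-lag grid: the true
  ## period is rarely an integer number of samples, and with wide-band
  ## signals the integer-lag samples sit visibly off the peak
  refine <- function(centre) {
    taus <- seq(max(centre - 1, 2), min(centre + 1, maxLag), by = 0.02)
    vals <- .rAt(st, taus)
    i <- which.max(vals)
    c(lag = taus[i], height = min(vals[i], 1))
  }
  ## a periodic signal peaks at every multiple of its period, so the global
  ## maximum may sit on a subharmonic; prefer the smallest sub-multiple lag
  ## carrying a peak of comparable height
  k0 <- idx[which.max(r[idx])]
  best <- refine(k0)
  rbest <- best["height"]
  for (m in rev(seq_len(floor(best["lag"] / minLag))[-1])) {
    candLag <- best["lag"] / m
    if (candLag < minLag) next
    cand <- refine(candLag)
    if (cand["height"] >= rbest - 0.1) { best <- cand; break }
  }
  rpk <- unname(best["height"])
  if (!is.finite(rpk) || rpk < voicingThreshold)
    return(list(f0 = NA_real_, voiced = FALSE, r = max(0, rpk)))
  list(f0 = clip@rate / unname(best["lag"]), voiced = TRUE,
       r = min(rpk, 1 - 1e-9))
}

#' Harmonics-to-noise ratio of a clip
#'
#' From the peak normalized autocorrelation r at the pitch period,
#' HNR = 10 log10(r / (1 - r)) dB: r estimates the fraction of signal power
#' that is periodic, so r/(1-r) is the harmonic-to-noise power ratio.
#' Values are capped at \code{maxHnr} (r approaching 1 for noiseless
#' periodic input).
#'
#' @param clip an \linkS4class{AudioClip} with detectable pitch; unvoiced
#'   input uses the peak autocorrelation in the search range anyway, giving
#'   a low (typically negative) HNR.
#' @param fmin,fmax pitch search range (Hz).
#' @param maxHnr cap in dB (default 60).
#' @return HNR in dB (finite).
#' @export
hnrEstimate <- function(clip, fmin = 75, fmax = 600, maxHnr = 60) {
  stopifnot(is(clip, "AudioClip"))
  p <- pitchEstimate(clip, fmin, fmax, voicingThreshold = 0)
  r <- min(max(p$r, 1e-6), 1 - 1e-12)
  min(10 * log10(r / (1 - r)), maxHnr)
}

#' Spectral center of gravity
#'
#' Amplitude-weighted mean frequency of the single-sided magnitude spectrum.
#'
#' @param clip an \linkS4class{AudioClip} with nonzero energy.
#' @return centroid in Hz, inside (0, rate/2).
#' @export
spectralCentroid <- function(clip) {
  stopifnot(is(clip, "AudioClip"))
  x <- clip@samples
  if (all(x == 0))
    stop("spectral centroid undefined for silence")
  n <- length(x)
  A <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1L)]
  f <- (seq_along(A) - 1L) * clip@rate / n
  sum(f * A) / sum(A)
}

#' Acoustic profile of a clip set
#'
#' Batch pitch / HNR / spectral-centroid characterization, the table used to
#' verify matched-set designs (voices vs instruments with equal pitch and
#' HNR distributions).
#'
#' @param clips list of \linkS4class{AudioClip}.
#' @param ... passed to \code{\link{pitchEstimate}} / \code{\link{hnrEstimate}}.
#' @return data.frame with columns id, category, duration, rms, pitch,
#'   voiced, hnr, centroid.
#' @export
acousticProfile <- function(clips, ...) {
  stopifnot(length(clips) > 0)
  rows <- lapply(clips, function(cl) {
    p <- pitchEstimate(cl, ...)
    data.frame(id = cl@id, category = cl@category,
               duration = duration(cl), rms = rms(cl),
               pitch = p$f0, voiced = p$voiced,
               hnr = hnrEstimate(cl, ...),
               centroid = spectralCentroid(cl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
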