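#' @include AllClasses.R
NULL

## apply a zero-phase (forward-backward) filter row-wise
.filtfiltRows <- function(mat, flt) {
  t(apply(mat, 1L, function(ch) signal::filtfilt(flt, ch)))
}

.replaceData <- function(x, mat) initialize(x, data = mat)

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-\code{order} Butterworth band-pass forward and backward
#' (zero-phase, so steady-state phase relationships across channels are
#' untouched; the effective magnitude order doubles). The default 0.1-100 Hz
#' band removes slow drift and high-frequency noise ahead of downsampling.
#'
#' @param rec an \linkS4class{EEGRecording} or \linkS4class{Epoch}.
#' @param low,high cutoff frequencies in Hz, \code{0 < low < high < rate/2}.
#' @param order filter order (default 4).
#' @return the filtered object.
#' @export
bandpassButterworth <- function(rec, low = 0.1, high = 100, order = 4) {
  stopifnot(is(rec, "EEGRecording") || is(rec, "Epoch"))
  rate <- samplingRate(rec)
  if (!(low > 0 && low < high && high < rate / 2))
    stop("cutoffs must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  .replaceData(rec, .filtfiltRows(channelData(rec), bf))
}

#' FFT multinotch filter
#'
#' Suppresses spectral amplitude in narrow bands around each listed
#' frequency (mains interference at 50/100/150 Hz by default) directly in
#' the frequency domain: bins within \code{width/2} of a notch frequency are
#' zeroed, with a linear taper of one bin at each notch edge; the spectrum
#' elsewhere is untouched.
#'
#' @param rec an \linkS4class{EEGRecording} or \linkS4class{Epoch}.
#' @param freqs notch centre frequencies in Hz (empty vector = identity).
#' @param width full notch width in Hz (default 0.5).
#' @return the filtered object.
#' @export
fftMultinotch <- function(rec, freqs = c(50, 100, 150), width = 0.5) {
  stopifnot(is(rec, "EEGRecording") || is(rec, "Epoch"))
  rate <- samplingRate(rec)
  if (!length(freqs)) return(rec)
  if (any(freqs >= rate / 2))
    stop("notch frequencies must be below Nyquist")
  mat <- channelData(rec)
  n <- ncol(mat)
  f <- (seq_len(n) - 1L) / n * rate
  f <- pmin(f, rate - f)          # fold: distance of each FFT bin from 0 Hz
  gain <- rep(1, n)
  binw <- rate / n
  for (f0 in freqs) {
    d <- abs(f - f0)
    gain[d <= width / 2] <- 0
    edge <- d > width / 2 & d <= width / 2 + binw
    gain[edge] <- pmin(gain[edge], (d[edge] - width / 2) / binw)
  }
  out <- t(apply(mat, 1L, function(ch)
    Re(stats::fft(stats::fft(ch) * gain, inverse = TRUE) / n)))
  .replaceData(rec, out)
}

#' Downsample a recording by an integer factor
#'
#' Zero-phase Butterworth anti-alias low-pass at 90\% of the new Nyquist
#' followed by integer-factor decimation, preserving in-band amplitudes and
#' the duration; event onsets are stored in seconds and are unaffected.
#' The band-pass stage normally precedes this step so content is already
#' limited well below the new Nyquist.
#'
#' @param rec an \linkS4class{EEGRecording} or \linkS4class{Epoch}.
#' @param newRate target rate in Hz; must divide the current rate.
#' @return the downsampled object.
#' @export
downsample <- function(rec, newRate) {
  stopifnot(is(rec, "EEGRecording") || is(rec, "Epoch"))
  rate <- samplingRate(rec)
  if (newRate > rate) stop("newRate must not exceed the current rate")
  q <- rate / newRate
  if (abs(q - round(q)) > 1e-9)
    stop("newRate must divide the current rate (integer decimation)")
  q <- round(q)
  if (q == 1L) return(rec)
  lp <- signal::butter(8, 0.9 / q, type = "low")
  mat <- .filtfiltRows(channelData(rec), lp)
  mat <- mat[, seq(1L, ncol(mat), by = q), drop = FALSE]
  initialize(rec, data = mat, rate = newRate)
}

#' Cut fixed-length epochs around sequence-onset events
#'
#' One epoch per event: the window runs from \code{pre} seconds before the
#' event onset to \code{seqDuration + post} seconds after it (69-s epochs
#' for a 64-s sequence with 2 s before and 3 s after). Events whose window
#' falls outside the record are skipped with a message.
#'
#' @param rec an \linkS4class{EEGRecording} with events.
#' @param pre seconds before event onset (default 2).
#' @param post seconds after sequence offset (default 3).
#' @param seqDuration stimulation-sequence duration in seconds.
#' @param code if given, only events with this code are used.
#' @return list of \linkS4class{Epoch} with \code{t0 = -pre}.
#' @export
segmentEpochs <- function(rec, pre = 2, post = 3, seqDuration, code = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  ev <- events(rec)
  if (!is.null(code)) ev <- ev[ev$code == code, , drop = FALSE]
  rate <- samplingRate(rec)
  mat <- channelData(rec)
  len <- round((pre + seqDuration + post) * rate)
  out <- list()
  for (i in seq_len(nrow(ev))) {
    start <- round((ev$onset[i] - pre) * rate) + 1L
    if (start < 1L || start + len - 1L > ncol(mat)) {
      message(sprintf("segmentEpochs: skipping event at %.3f s (window out of bounds)",
                      ev$onset[i]))
      next
    }
    out[[length(out) + 1L]] <-
      epoch(mat[, start:(start + len - 1L), drop = FALSE], rate,
            channelLabels(rec), t0 = -pre)
  }
  out
}

#' Interpolate bad channels from nearest neighbours
#'
#' Replaces each bad channel by the mean of its \code{k} nearest good
#' channels (Euclidean distance on the electrode layout), the linear
#' neighbour interpolation used for noisy electrodes.
#'
#' @param ep an \linkS4class{Epoch} (or \linkS4class{EEGRecording}).
#' @param bad character labels of channels to repair.
#' @param layout data.frame with columns label, x, y, z (see
#'   \code{\link{readElectrodeLayout}}).
#' @param k neighbours to average (3 or 4; default 4).
#' @return the repaired object; good channels are untouched.
#' @export
interpolateChannels <- function(ep, bad, layout, k = 4) {
  stopifnot(is(ep, "Epoch") || is(ep, "EEGRecording"), k >= 1)
  if (!length(bad)) return(ep)
  labs <- channelLabels(ep)
  if (!all(bad %in% labs)) stop("bad labels not found among channels")
  if (all(labs %in% bad)) stop("cannot interpolate: all channels bad")
  if (!all(labs %in% layout$label))
    stop("layout is missing some channel labels")
  pos <- as.matrix(layout[match(labs, layout$label), c("x", "y", "z")])
  good <- setdiff(labs, bad)
  if (length(good) < k)
    stop(sprintf("fewer than k = %d good channels available", k))
  mat <- channelData(ep)
  for (b in bad) {
    bi <- match(b, labs)
    d <- sqrt(colSums((t(pos) - pos[bi, ])^2))
    d[match(bad, labs)] <- Inf      # neighbours must be good channels
    nb <- order(d)[seq_len(k)]
    mat[bi, ] <- colMeans(mat[nb, , drop = FALSE])
  }
  .replaceData(ep, mat)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across all channels, so the channel
#' mean is zero at every sample. Idempotent.
#'
#' @param ep an \linkS4class{Epoch} (or \linkS4class{EEGRecording}) with at
#'   least 2 channels.
#' @return the re-referenced object.
#' @export
rereferenceAverage <- function(ep) {
  stopifnot(is(ep, "Epoch") || is(ep, "EEGRecording"))
  mat <- channelData(ep)
  if (nrow(mat) < 2) stop("average reference needs at least 2 channels")
  .replaceData(ep, sweep(mat, 2L, colMeans(mat)))
}

#' Longest integer-cycle duration
#'
#' The largest duration not exceeding \code{min(available, maxDuration)}
#' that contains a whole number of cycles of \code{targetFreq}:
#' \code{floor(available * f) / f}.
#'
#' @param available available duration in seconds.
#' @param targetFreq cycle frequency in Hz.
#' @param maxDuration optional cap in seconds.
#' @return list with \code{duration} (s) and \code{cycles} (integer).
#' @examples
#' integerCycleDuration(65, 4 / 3, maxDuration = 60)       # 60 s, 80 cycles
#' integerCycleDuration(65, 7.8125 / 3, maxDuration = 60)  # 59.904 s, 156 cycles
#' @export
integerCycleDuration <- function(available, targetFreq, maxDuration = Inf) {
  stopifnot(targetFreq > 0)
  avail <- min(available, maxDuration)
  cycles <- floor(avail * targetFreq + 1e-9)
  if (cycles < 1) stop("less than one target cycle available")
  list(duration = cycles / targetFreq, cycles = as.integer(cycles))
}

#' Resegment an epoch to a whole number of target cycles
#'
#' Drops \code{skip} seconds from the start (pre-onset margin plus fade-in)
#' and truncates the remainder to the longest duration containing an exact
#' integer number of cycles of \code{targetFreq}, eliminating spectral
#' leakage of the periodic response. The cut is realized on the sample grid
#' (\code{round(duration * rate)} samples).
#'
#' @param ep an \linkS4class{Epoch}.
#' @param targetFreq oddball frequency in Hz.
#' @param skip seconds to discard from the epoch start (default 0).
#' @param maxDuration optional cap on the retained duration (s).
#' @return the resegmented \linkS4class{Epoch}.
#' @export
resegmentIntegerCycles <- function(ep, targetFreq, skip = 0,
                                   maxDuration = Inf) {
  stopifnot(is(ep, "Epoch"))
  avail <- duration(ep) - skip
  if (avail < 1 / targetFreq) stop("epoch too short after skip")
  icd <- integerCycleDuration(avail, targetFreq, maxDuration)
  rate <- samplingRate(ep)
  start <- round(skip * rate) + 1L
  len <- round(icd$duration * rate)
  mat <- channelData(ep)[, start:(start + len - 1L), drop = FALSE]
  initialize(ep, data = mat, t0 = ep@t0 + skip)
}

#' Peak-to-peak epoch rejection helper
#'
#' Optional artifact screen: flags epochs whose maximum peak-to-peak
#' amplitude on any channel exceeds a threshold. Off by default in the
#' pipeline; supplied for users who want a numeric criterion in place of
#' visual inspection.
#'
#' @param epochs list of \linkS4class{Epoch}.
#' @param threshold peak-to-peak limit in uV.
#' @return logical vector, \code{TRUE} for epochs to keep.
#' @export
rejectByPeakToPeak <- function(epochs, threshold) {
  vapply(epochs, function(ep) {
    ptp <- apply(channelData(ep), 1L, function(ch) diff(range(ch)))
    max(ptp) <= threshold
  }, logical(1))
}
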