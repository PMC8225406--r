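#' @include AllGenerics.R
NULL

## ---- AudioClip -------------------------------------------------------------

#' AudioClip: a mono sampled waveform with a category label
#'
#' The unit of stimulus engineering: a short mono sound (arbitrary linear
#' units) with its sampling rate, a category label (\code{"vocal"} or
#' \code{"nonvocal"}) and an identifier.
#'
#' @slot samples numeric waveform (finite values only).
#' @slot rate sampling rate in Hz.
#' @slot category \code{"vocal"} or \code{"nonvocal"}.
#' @slot id identifier string.
#' @export
setClass("AudioClip",
  representation(samples = "numeric", rate = "numeric",
                 category = "character", id = "character"),
  prototype(samples = numeric(), rate = 44100,
            category = "nonvocal", id = ""))

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (!object@category %in% c("vocal", "nonvocal"))
    msg <- c(msg, "category must be 'vocal' or 'nonvocal'")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioClip
#'
#' @param samples numeric waveform.
#' @param rate sampling rate in Hz.
#' @param category \code{"vocal"} or \code{"nonvocal"}.
#' @param id identifier string.
#' @return an \linkS4class{AudioClip}.
#' @examples
#' clip <- audioClip(sin(2 * pi * 440 * seq(0, 0.25, length.out = 4000)),
#'                   rate = 16000, category = "nonvocal", id = "a440")
#' duration(clip)
#' @export
audioClip <- function(samples, rate, category = "nonvocal", id = "") {
  new("AudioClip", samples = as.numeric(samples), rate = rate,
      category = category, id = id)
}

#' @describeIn samplingRate rate of an audio clip
#' @export
setMethod("samplingRate", "AudioClip", function(x) x@rate)

#' @describeIn duration duration of an audio clip
#' @export
setMethod("duration", "AudioClip", function(x) length(x@samples) / x@rate)

#' @describeIn samples waveform of an audio clip
#' @export
setMethod("samples", "AudioClip", function(x) x@samples)

#' Category label of a clip
#' @param x an \linkS4class{AudioClip}.
#' @return \code{"vocal"} or \code{"nonvocal"}.
#' @export
clipCategory <- function(x) x@category

#' Identifier of a clip
#' @param x an \linkS4class{AudioClip}.
#' @return id string.
#' @export
clipId <- function(x) x@id

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip '%s' (%s): %.4g s at %g Hz, RMS %.4g\n",
              object@id, object@category,
              length(object@samples) / object@rate, object@rate,
              sqrt(mean(object@samples^2))))
})

## ---- StimulusSequence ------------------------------------------------------

#' StimulusSequence: a concatenated periodic sound sequence
#'
#' The waveform presented to a listener: sounds of equal duration (the SOA)
#' concatenated back-to-back with the oddball category in every
#' \code{oddballPeriod}-th slot, plus an event table.
#'
#' @slot waveform numeric samples.
#' @slot rate Hz.
#' @slot events data.frame with columns \code{onset} (s), \code{id},
#'   \code{category}, \code{is_target} (attentional target flag).
#' @slot baseFreq stimulus presentation rate, 1/SOA (Hz).
#' @slot targetFreq oddball rate, baseFreq / oddballPeriod (Hz).
#' @slot soa stimulus-onset asynchrony in seconds.
#' @slot oddballPeriod integer oddball period (every n-th sound).
#' @export
setClass("StimulusSequence",
  representation(waveform = "numeric", rate = "numeric",
                 events = "data.frame", baseFreq = "numeric",
                 targetFreq = "numeric", soa = "numeric",
                 oddballPeriod = "integer"))

setValidity("StimulusSequence", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("onset", "id", "category", "is_target")
  if (!all(need %in% names(ev)))
    msg <- c(msg, "events must have columns onset, id, category, is_target")
  if (nrow(ev) > 1) {
    d <- diff(ev$onset)
    if (any(abs(d - object@soa) > 1e-9))
      msg <- c(msg, "consecutive event onsets must differ by exactly soa")
  }
  if (abs(object@targetFreq - object@baseFreq / object@oddballPeriod) > 1e-9)
    msg <- c(msg, "targetFreq must equal baseFreq / oddballPeriod")
  if (length(msg)) msg else TRUE
})

#' @describeIn samplingRate rate of a stimulus sequence
#' @export
setMethod("samplingRate", "StimulusSequence", function(x) x@rate)

#' @describeIn duration duration of a stimulus sequence
#' @export
setMethod("duration", "StimulusSequence", function(x) length(x@waveform) / x@rate)

#' @describeIn samples waveform of a stimulus sequence
#' @export
setMethod("samples", "StimulusSequence", function(x) x@waveform)

#' @describeIn events event table of a stimulus sequence
#' @export
setMethod("events", "StimulusSequence", function(x) x@events)

#' Base (presentation) frequency of a sequence
#' @param x a \linkS4class{StimulusSequence}.
#' @return Hz.
#' @export
baseFreq <- function(x) x@baseFreq

#' Target (oddball) frequency of a sequence
#' @param x a \linkS4class{StimulusSequence}.
#' @return Hz.
#' @export
targetFreq <- function(x) x@targetFreq

setMethod("show", "StimulusSequence", function(object) {
  cat(sprintf(
    "StimulusSequence: %.3f s at %g Hz | base %.4g Hz, target %.4g Hz\n",
    length(object@waveform) / object@rate, object@rate,
    object@baseFreq, object@targetFreq))
  cat(sprintf("  %d events (%d oddball, %d attentional targets)\n",
              nrow(object@events),
              sum(object@events$category == "vocal"),
              sum(object@events$is_target)))
})

## ---- EEGRecording / Epoch --------------------------------------------------

#' EEGRecording: continuous multichannel EEG
#'
#' Channels-by-samples matrix in microvolts with channel labels and an
#' event table (onset in seconds, integer code).
#'
#' @slot data channels x samples matrix (uV).
#' @slot rate sampling rate (Hz).
#' @slot channelLabels character vector, one unique label per row.
#' @slot events data.frame with columns \code{onset} (s) and \code{code}.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", rate = "numeric",
                 channelLabels = "character", events = "data.frame"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "one channel label per data row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@events)) {
    if (!all(c("onset", "code") %in% names(object@events)))
      msg <- c(msg, "events must have columns onset and code")
    else {
      dur <- ncol(object@data) / object@rate
      if (any(object@events$onset < 0 | object@events$onset > dur))
        msg <- c(msg, "event onsets must lie within the record")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (uV).
#' @param rate sampling rate in Hz.
#' @param channelLabels character labels, one per row.
#' @param events data.frame with \code{onset} (s) and \code{code}; empty by
#'   default.
#' @return an \linkS4class{EEGRecording}.
#' @export
eegRecording <- function(data, rate, channelLabels = rownames(data),
                         events = data.frame(onset = numeric(),
                                             code = integer())) {
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channelLabels
  new("EEGRecording", data = data, rate = rate,
      channelLabels = channelLabels, events = events)
}

#' @describeIn samplingRate rate of a recording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)

#' @describeIn duration duration of a recording
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@rate)

#' @describeIn channelData data matrix of a recording
#' @export
setMethod("channelData", "EEGRecording", function(x) x@data)

#' @describeIn channelLabels labels of a recording
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @describeIn events event table of a recording
#' @export
setMethod("events", "EEGRecording", function(x) x@events)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples (%.2f s at %g Hz), %d events\n",
              nrow(object@data), ncol(object@data),
              ncol(object@data) / object@rate, object@rate,
              nrow(object@events)))
})

#' Epoch: a fixed-length multichannel EEG cut
#'
#' A channels-by-samples segment aligned to a stimulation-sequence onset;
#' \code{t0} is the time of the first sample relative to that onset
#' (negative when a pre-onset margin is included).
#'
#' @slot data channels x samples matrix (uV).
#' @slot rate Hz.
#' @slot channelLabels character labels.
#' @slot t0 seconds relative to sequence onset.
#' @export
setClass("Epoch",
  representation(data = "matrix", rate = "numeric",
                 channelLabels = "character", t0 = "numeric"))

setValidity("Epoch", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "one channel label per data row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an Epoch
#'
#' @param data channels x samples matrix (uV).
#' @param rate Hz.
#' @param channelLabels labels, one per row.
#' @param t0 time of first sample relative to sequence onset (s).
#' @return an \linkS4class{Epoch}.
#' @export
epoch <- function(data, rate, channelLabels = rownames(data), t0 = 0) {
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channelLabels
  new("Epoch", data = data, rate = rate, channelLabels = channelLabels,
      t0 = t0)
}

#' @describeIn samplingRate rate of an epoch
#' @export
setMethod("samplingRate", "Epoch", function(x) x@rate)

#' @describeIn duration duration of an epoch
#' @export
setMethod("duration", "Epoch", function(x) ncol(x@data) / x@rate)

#' @describeIn channelData data matrix of an epoch
#' @export
setMethod("channelData", "Epoch", function(x) x@data)

#' @describeIn channelLabels labels of an epoch
#' @export
setMethod("channelLabels", "Epoch", function(x) x@channelLabels)

setMethod("show", "Epoch", function(object) {
  cat(sprintf("Epoch: %d channels x %d samples (%.3f s at %g Hz), t0 = %.3f s\n",
              nrow(object@data), ncol(object@data),
              ncol(object@data) / object@rate, object@rate, object@t0))
})

## ---- Spectra ---------------------------------------------------------------

#' AmplitudeSpectrum: single-sided amplitude spectrum per channel
#'
#' Bin frequencies run from 0 in steps of \code{resolution} = 1/duration.
#' Scaling is such that a bin-centred sinusoid of amplitude A appears with
#' spectral amplitude A. Values may be negative after baseline subtraction
#' (see \code{\link{baselineSubtract}}).
#'
#' @slot freqs Hz grid.
#' @slot amplitude channels x bins matrix (uV).
#' @slot resolution Hz (bin spacing).
#' @slot channelLabels labels, one per row.
#' @export
setClass("AmplitudeSpectrum",
  representation(freqs = "numeric", amplitude = "matrix",
                 resolution = "numeric", channelLabels = "character"))

setValidity("AmplitudeSpectrum", function(object) {
  msg <- character()
  if (ncol(object@amplitude) != length(object@freqs))
    msg <- c(msg, "one frequency per amplitude column required")
  if (nrow(object@amplitude) != length(object@channelLabels))
    msg <- c(msg, "one channel label per amplitude row required")
  if (length(object@freqs) > 1) {
    d <- diff(object@freqs)
    if (object@freqs[1] != 0 || any(abs(d - object@resolution) > 1e-9))
      msg <- c(msg, "freqs must be uniform from 0 with spacing = resolution")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn freqs grid of an amplitude spectrum
#' @export
setMethod("freqs", "AmplitudeSpectrum", function(x) x@freqs)

#' @describeIn spectralValues amplitudes (uV)
#' @export
setMethod("spectralValues", "AmplitudeSpectrum", function(x) x@amplitude)

#' @describeIn frequencyResolution of an amplitude spectrum
#' @export
setMethod("frequencyResolution", "AmplitudeSpectrum", function(x) x@resolution)

#' @describeIn channelLabels labels of an amplitude spectrum
#' @export
setMethod("channelLabels", "AmplitudeSpectrum", function(x) x@channelLabels)

setMethod("show", "AmplitudeSpectrum", function(object) {
  cat(sprintf("AmplitudeSpectrum: %d channels x %d bins, 0-%.4g Hz at %.4g Hz resolution\n",
              nrow(object@amplitude), ncol(object@amplitude),
              max(object@freqs), object@resolution))
})

#' SNRSpectrum: per-bin amplitude over local-baseline mean
#'
#' @slot freqs Hz grid.
#' @slot snr channels x bins matrix (dimensionless); NA at edge bins where
#'   the baseline window does not fit.
#' @slot channelLabels labels.
#' @export
setClass("SNRSpectrum",
  representation(freqs = "numeric", snr = "matrix",
                 channelLabels = "character"))

#' @describeIn freqs grid of an SNR spectrum
#' @export
setMethod("freqs", "SNRSpectrum", function(x) x@freqs)

#' @describeIn spectralValues SNR values
#' @export
setMethod("spectralValues", "SNRSpectrum", function(x) x@snr)

#' @describeIn channelLabels labels of an SNR spectrum
#' @export
setMethod("channelLabels", "SNRSpectrum", function(x) x@channelLabels)

setMethod("show", "SNRSpectrum", function(object) {
  cat(sprintf("SNRSpectrum: %d channels x %d bins, median SNR %.3g\n",
              nrow(object@snr), ncol(object@snr),
              stats::median(object@snr, na.rm = TRUE)))
})

## ---- HarmonicResponse ------------------------------------------------------

#' HarmonicResponse: significance and summed amplitude over harmonics
#'
#' Result of walking the harmonics of a fundamental on a (channel-pooled)
#' spectrum: per-harmonic z-scores and significance flags, plus the
#' per-channel baseline-subtracted amplitude summed over the significant
#' harmonics (the topography vector).
#'
#' @slot fundamental Hz.
#' @slot harmonics Hz, the retained harmonic frequencies in order (base-rate
#'   multiples excluded).
#' @slot z per-harmonic z-score (channel-pooled).
#' @slot significant per-harmonic logical flag.
#' @slot summedAmplitude named per-channel summed baseline-subtracted
#'   amplitude (uV) over significant harmonics.
#' @export
setClass("HarmonicResponse",
  representation(fundamental = "numeric", harmonics = "numeric",
                 z = "numeric", significant = "logical",
                 summedAmplitude = "numeric"))

setValidity("HarmonicResponse", function(object) {
  msg <- character()
  if (length(object@z) != length(object@harmonics) ||
      length(object@significant) != length(object@harmonics))
    msg <- c(msg, "z and significant must be parallel to harmonics")
  if (length(msg)) msg else TRUE
})

#' Harmonic frequencies retained in a response
#' @param x a \linkS4class{HarmonicResponse}.
#' @return Hz vector.
#' @export
harmonics <- function(x) x@harmonics

#' Number of consecutive significant harmonics
#' @param x a \linkS4class{HarmonicResponse}.
#' @return integer count.
#' @export
nSignificant <- function(x) sum(x@significant)

#' Per-channel summed baseline-subtracted amplitude (topography vector)
#' @param x a \linkS4class{HarmonicResponse}.
#' @return named numeric, uV per channel.
#' @export
summedAmplitude <- function(x) x@summedAmplitude

setMethod("show", "HarmonicResponse", function(object) {
  cat(sprintf("HarmonicResponse at %.4g Hz: %d/%d significant harmonics\n",
              object@fundamental, sum(object@significant),
              length(object@harmonics)))
  if (length(object@harmonics))
    cat(sprintf("  %s\n", paste(sprintf("%.4g Hz (z=%.2f%s)",
        object@harmonics, object@z,
        ifelse(object@significant, "*", "")), collapse = ", ")))
})

## ---- BaselineConfig --------------------------------------------------------

#' Local-baseline configuration for spectral statistics
#'
#' The baseline of a bin is built from its flanking bins: on each side,
#' skip \code{skipAdjacent} immediately adjacent bins, then take candidate
#' bins outward. With \code{dropExtremes = "none"} the candidates are
#' \code{nSide} bins per side. With \code{dropExtremes = "minmax"},
#' \code{nSide + 2} candidates are taken per side and each side's minimum
#' and maximum are discarded, so exactly \code{nSide} per side remain
#' (default 10 + 10 = 20 baseline bins in both modes).
#'
#' @slot nSide retained bins per side (default 10).
#' @slot skipAdjacent adjacent bins skipped per side (default 1).
#' @slot dropExtremes \code{"none"} or \code{"minmax"}.
#' @export
setClass("BaselineConfig",
  representation(nSide = "integer", skipAdjacent = "integer",
                 dropExtremes = "character"),
  prototype(nSide = 10L, skipAdjacent = 1L, dropExtremes = "none"))

setValidity("BaselineConfig", function(object) {
  msg <- character()
  if (object@nSide < 3L) msg <- c(msg, "nSide must be >= 3")
  if (object@skipAdjacent < 0L) msg <- c(msg, "skipAdjacent must be >= 0")
  if (!object@dropExtremes %in% c("none", "minmax"))
    msg <- c(msg, "dropExtremes must be 'none' or 'minmax'")
  if (length(msg)) msg else TRUE
})

#' Construct a BaselineConfig
#'
#' @param nSide retained baseline bins per side.
#' @param skipAdjacent immediately adjacent bins to skip per side.
#' @param dropExtremes \code{"none"} (default; the convention used for
#'   baseline subtraction, SNR and the individual-subject test) or
#'   \code{"minmax"} (the convention used for group-level z-scores).
#' @return a \linkS4class{BaselineConfig}.
#' @export
baselineConfig <- function(nSide = 10, skipAdjacent = 1,
                           dropExtremes = c("none", "minmax")) {
  new("BaselineConfig", nSide = as.integer(nSide),
      skipAdjacent = as.integer(skipAdjacent),
      dropExtremes = match.arg(dropExtremes))
}

## half-width of the candidate window on one side, in bins
.baselineReach <- function(cfg) {
  extra <- if (cfg@dropExtremes == "minmax") 2L else 0L
  cfg@skipAdjacent + cfg@nSide + extra
}
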