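#' @include AllGenerics.R
NULL

#' Sampling rate of an object
#'
#' @param x an object holding sampled data (audio clip, EEG recording,
#'   epoch or stimulus sequence).
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Duration of an object in seconds
#'
#' @param x a sampled-data object.
#' @return duration in seconds (sample count / rate).
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Raw samples of an audio object
#'
#' @param x an \linkS4class{AudioClip} or \linkS4class{StimulusSequence}.
#' @return numeric waveform.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Channel-by-sample data matrix
#'
#' @param x an \linkS4class{EEGRecording} or \linkS4class{Epoch}.
#' @return numeric matrix, channels in rows.
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))

#' Channel labels
#'
#' @param x an object with labelled channels.
#' @return character vector of labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Event table
#'
#' @param x an object carrying events (a stimulus sequence or an EEG
#'   recording).
#' @return a data.frame with at least an \code{onset} column (seconds).
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Frequency grid of a spectrum
#'
#' @param x an \linkS4class{AmplitudeSpectrum} or \linkS4class{SNRSpectrum}.
#' @return numeric vector of bin frequencies in Hz, starting at 0.
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' Spectral values matrix
#'
#' @param x a spectrum object.
#' @return channels-by-bins numeric matrix.
#' @export
setGeneric("spectralValues", function(x) standardGeneric("spectralValues"))

#' Frequency resolution
#'
#' @param x a spectrum object.
#' @return bin spacing in Hz (1/duration of the transformed epoch).
#' @export
setGeneric("frequencyResolution", function(x) standardGeneric("frequencyResolution"))
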