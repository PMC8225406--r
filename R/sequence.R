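#' @include AllClasses.R stimgen.R
NULL

#' SequenceSpec: parameters of a periodic stimulation sequence
#'
#' @slot soa stimulus-onset asynchrony in seconds (= stimulus duration;
#'   0.250 gives a 4 Hz base rate, 0.128 gives 7.8125 Hz).
#' @slot oddballPeriod every n-th sound is the oddball category (default 3).
#' @slot totalDuration sequence length in seconds (including fades).
#' @slot fadeDuration fade-in and fade-out length in seconds (default 2).
#' @slot nAttentionalTargets number of attenuated attentional targets
#'   (default 6).
#' @slot attenuationFactor RMS attenuation of targets (default 12.5).
#' @slot targetSpacing minimum spacing between target onsets in seconds.
#' @slot seed integer RNG seed for the pseudo-random order.
#' @export
setClass("SequenceSpec",
  representation(soa = "numeric", oddballPeriod = "integer",
                 totalDuration = "numeric", fadeDuration = "numeric",
                 nAttentionalTargets = "integer",
                 attenuationFactor = "numeric", targetSpacing = "numeric",
                 seed = "integer"))

setValidity("SequenceSpec", function(object) {
  msg <- character()
  if (object@soa <= 0) msg <- c(msg, "soa must be positive")
  if (object@oddballPeriod < 2L) msg <- c(msg, "oddballPeriod must be >= 2")
  if (object@fadeDuration < 0) msg <- c(msg, "fadeDuration must be >= 0")
  if (object@totalDuration <= 2 * object@fadeDuration)
    msg <- c(msg, "totalDuration must exceed 2 * fadeDuration")
  if (object@attenuationFactor < 1)
    msg <- c(msg, "attenuationFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SequenceSpec
#'
#' @param soa stimulus-onset asynchrony (s).
#' @param oddballPeriod oddball every n-th sound.
#' @param totalDuration sequence length (s); must be a whole number of SOAs.
#' @param fadeDuration fade-in/out length (s).
#' @param nAttentionalTargets attenuated targets per sequence.
#' @param attenuationFactor RMS division factor for targets.
#' @param targetSpacing minimum spacing between target onsets (s).
#' @param seed RNG seed.
#' @return a \linkS4class{SequenceSpec}.
#' @export
sequenceSpec <- function(soa = 0.250, oddballPeriod = 3, totalDuration = 64,
                         fadeDuration = 2, nAttentionalTargets = 6,
                         attenuationFactor = 12.5, targetSpacing = 2,
                         seed = 1L) {
  new("SequenceSpec", soa = soa, oddballPeriod = as.integer(oddballPeriod),
      totalDuration = totalDuration, fadeDuration = fadeDuration,
      nAttentionalTargets = as.integer(nAttentionalTargets),
      attenuationFactor = attenuationFactor, targetSpacing = targetSpacing,
      seed = as.integer(seed))
}

## draw `count` exemplars from a pool of size `npool` without immediate
## repetition, refilling a without-replacement bag when exhausted
.drawNoRepeat <- function(npool, count) {
  out <- integer(count)
  bag <- integer(0)
  last <- 0L
  for (i in seq_len(count)) {
    if (!length(bag)) bag <- sample.int(npool)
    if (length(bag) > 1L && bag[1L] == last) bag <- c(bag[-1L], bag[1L])
    out[i] <- bag[1L]
    bag <- bag[-1L]
    last <- out[i]
  }
  out
}

#' Assemble a periodic stimulation sequence
#'
#' Concatenates equal-duration clips back-to-back so that every
#' \code{oddballPeriod}-th sound (0-based index 2 mod 3 for the default
#' period) is drawn from the vocal pool and all others from the non-vocal
#' pool, embeds attenuated attentional targets outside the fade windows,
#' and applies linear fade-in/fade-out gain ramps to the summed waveform.
#' Non-vocal exemplars are drawn without immediate repetition, refilling the
#' pool when exhausted; vocal exemplars are drawn uniformly. Each seed gives
#' a fresh, reproducible pseudo-random order.
#'
#' @param vocal,nonvocal lists of \linkS4class{AudioClip}; all clips must
#'   share the sampling rate and have duration exactly equal to the SOA.
#' @param spec a \linkS4class{SequenceSpec}.
#' @return a \linkS4class{StimulusSequence}.
#' @examples
#' rate <- 8000; n <- rate / 4
#' mk <- function(id, cat) audioClip(rnorm(n, sd = 0.1), rate, cat, id)
#' voc <- lapply(1:4, function(i) mk(paste0("v", i), "vocal"))
#' nvc <- lapply(1:8, function(i) mk(paste0("n", i), "nonvocal"))
#' seqn <- buildSequence(voc, nvc, sequenceSpec(totalDuration = 16, seed = 7))
#' baseFreq(seqn); targetFreq(seqn)
#' @export
buildSequence <- function(vocal, nonvocal, spec) {
  stopifnot(is(spec, "SequenceSpec"), length(vocal) > 0, length(nonvocal) > 0)
  clips <- c(vocal, nonvocal)
  rates <- vapply(clips, samplingRate, numeric(1))
  lens <- vapply(clips, function(cl) length(cl@samples), integer(1))
  if (length(unique(rates)) != 1L)
    stop("all clips must share one sampling rate")
  if (length(unique(lens)) != 1L)
    stop("all clips must have identical duration (= soa)")
  rate <- rates[1]
  nClip <- lens[1]
  if (abs(nClip / rate - spec@soa) > 1e-9)
    stop(sprintf("clip duration %.6g s does not equal soa %.6g s",
                 nClip / rate, spec@soa))
  nEvents <- round(spec@totalDuration / spec@soa)
  if (abs(nEvents * spec@soa - spec@totalDuration) > 1e-6)
    stop("totalDuration must be a whole number of SOAs")

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(spec@seed)

  idx0 <- seq_len(nEvents) - 1L
  isVocal <- (idx0 %% spec@oddballPeriod) == (spec@oddballPeriod - 1L)
  pick <- integer(nEvents)
  pick[isVocal] <- sample.int(length(vocal), sum(isVocal), replace = TRUE)
  pick[!isVocal] <- .drawNoRepeat(length(nonvocal), sum(!isVocal))

  onset <- idx0 * spec@soa
  eligible <- which(onset >= spec@fadeDuration &
                    onset + spec@soa <= spec@totalDuration - spec@fadeDuration)
  if (length(eligible) < spec@nAttentionalTargets)
    stop("not enough non-fade events to place attentional targets")
  targets <- integer(0)
  if (spec@nAttentionalTargets > 0L) {
    for (try in seq_len(1000L)) {
      cand <- sort(sample(eligible, spec@nAttentionalTargets))
      if (spec@nAttentionalTargets == 1L ||
          min(diff(onset[cand])) >= spec@targetSpacing) {
        targets <- cand
        break
      }
    }
    if (!length(targets))
      stop("could not place attentional targets with the requested spacing")
  }

  wave <- numeric(nEvents * nClip)
  ids <- character(nEvents)
  for (i in seq_len(nEvents)) {
    cl <- if (isVocal[i]) vocal[[pick[i]]] else nonvocal[[pick[i]]]
    ids[i] <- cl@id
    s <- cl@samples
    if (i %in% targets) s <- s / spec@attenuationFactor
    wave[((i - 1L) * nClip + 1L):(i * nClip)] <- s
  }
  nf <- round(spec@fadeDuration * rate)
  if (nf > 0) {
    ramp <- seq(0, 1, length.out = nf)
    wave[seq_len(nf)] <- wave[seq_len(nf)] * ramp
    ntot <- length(wave)
    wave[ntot - seq_len(nf) + 1L] <- wave[ntot - seq_len(nf) + 1L] * ramp
  }

  ev <- data.frame(onset = onset, id = ids,
                   category = ifelse(isVocal, "vocal", "nonvocal"),
                   is_target = seq_len(nEvents) %in% targets,
                   stringsAsFactors = FALSE)
  new("StimulusSequence", waveform = wave, rate = rate, events = ev,
      baseFreq = 1 / spec@soa,
      targetFreq = 1 / spec@soa / spec@oddballPeriod,
      soa = spec@soa, oddballPeriod = spec@oddballPeriod)
}
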