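#' @include AllClasses.R stimgen.R
NULL

#' Detection outcome tallies
#'
#' @param nSignal voice-present trial count.
#' @param nNoise voice-absent trial count.
#' @param hits "yes" responses on present trials.
#' @param falseAlarms "yes" responses on absent trials.
#' @return a validated list of the four counts.
#' @export
detectionOutcome <- function(nSignal, nNoise, hits, falseAlarms) {
  stopifnot(nSignal >= 1, nNoise >= 1,
            hits >= 0, hits <= nSignal,
            falseAlarms >= 0, falseAlarms <= nNoise)
  list(nSignal = nSignal, nNoise = nNoise, hits = hits,
       falseAlarms = falseAlarms)
}

#' Sensitivity index d'
#'
#' d' = qnorm(hit rate) - qnorm(false-alarm rate), the bias-free
#' signal-detection measure of voice-detection performance. Extreme rates
#' (0 or 1) are made interior first: \code{"clip"} clips rates to
#' [1/(2N), 1 - 1/(2N)] (default), \code{"loglinear"} uses
#' (count + 0.5)/(N + 1).
#'
#' @param outcome a \code{\link{detectionOutcome}}.
#' @param correction \code{"clip"} or \code{"loglinear"}.
#' @return d' (numeric scalar).
#' @examples
#' dPrime(detectionOutcome(40, 40, 39, 1))
#' @export
dPrime <- function(outcome, correction = c("clip", "loglinear")) {
  correction <- match.arg(correction)
  rate <- function(count, n) {
    switch(correction,
      clip = min(max(count / n, 1 / (2 * n)), 1 - 1 / (2 * n)),
      loglinear = (count + 0.5) / (n + 1))
  }
  hr <- rate(outcome$hits, outcome$nSignal)
  far <- rate(outcome$falseAlarms, outcome$nNoise)
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Build voice-detection trial sets
#'
#' \code{task = "sequence"}: 80 five-sound mini-sequences per condition, 40
#' with one voice (always in position 3, mimicking the oddball structure)
#' and 40 without, in random order. \code{task = "isolation"}: single
#' sounds; 33 vocal + 67 non-vocal for the standard and scrambled
#' conditions (reproducing the 1:2 ratio of the stimulation sequences), and
#' the full 16 + 16 set for the harmonic condition.
#'
#' @param vocalIds,nonvocalIds character identifiers of the available
#'   clips (or lists of \linkS4class{AudioClip}).
#' @param condition \code{"standard"}, \code{"scrambled"} or
#'   \code{"harmonic"}.
#' @param task \code{"sequence"} or \code{"isolation"}.
#' @param seed RNG seed; trial sets are reproducible per seed.
#' @return data.frame with columns trial, condition, task, voice_present,
#'   voice_position (NA when absent) and sounds (semicolon-joined ids).
#' @export
buildBehaviorTrials <- function(vocalIds, nonvocalIds,
                                condition = c("standard", "scrambled",
                                              "harmonic"),
                                task = c("sequence", "isolation"),
                                seed = 1L) {
  condition <- match.arg(condition)
  task <- match.arg(task)
  asIds <- function(x) {
    if (is.list(x)) vapply(x, clipId, character(1)) else as.character(x)
  }
  vocalIds <- asIds(vocalIds); nonvocalIds <- asIds(nonvocalIds)
  stopifnot(length(vocalIds) >= 1, length(nonvocalIds) >= 1)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)

  pickN <- function(pool, n)
    pool[sample.int(length(pool), n, replace = n > length(pool))]

  if (task == "sequence") {
    nPresent <- 40L; nAbsent <- 40L
    present <- sample(rep(c(TRUE, FALSE), c(nPresent, nAbsent)))
    sounds <- vapply(present, function(p) {
      s <- pickN(nonvocalIds, 5L)
      if (p) s[3L] <- pickN(vocalIds, 1L)
      paste(s, collapse = ";")
    }, character(1))
    data.frame(trial = seq_along(present), condition = condition,
               task = task, voice_present = present,
               voice_position = ifelse(present, 3L, NA_integer_),
               sounds = sounds, stringsAsFactors = FALSE)
  } else {
    if (condition == "harmonic") {
      voc <- vocalIds; nvc <- nonvocalIds
    } else {
      voc <- pickN(vocalIds, 33L); nvc <- pickN(nonvocalIds, 67L)
    }
    ids <- c(voc, nvc)
    present <- c(rep(TRUE, length(voc)), rep(FALSE, length(nvc)))
    ord <- sample.int(length(ids))
    data.frame(trial = seq_along(ids), condition = condition, task = task,
               voice_present = present[ord],
               voice_position = ifelse(present[ord], 1L, NA_integer_),
               sounds = ids[ord], stringsAsFactors = FALSE)
  }
}

#' Score yes/no responses against a trial set
#'
#' @param trials a trial data.frame from \code{\link{buildBehaviorTrials}}
#'   (needs a logical \code{voice_present} column).
#' @param responses logical vector ("yes" = voice heard), one per trial.
#' @return a \code{\link{detectionOutcome}}.
#' @export
scoreResponses <- function(trials, responses) {
  if (nrow(trials) != length(responses))
    stop("one response per trial required")
  present <- trials$voice_present
  detectionOutcome(nSignal = sum(present), nNoise = sum(!present),
                   hits = sum(responses[present]),
                   falseAlarms = sum(responses[!present]))
}
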