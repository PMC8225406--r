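#' @include AllClasses.R
NULL

#' Write a sequence event manifest
#'
#' Tab-separated text: onset_s, id, category, is_target.
#'
#' @param x a \linkS4class{StimulusSequence} or an event data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEventManifest <- function(x, path) {
  ev <- if (is(x, "StimulusSequence")) events(x) else x
  out <- data.frame(onset_s = ev$onset, id = ev$id, category = ev$category,
                    is_target = as.integer(ev$is_target))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sequence event manifest
#'
#' @param path path to a manifest written by
#'   \code{\link{writeEventManifest}}.
#' @return data.frame with columns onset, id, category, is_target.
#' @export
readEventManifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(onset = tab$onset_s, id = tab$id, category = tab$category,
             is_target = as.logical(tab$is_target),
             stringsAsFactors = FALSE)
}

#' Write a topography vector as a (label, value) table
#'
#' @param topo named per-channel values.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTopographyTable <- function(topo, path) {
  utils::write.table(
    data.frame(label = names(topo), value = as.numeric(topo)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a spectrum as long-format tab-separated text
#'
#' Columns: freq, channel, value.
#'
#' @param spec an \linkS4class{AmplitudeSpectrum} or
#'   \linkS4class{SNRSpectrum}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSpectrumTable <- function(spec, path) {
  v <- spectralValues(spec)
  out <- data.frame(
    freq = rep(freqs(spec), each = nrow(v)),
    channel = rep(channelLabels(spec), times = ncol(v)),
    value = as.numeric(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read ROI definitions from a plain-text config
#'
#' One ROI per line: \code{name: label1 label2 ...}.
#'
#' @param path file path.
#' @return named list of character label vectors.
#' @export
readRoiDefinitions <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
  out <- list()
  for (ln in lines) {
    p <- strsplit(ln, ":")[[1]]
    if (length(p) != 2) stop("malformed ROI line: ", ln)
    out[[trimws(p[1])]] <- strsplit(trimws(p[2]), "[ \t]+")[[1]]
  }
  out
}
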