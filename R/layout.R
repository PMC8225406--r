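#' @include AllClasses.R
NULL

#' Read an electrode layout table
#'
#' Plain-text table with one electrode per line: \code{label x y z}
#' (whitespace-separated, \code{#} comments allowed). Coordinates are
#' normalized to the unit sphere.
#'
#' @param path file path.
#' @return data.frame with columns label, x, y, z (unit-norm rows).
#' @export
readElectrodeLayout <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$label)) stop("duplicate electrode labels in layout")
  r <- sqrt(tab$x^2 + tab$y^2 + tab$z^2)
  if (any(r == 0)) stop("zero-length electrode position in layout")
  tab$x <- tab$x / r; tab$y <- tab$y / r; tab$z <- tab$z / r
  tab
}

#' The shipped 128-channel scalp layout
#'
#' A 128-electrode unit-sphere layout using the extended 10-05 label set
#' (the labelling convention of the analyses, e.g. TP8h, CP6, C6, T8),
#' equivalent in coverage to a 128-channel active-electrode cap.
#'
#' @return data.frame with columns label, x, y, z.
#' @export
defaultLayout <- function() {
  readElectrodeLayout(system.file("extdata", "layout_128ch_1005.txt",
                                  package = "fpas", mustWork = TRUE))
}
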