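#' @include AllClasses.R
NULL

## ---- simple documented container for synthetic data ------------------------
## A text header (key: value lines, then an EVENTS block, then DATA) followed
## by a little-endian float64 body, channels interleaved by sample.

#' Write an EEG recording to the package container
#'
#' Plain-text header (rate, channel labels, events) followed by a
#' little-endian float64 body, sample-major. A simple, documented format
#' for moving synthetic recordings between tools.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEEGContainer <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "FPASEEG 1",
    sprintf("rate: %.10g", samplingRate(rec)),
    sprintf("channels: %s", paste(channelLabels(rec), collapse = "\t")),
    sprintf("samples: %d", ncol(channelData(rec))),
    "events:",
    sprintf("  %.9g\t%d", events(rec)$onset, as.integer(events(rec)$code)),
    "data: float64le sample-major")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(channelData(rec)), con, 8, endian = "little")
  invisible(path)
}

#' Read a recording written by \code{\link{writeEEGContainer}}
#'
#' @param path file path.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEEGContainer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readLine <- function() {
    out <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch) || !nzchar(ch) || ch == "\n") break
      out <- c(out, ch)
    }
    paste(out, collapse = "")
  }
  if (readLine() != "FPASEEG 1") stop("not an FPASEEG container")
  rate <- NULL; labs <- NULL; nsamp <- NULL
  ev <- data.frame(onset = numeric(), code = integer())
  repeat {
    ln <- readLine()
    if (grepl("^rate:", ln)) rate <- as.numeric(sub("^rate: *", "", ln))
    else if (grepl("^channels:", ln))
      labs <- strsplit(sub("^channels: *", "", ln), "\t")[[1]]
    else if (grepl("^samples:", ln))
      nsamp <- as.integer(sub("^samples: *", "", ln))
    else if (grepl("^  ", ln)) {
      p <- strsplit(trimws(ln), "\t")[[1]]
      ev <- rbind(ev, data.frame(onset = as.numeric(p[1]),
                                 code = as.integer(p[2])))
    } else if (grepl("^data:", ln)) break
    else if (ln == "events:") next
    else if (!nzchar(ln)) stop("truncated container header")
  }
  mat <- matrix(readBin(con, "double", length(labs) * nsamp, 8,
                        endian = "little"), nrow = length(labs))
  eegRecording(mat, rate, labs, ev)
}

## ---- BDF (24-bit EDF-style) -----------------------------------------------

.padfield <- function(x, width) {
  s <- substr(format(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a BDF (24-bit EDF-style) file
#'
#' One-second data records; sample values are stored as 24-bit integers
#' with a physical range of +/-32768 uV (resolution ~1/256 uV). Events are
#' encoded in an appended Status channel carrying the event code at its
#' onset sample.
#'
#' @param rec an \linkS4class{EEGRecording}; the rate must be an integer
#'   and the sample count a whole number of seconds.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBdf <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  rate <- samplingRate(rec)
  if (abs(rate - round(rate)) > 1e-9) stop("BDF needs an integer rate")
  rate <- round(rate)
  mat <- channelData(rec)
  n <- ncol(mat)
  if (n %% rate != 0) stop("BDF needs a whole number of 1-s records")
  nrec <- n %/% rate
  status <- numeric(n)
  ev <- events(rec)
  if (nrow(ev)) status[round(ev$onset * rate) + 1L] <- ev$code
  labs <- c(channelLabels(rec), "Status")
  all <- rbind(mat, status)
  nch <- nrow(all)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(255L), con)
  writeChar(.padfield("BIOSEMI", 7), con, eos = NULL)
  writeChar(.padfield("synthetic", 80), con, eos = NULL)       # patient
  writeChar(.padfield("fpas", 80), con, eos = NULL)            # recording
  writeChar(.padfield("01.01.00", 8), con, eos = NULL)
  writeChar(.padfield("00.00.00", 8), con, eos = NULL)
  writeChar(.padfield((nch + 1L) * 256L, 8), con, eos = NULL)
  writeChar(.padfield("24BIT", 44), con, eos = NULL)
  writeChar(.padfield(nrec, 8), con, eos = NULL)
  writeChar(.padfield(1, 8), con, eos = NULL)
  writeChar(.padfield(nch, 4), con, eos = NULL)
  wf <- function(vals, width)
    for (v in vals) writeChar(.padfield(v, width), con, eos = NULL)
  wf(labs, 16)
  wf(rep("synthetic", nch), 80)
  wf(rep("uV", nch), 8)
  wf(rep(-32768, nch), 8)
  wf(rep(32768, nch), 8)
  wf(rep(-8388608, nch), 8)
  wf(rep(8388607, nch), 8)
  wf(rep("none", nch), 80)
  wf(rep(rate, nch), 8)
  wf(rep("", nch), 32)

  gain <- (32768 - (-32768)) / (8388607 - (-8388608))
  dig <- round(all / gain)
  dig <- pmax(pmin(dig, 8388607), -8388608)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    v <- as.vector(t(dig[, idx, drop = FALSE]))  # channel-major within record
    u <- ifelse(v < 0, v + 16777216, v)
    b <- integer(3 * length(u))
    b[seq(1, by = 3, length.out = length(u))] <- u %% 256
    b[seq(2, by = 3, length.out = length(u))] <- (u %/% 256) %% 256
    b[seq(3, by = 3, length.out = length(u))] <- (u %/% 65536) %% 256
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a BDF (24-bit EDF-style) file
#'
#' Parses the header, scales digital values to physical units and, when a
#' Status channel is present, converts its nonzero samples to events.
#'
#' @param path file path.
#' @return an \linkS4class{EEGRecording}.
#' @export
readBdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 1)
  if (as.integer(magic) != 255L) stop("not a BDF file")
  rf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  if (rf(7) != "BIOSEMI") stop("not a BDF file")
  rf(80); rf(80); rf(8); rf(8); rf(8); rf(44)
  nrec <- as.integer(rf(8))
  recdur <- as.numeric(rf(8))
  nch <- as.integer(rf(4))
  labs <- vapply(seq_len(nch), function(i) rf(16), character(1))
  for (i in seq_len(nch)) rf(80)
  for (i in seq_len(nch)) rf(8)
  physMin <- vapply(seq_len(nch), function(i) as.numeric(rf(8)), numeric(1))
  physMax <- vapply(seq_len(nch), function(i) as.numeric(rf(8)), numeric(1))
  digMin <- vapply(seq_len(nch), function(i) as.numeric(rf(8)), numeric(1))
  digMax <- vapply(seq_len(nch), function(i) as.numeric(rf(8)), numeric(1))
  for (i in seq_len(nch)) rf(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rf(8)), integer(1))
  for (i in seq_len(nch)) rf(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel rates are not supported")
  rate <- spr[1] / recdur
  gain <- (physMax - physMin) / (digMax - digMin)
  mat <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    b <- as.integer(readBin(con, "raw", 3 * nch * spr[1]))
    n3 <- length(b) / 3
    v <- b[seq(1, by = 3, length.out = n3)] +
      b[seq(2, by = 3, length.out = n3)] * 256L +
      b[seq(3, by = 3, length.out = n3)] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    vm <- matrix(v, nrow = spr[1])                # samples x channels
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    mat[, idx] <- t(vm)
  }
  mat <- mat * gain + (physMin - digMin * gain)
  ev <- data.frame(onset = numeric(), code = integer())
  si <- match("Status", labs)
  if (!is.na(si)) {
    codes <- round(mat[si, ])
    on <- which(codes != 0)
    ev <- data.frame(onset = (on - 1L) / rate, code = as.integer(codes[on]))
    mat <- mat[-si, , drop = FALSE]
    labs <- labs[-si]
  }
  eegRecording(mat, rate, labs, ev)
}
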