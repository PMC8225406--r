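#' @include AllClasses.R
NULL

## Minimal RIFF/WAVE support, mono, PCM16/PCM24/IEEE float32.

#' Read a mono WAV file
#'
#' Supports 16- and 24-bit PCM and 32-bit IEEE float, mono. Integer
#' samples are scaled to [-1, 1).
#'
#' @param path file path.
#' @param category,id metadata for the returned clip.
#' @return an \linkS4class{AudioClip}.
#' @export
readWav <- function(path, category = "nonvocal", id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id4 <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id4)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id4 == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little"),
        nChannels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id4 == "data") {
      data <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt or data chunk")
  if (fmt$nChannels != 1) stop("only mono WAV is supported")
  x <- switch(as.character(fmt$audioFormat),
    "1" = {
      if (fmt$bits == 16) {
        readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24) {
        b <- as.integer(data)
        n <- length(b) / 3
        v <- b[seq(1, by = 3, length.out = n)] +
          b[seq(2, by = 3, length.out = n)] * 256L +
          b[seq(3, by = 3, length.out = n)] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data, "double", length(data) / 4, 4, endian = "little"),
    stop("unsupported WAV format code: ", fmt$audioFormat))
  audioClip(x, fmt$rate, category = category, id = id)
}

#' Write a mono WAV file
#'
#' @param clip an \linkS4class{AudioClip} (or numeric vector with
#'   \code{rate}).
#' @param path output path.
#' @param bitDepth 16 or 24 (PCM) or \code{"float32"}.
#' @param rate required when \code{clip} is a bare numeric vector.
#' @return invisibly, the path.
#' @export
writeWav <- function(clip, path, bitDepth = 16, rate = NULL) {
  if (is(clip, "AudioClip")) {
    x <- clip@samples; rate <- clip@rate
  } else {
    x <- as.numeric(clip)
    if (is.null(rate)) stop("rate required for a bare waveform")
  }
  isFloat <- identical(bitDepth, "float32")
  bits <- if (isFloat) 32L else as.integer(bitDepth)
  if (!isFloat && !bits %in% c(16L, 24L)) stop("bitDepth must be 16, 24 or 'float32'")
  bytes <- bits / 8L
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (isFloat) 3L else 1L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, 4, endian = "little")
  if (isFloat) {
    writeBin(x, con, 4, endian = "little")
  } else if (bits == 16L) {
    v <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    v <- pmax(pmin(round(x * 8388608), 8388607), -8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- integer(3 * n)
    b[seq(1, by = 3, length.out = n)] <- v %% 256
    b[seq(2, by = 3, length.out = n)] <- (v %/% 256) %% 256
    b[seq(3, by = 3, length.out = n)] <- (v %/% 65536) %% 256
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
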