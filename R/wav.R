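#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for the package's synthetic voices.  The
#' waveform is rescaled only if it exceeds the [-1, 1] full-scale range.
#'
#' @param x numeric vector, nominally in [-1, 1].
#' @param path output file path.
#' @param fs sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs) {
  fs <- as.integer(round(check_scalar(fs, "fs", lower = 1)))
  peak <- max(abs(x), 1)
  pcm <- as.integer(round(pmax(pmin(x / peak, 1), -1) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(2L * fs, con, size = 4, endian = "little")     # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path input file path.
#' @return list with `samples` (numeric in [-1, 1]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; n_channels <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1L] != 1L) stop("only PCM WAV is supported")
      n_channels <- fmt[2L]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM is supported")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(fs)) stop("no fmt chunk found in ", path)
  if (n_channels > 1L) {
    pcm <- matrix(pcm, nrow = n_channels)
    pcm <- colMeans(pcm)
  }
  list(samples = as.numeric(pcm) / 32768, fs = as.numeric(fs))
}
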