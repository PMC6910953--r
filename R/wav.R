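#' Read a mono PCM WAV file
#'
#' Minimal reader for RIFF/WAVE files containing 16-bit integer PCM.
#' Returns the waveform as a numeric vector scaled to \code{[-1, 1]} with the
#' sample rate attached as an attribute.
#'
#' @param path Path to a \code{.wav} file.
#' @param channel Channel to extract if the file is multi-channel. By default
#'   multi-channel files are an error, because silently mixing or picking a
#'   channel would change the signal under analysis.
#' @return Numeric vector of samples in \code{[-1, 1]} with attribute
#'   \code{sample_rate} (Hz).
#' @seealso [write_wav()], [load_and_normalize()]
#' @export
read_wav <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1L, size = 4L,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$audio_format != 1L || fmt$bits != 16L)
    stop("only 16-bit integer PCM WAV is supported")

  samples <- readBin(data_raw, "integer", length(data_raw) / 2L,
                     size = 2L, endian = "little")
  if (fmt$n_channels > 1L) {
    if (is.null(channel)) {
      stop("multi-channel WAV: pass `channel` to select one explicitly")
    }
    samples <- samples[seq(channel, length(samples), by = fmt$n_channels)]
  }
  x <- samples / 32768
  attr(x, "sample_rate") <- fmt$sample_rate
  x
}

#' Write a mono PCM WAV file
#'
#' Writes a numeric waveform in \code{[-1, 1]} as 16-bit integer PCM.
#'
#' @param x Numeric vector of samples; values outside \code{[-1, 1]} are
#'   clipped.
#' @param path Output path.
#' @param sample_rate Sample rate in Hz.
#' @return The path, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 16000L) {
  samples <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  n_bytes <- length(samples) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")           # block align
  writeBin(16L, con, size = 2L, endian = "little")          # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(samples, con, size = 2L, endian = "little")
  invisible(path)
}
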