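#' Read and write mono PCM16 WAV files
#'
#' Minimal RIFF/WAVE codec for the single format this package produces and
#' consumes: uncompressed PCM, 16-bit, one channel. Samples are exchanged
#' as doubles in \[-1, 1\] and scaled by 32767.
#'
#' @param samples numeric vector in \[-1, 1\]; values outside are clipped.
#' @param path file path.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   list with elements `samples` (doubles in \[-1, 1\]) and
#'   `sampling_rate_hz`.
#' @export
write_wav <- function(samples, path, sampling_rate_hz = 250000L) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)                       # PCM fmt chunk size
  w16(1L)                        # audio format: PCM
  w16(1L)                        # channels
  w32(sampling_rate_hz)
  w32(sampling_rate_hz * 2L)     # byte rate
  w16(2L)                        # block align
  w16(16L)                       # bits per sample
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV is supported: ", path)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", size - 8L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little")
      return(list(samples = pcm / 32767, sampling_rate_hz = fs))
    } else {
      readBin(con, "raw", size)
    }
  }
}
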