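# Minimal mono 16-bit PCM WAV reader/writer for audio streams, templates
# and feedback clips. (No audio package is shipped with the target R
# stacks, and the canonical PCM container is simple enough to support
# directly.)

#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to [-1, 1] and quantized to 16 bits.
#'
#' @param x Samples in [-1, 1]. @param path Output file. @param rate Sample
#'   rate, Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate) {
  pcm <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(pcm) * 2L
  w_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w_int(36L + n_data, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_int(16L, 4); w_int(1L, 2); w_int(1L, 2)        # PCM, mono
  w_int(as.integer(rate), 4)
  w_int(as.integer(rate) * 2L, 4)                  # byte rate
  w_int(2L, 2); w_int(16L, 2)                      # block align, bits
  writeChar("data", con, eos = NULL)
  w_int(n_data, 4)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file written by [write_wav()] or any mono 16-bit PCM
#'   writer.
#' @return List: `x` (samples in [-1, 1]), `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV is supported")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      ba_bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit PCM WAV is supported")
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      x <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little") / 32767
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(rate) && !is.null(x)) break
  }
  if (is.null(rate) || is.null(x)) stop("malformed WAV file: ", path)
  list(x = x, rate = rate)
}
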