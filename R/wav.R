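# Minimal RIFF/WAVE PCM reader and writer.
#
# The environment ships no WAV-capable package, and the format needed here is
# narrow: RIFF with a fmt chunk (PCM integer or IEEE float) and a data chunk.
# Unknown chunks are skipped. Samples are returned as doubles in [-1, 1].

#' Read a RIFF WAV file
#'
#' Reads a PCM WAV file (8/16/24/32-bit integer or 32/64-bit IEEE float) and
#' returns the samples scaled to `[-1, 1]` together with the sampling rate and
#' channel count. Multi-channel data is returned as a matrix with one column
#' per channel.
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `samples` (numeric vector, or matrix for
#'   multi-channel files), `fs` (sampling rate in Hz) and `n_channels`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    ms_abort(paste0("WAV file not found: ", path), "format")
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    ms_abort(paste0("not a RIFF file: ", path), "format")
  }
  readBin(con, "integer", 1, 4, endian = "little") # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    ms_abort(paste0("not a WAVE file: ", path), "format")
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(chunk[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(chunk[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        fs           = readBin(chunk[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(chunk[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2) # skip chunk (word aligned)
      next
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }

  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0) {
    ms_abort(paste0("unreadable or empty WAV file: ", path), "format")
  }
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; treat per its bit depth.
  if (!fmt$audio_format %in% c(1L, 3L, 65534L)) {
    ms_abort(paste0("unsupported WAV encoding (format tag ", fmt$audio_format, ")"), "format")
  }

  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                               signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                              signed = TRUE, endian = "little")) / 32768,
    "24" = wav_int24(data_raw) / 8388608,
    "32" = if (fmt$audio_format == 3L) {
      as.numeric(readBin(data_raw, "double", length(data_raw) %/% 4, 4, endian = "little"))
    } else {
      as.numeric(readBin(data_raw, "integer", length(data_raw) %/% 4, 4,
                         endian = "little")) / 2147483648
    },
    "64" = as.numeric(readBin(data_raw, "double", length(data_raw) %/% 8, 8, endian = "little")),
    ms_abort(paste0("unsupported WAV bit depth: ", fmt$bits), "format")
  )

  nch <- fmt$n_channels
  if (nch > 1) {
    n <- (length(x) %/% nch) * nch
    x <- matrix(x[seq_len(n)], nrow = nch)
    x <- t(x)
  }
  list(samples = x, fs = fmt$fs, n_channels = nch)
}

wav_int24 <- function(raw) {
  n <- length(raw) %/% 3
  b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
  v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write a mono WAV file
#'
#' Writes a numeric vector as a 16-bit PCM mono RIFF WAV file. Samples are
#' clipped to `[-1, 1]` before quantization.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  q <- as.integer(pmax(-32768, pmin(32767, round(pmax(-1, pmin(1, samples)) * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
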