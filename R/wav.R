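# Minimal RIFF/WAV reader and writer. Supports the formats produced by
# ordinary recorders: PCM integer (8/16/24/32 bit) and IEEE float (32/64 bit),
# mono or multichannel. All amplitudes are normalized to [-1, 1] on read; the
# segmentation math is amplitude-scale invariant, so normalization is harmless.

#' Read a WAV file
#'
#' Reads a RIFF/WAV file (PCM 8/16/24/32-bit integer or 32/64-bit IEEE float)
#' and returns a [seg_signal()] with amplitudes normalized to `[-1, 1]`.
#' Multichannel input is averaged to mono. The sampling rate is taken from
#' the file header.
#'
#' @param path path to a WAV file.
#' @return A [seg_signal()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little"),
        channels = readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little"),
        fs       = readBin(con, integer(), 1, size = 4, endian = "little"),
        byte_rate   = readBin(con, integer(), 1, size = 4, endian = "little"),
        block_align = readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little"),
        bits     = readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little")
      )
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, raw(), extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), size)
      if (size %% 2 == 1) invisible(readBin(con, raw(), 1))
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, raw(), size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV file (missing fmt/data chunk): ", path)
  }
  if (!fmt$format %in% c(1L, 3L)) {
    stop("unsupported WAV format code ", fmt$format, " in ", path)
  }

  x <- decode_wav_samples(data_raw, fmt$format, fmt$bits)
  ch <- fmt$channels
  if (ch > 1) {
    n_frames <- length(x) %/% ch
    x <- colMeans(matrix(x[seq_len(n_frames * ch)], nrow = ch))
  }
  seg_signal(x, fs = fmt$fs)
}

decode_wav_samples <- function(raw_bytes, format, bits) {
  if (format == 3L) {
    size <- bits %/% 8
    if (!size %in% c(4L, 8L)) stop("unsupported float WAV bit depth: ", bits)
    return(readBin(raw_bytes, numeric(), length(raw_bytes) %/% size,
                   size = size, endian = "little"))
  }
  switch(as.character(bits),
    "8" = {
      u <- as.integer(raw_bytes)  # unsigned convention for 8-bit PCM
      (u - 128) / 128
    },
    "16" = {
      v <- readBin(raw_bytes, integer(), length(raw_bytes) %/% 2,
                   size = 2, signed = TRUE, endian = "little")
      v / 32768
    },
    "24" = {
      n <- length(raw_bytes) %/% 3
      b <- matrix(as.integer(raw_bytes[seq_len(n * 3)]), nrow = 3)
      u <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      u <- ifelse(u >= 2^23, u - 2^24, u)
      u / 2^23
    },
    "32" = {
      v <- readBin(raw_bytes, integer(), length(raw_bytes) %/% 4,
                   size = 4, endian = "little")
      v / 2^31
    },
    stop("unsupported PCM WAV bit depth: ", bits)
  )
}

#' Write a WAV file
#'
#' Writes a mono PCM WAV file. Amplitudes outside `[-1, 1]` are clipped, with
#' a warning reporting how many samples were affected.
#'
#' @param x a [seg_signal()] or numeric vector of amplitudes in `[-1, 1]`.
#' @param path output file path.
#' @param fs sampling rate in Hz; defaults to the signal's own rate.
#' @param bit_depth PCM bit depth: 8, 16 (default), 24 or 32.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL, bit_depth = 16) {
  fs <- signal_fs(x, fs)
  y <- as_samples(x)
  if (any(!is.finite(y))) stop("signal samples must be finite")
  if (!bit_depth %in% c(8, 16, 24, 32)) {
    stop("'bit_depth' must be one of 8, 16, 24, 32")
  }
  n_clip <- sum(y < -1 | y > 1)
  if (n_clip > 0) {
    warning(sprintf("%d sample(s) clipped to [-1, 1] while writing %s",
                    n_clip, path))
    y <- pmin(pmax(y, -1), 1)
  }

  scale <- 2^(bit_depth - 1)
  v <- pmin(round(y * scale), scale - 1)  # +1.0 maps to the largest code
  n <- length(v)
  bytes_per <- bit_depth %/% 8
  data_size <- n * bytes_per

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write WAV file: ", path))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  if (bit_depth == 8) {
    writeBin(as.raw(v + 128), con)
  } else if (bit_depth == 24) {
    u <- ifelse(v < 0, v + 2^24, v)
    b <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
    writeBin(as.raw(b), con)
  } else {
    writeBin(as.integer(v), con, size = bytes_per, endian = "little")
  }
  invisible(path)
}
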