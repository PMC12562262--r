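#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for mono recordings stored as 16-bit PCM
#' (format code 1) or 32/64-bit IEEE float (format code 3). Heart-sound
#' corpora such as PhysioNet 2016/2022 ship 16-bit PCM mono files, which is
#' the layout this reader targets. Samples are returned as doubles in
#' [-1, 1] for PCM input.
#'
#' @param path Path to a `.wav` file.
#' @param target_rate If non-`NULL` and the file's sample rate differs,
#'   the signal is resampled (polyphase, [signal::resample()]) to this rate.
#' @return A list with `samples` (double vector) and `rate` (Hz).
#' @export
read_wav <- function(path, target_rate = NULL) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        code       = readBin(raw_fmt[1:2], "integer", 1, size = 2, endian = "little"),
        channels   = readBin(raw_fmt[3:4], "integer", 1, size = 2, endian = "little"),
        rate       = readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little"),
        bits       = readBin(raw_fmt[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path, call. = FALSE)
      if (fmt$channels != 1L) {
        stop("only mono WAV supported, got ", fmt$channels, " channels: ", path,
             call. = FALSE)
      }
      if (fmt$code == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        x <- readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little")
        samples <- x / 32768
      } else if (fmt$code == 3L && fmt$bits %in% c(32L, 64L)) {
        bytes <- fmt$bits %/% 8L
        samples <- readBin(con, "double", size %/% bytes, size = bytes,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$code, ", ", fmt$bits,
             " bit): ", path, call. = FALSE)
      }
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk in WAV: ", path, call. = FALSE)

  rate <- fmt$rate
  if (!is.null(target_rate) && rate != target_rate) {
    samples <- as.numeric(signal::resample(samples, p = target_rate, q = rate))
    rate <- target_rate
  }
  list(samples = samples, rate = rate)
}

#' Write a mono WAV file
#'
#' Writes samples as 16-bit PCM (values clipped to [-1, 1]) or 32-bit IEEE
#' float.
#'
#' @param samples Double vector of amplitudes.
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16L) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32", call. = FALSE)
  bytes <- bits %/% 8L
  data_size <- length(samples) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  code <- if (bits == 16L) 1L else 3L
  writeBin(code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")   # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    x <- pmax(pmin(samples, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}
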