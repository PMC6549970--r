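#' Waveform container
#'
#' A waveform is a mono amplitude sequence with a sample rate. Samples are
#' dimensionless (full scale roughly \[-1, 1\] for rendered audio).
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `waveform`: list with `samples`, `sample_rate`.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read a RIFF WAV file
#'
#' Reads PCM (8/16/24/32-bit integer) or IEEE float (32/64-bit) WAV audio.
#' Stereo or multi-channel input is averaged across channels with a warning;
#' samples are scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format == 65534) fmt$audio_format <- 1  # WAVE_FORMAT_EXTENSIBLE, assume PCM

  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3) {
    readBin(data_raw, "double", n, bytes, endian = "little")
  } else if (fmt$audio_format == 1) {
    if (fmt$bits == 8) {
      (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 16) {
      readBin(data_raw, "integer", n, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n, 4, endian = "little") / 2^31
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)

  if (fmt$n_channels > 1) {
    warning("multi-channel WAV (", fmt$n_channels,
            " channels): averaging to mono")
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  waveform(x, fmt$sample_rate)
}

#' Write a RIFF WAV file
#'
#' @param w A [waveform()]; samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @param bits Bit depth, 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 32))
  x <- pmin(1, pmax(-1, w$samples))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes <- bits %/% 8
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmt_code <- if (bits == 32) 3L else 1L
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(w$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(w$sample_rate * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmin(32767, pmax(-32768, round(x * 32768)))),
             con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
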