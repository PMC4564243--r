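#' Sampled audio recording
#'
#' A minimal container for mono sampled audio: a numeric vector of amplitudes
#' normalized to `[-1, 1]` plus its sampling rate in Hz. Every stage of the
#' pipeline (synthesis, spectrograms, click detection) consumes and produces
#' this type.
#'
#' @param samples Numeric vector of amplitudes, nominally within `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param start_offset Time of the first sample in seconds (default 0); carried
#'   through so annotations in absolute file time stay aligned.
#' @return An object of class `wave_recording`.
#' @examples
#' rec <- wave_recording(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' rec
#' @export
wave_recording <- function(samples, sample_rate, start_offset = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("empty recording", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, start_offset = start_offset),
    class = "wave_recording"
  )
}

#' @export
print.wave_recording <- function(x, ...) {
  cat(sprintf(
    "<wave_recording: %d samples @ %g Hz (%.3f s)>\n",
    length(x$samples), x$sample_rate, length(x$samples) / x$sample_rate
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [wave_recording()].
#' @return Length in seconds.
#' @export
wave_duration <- function(recording) {
  length(recording$samples) / recording$sample_rate
}

# --- RIFF/WAVE PCM reader & writer -------------------------------------------
# Plain little-endian PCM only (format tag 1), 16- or 24-bit, as written by the
# field recorders the pipeline targets. Other codecs raise a format error that
# names the format tag.

#' Read a PCM WAV file
#'
#' Reads 16- or 24-bit integer PCM RIFF/WAVE files. Samples are scaled to
#' `[-1, 1]` by the full-scale integer of the bit depth. Multi-channel files
#' are reduced to channel 1 with a warning.
#'
#' @param path Path to a `.wav` file.
#' @return A [wave_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) {
      stop("truncated WAV file (no data chunk): ", path, call. = FALSE)
    }
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) stop("truncated WAV header: ", path, call. = FALSE)
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      if (length(fmt_raw) < 16) stop("truncated fmt chunk: ", path, call. = FALSE)
      u16 <- function(i) sum(as.integer(fmt_raw[i + 0:1]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(fmt_raw[i + 0:3]) * 256^(0:3))
      fmt <- list(
        tag = u16(1), channels = u16(3), rate = u32(5), bits = u16(15)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk", call. = FALSE)
      if (fmt$tag != 1L) {
        stop(sprintf("unsupported WAV codec (format tag %d); only PCM is supported", fmt$tag),
             call. = FALSE)
      }
      if (!fmt$bits %in% c(16L, 24L)) {
        stop(sprintf("unsupported PCM bit depth %d; expected 16 or 24", fmt$bits),
             call. = FALSE)
      }
      bytes_per <- fmt$bits / 8L
      n_total <- sz %/% bytes_per
      if (fmt$bits == 16L) {
        x <- readBin(con, "integer", n_total, size = 2, signed = TRUE, endian = "little")
        x <- x / 2^15
      } else {
        raw3 <- readBin(con, "raw", n_total * 3L)
        n_total <- length(raw3) %/% 3L
        b <- matrix(as.numeric(raw3[seq_len(n_total * 3L)]), nrow = 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        x <- v / 2^23
      }
      if (length(x) < 1) stop("WAV file contains no samples: ", path, call. = FALSE)
      if (fmt$channels > 1L) {
        warning(sprintf("%d channels found; using channel 1", fmt$channels))
        x <- x[seq(1, length(x), by = fmt$channels)]
      }
      return(wave_recording(x, fmt$rate))
    } else {
      skipped <- readBin(con, "raw", sz)
      if (length(skipped) < sz) stop("truncated WAV chunk '", id, "': ", path, call. = FALSE)
    }
  }
}

#' Write a PCM WAV file
#'
#' Writes a [wave_recording()] as mono integer PCM. Samples outside `[-1, 1]`
#' are clipped with a warning. Round-tripping through [read_wav()] reproduces
#' the samples within one quantization step of the chosen bit depth.
#'
#' @param recording A [wave_recording()].
#' @param path Output path.
#' @param bit_depth 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, bit_depth = 16) {
  stopifnot(inherits(recording, "wave_recording"))
  if (!bit_depth %in% c(16, 24)) stop("bit_depth must be 16 or 24", call. = FALSE)
  x <- recording$samples
  if (length(x) < 1) stop("empty recording", call. = FALSE)
  if (any(x > 1 | x < -1)) {
    warning("samples outside [-1, 1] clipped")
    x <- pmin(1, pmax(-1, x))
  }
  fs <- round(recording$sample_rate)
  n <- length(x)
  bytes_per <- bit_depth / 8L
  data_sz <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")

  wch("RIFF"); w32(36 + data_sz); wch("WAVE")
  wch("fmt "); w32(16)
  w16(1); w16(1)              # PCM, mono
  w32(fs); w32(fs * bytes_per) # byte rate
  w16(bytes_per); w16(bit_depth)
  wch("data"); w32(data_sz)

  full <- 2^(bit_depth - 1)
  q <- as.integer(pmin(pmax(round(x * full), -full), full - 1))
  if (bit_depth == 16) {
    writeBin(q, con, size = 2, endian = "little")
  } else {
    v <- ifelse(q < 0, q + 2^24, q)
    b1 <- v %% 256; b2 <- (v %/% 256) %% 256; b3 <- (v %/% 65536) %% 256
    writeBin(as.raw(rbind(b1, b2, b3)), con)
  }
  invisible(path)
}
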