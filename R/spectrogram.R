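#' Spectrogram parameters
#'
#' STFT parameterization matching the study conventions: Hamming window, 50%
#' overlap, no zero padding, no detrending. The default `nfft = 512` at 96 kHz
#' gives a 187.5 Hz bin width and a 2.67 ms hop.
#'
#' @param nfft Window/FFT length in samples (positive even integer).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `spectrogram_params`.
#' @export
spectrogram_params <- function(nfft = 512, overlap = 0.5, sample_rate = 96000) {
  stopifnot(nfft > 0, nfft %% 2 == 0, overlap >= 0, overlap < 1, sample_rate > 0)
  structure(list(nfft = as.integer(nfft), overlap = overlap,
                 window = "hamming", sample_rate = sample_rate),
            class = "spectrogram_params")
}

#' Compute a power spectrogram
#'
#' One-sided short-time power spectrogram with a Hamming window. Frame `k`
#' (0-based) covers samples `[k*hop, k*hop + nfft)` with
#' `hop = nfft * (1 - overlap)`; its time stamp is the centre of that span.
#' Power is stored both linearly (for SNR arithmetic) and in dB relative to the
#' spectrogram maximum (for display and thresholding; the recordings carry no
#' absolute calibration).
#'
#' @param recording A [wave_recording()] at least `nfft` samples long.
#' @param params A [spectrogram_params()]; its `sample_rate` is overridden by
#'   the recording's.
#' @return An object of class `orca_spectrogram` with fields `power` (dB re
#'   max, frames x bins), `linear` (linear power), `frame_times` (s),
#'   `bin_freqs` (Hz) and `params`.
#' @export
compute_spectrogram <- function(recording, params = spectrogram_params()) {
  stopifnot(inherits(recording, "wave_recording"),
            inherits(params, "spectrogram_params"))
  x <- recording$samples
  nfft <- params$nfft
  if (length(x) < nfft) {
    stop(sprintf("recording (%d samples) shorter than nfft (%d)", length(x), nfft),
         call. = FALSE)
  }
  fs <- recording$sample_rate
  params$sample_rate <- fs
  hop <- round(nfft * (1 - params$overlap))
  n_frames <- (length(x) - nfft) %/% hop + 1
  w <- as.numeric(signal::hamming(nfft))

  starts <- (seq_len(n_frames) - 1) * hop
  frames <- matrix(x[outer(seq_len(nfft), starts, "+")], nrow = nfft) * w
  spec <- stats::mvfft(frames)
  n_bins <- nfft %/% 2 + 1
  p <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  p <- t(p) # frames x bins

  pmax_ <- max(p)
  db <- 10 * log10(pmax(p, pmax_ * 1e-20) / pmax_)
  structure(list(
    power = db,
    linear = p,
    frame_times = (starts + nfft / 2) / fs + recording$start_offset,
    bin_freqs = (seq_len(n_bins) - 1) * fs / nfft,
    params = params
  ), class = "orca_spectrogram")
}

#' @export
print.orca_spectrogram <- function(x, ...) {
  cat(sprintf("<orca_spectrogram: %d frames x %d bins, %.1f Hz bins, hop %.2f ms>\n",
              nrow(x$power), ncol(x$power), x$bin_freqs[2] - x$bin_freqs[1],
              1000 * diff(x$frame_times[1:2])))
  invisible(x)
}

#' Plot a spectrogram
#'
#' @param object An `orca_spectrogram`.
#' @param floor_db Dynamic-range floor in dB re max (default -70).
#' @param ... Unused.
#' @return A ggplot object (time in s, frequency in kHz, power in dB re max).
#' @export
autoplot.orca_spectrogram <- function(object, floor_db = -70, ...) {
  df <- expand.grid(time = object$frame_times, freq = object$bin_freqs / 1000)
  df$db <- pmax(as.vector(object$power), floor_db)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB re max") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (kHz)") +
    ggplot2::theme_minimal()
}
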