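#' Frequency contour specification
#'
#' Defines the fundamental frequency track of a synthetic call as breakpoints
#' `(time s, frequency kHz)` joined by linear or cubic-spline interpolation.
#' Times must be strictly increasing and start at 0; frequencies positive.
#'
#' @param times Breakpoint times in seconds, starting at 0.
#' @param freqs_khz Breakpoint frequencies in kHz.
#' @param interpolation `"linear"` or `"cubic"`.
#' @return An object of class `contour_spec`.
#' @export
contour_spec <- function(times, freqs_khz, interpolation = c("linear", "cubic")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(times) == length(freqs_khz), length(times) >= 2)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("breakpoint times must be strictly increasing and start at 0", call. = FALSE)
  }
  if (any(freqs_khz <= 0)) stop("contour frequencies must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), freqs_khz = as.numeric(freqs_khz),
                 interpolation = interpolation),
            class = "contour_spec")
}

#' Evaluate a contour at given times
#' @param spec A [contour_spec()].
#' @param t Times (s) within the contour's span.
#' @return Instantaneous frequency in kHz at `t`.
#' @export
contour_frequency <- function(spec, t) {
  if (spec$interpolation == "linear") {
    stats::approx(spec$times, spec$freqs_khz, xout = t, rule = 2)$y
  } else {
    f <- stats::splinefun(spec$times, spec$freqs_khz, method = "natural")
    pmax(f(t), min(spec$freqs_khz) * 0.1)
  }
}

#' @export
print.contour_spec <- function(x, ...) {
  cat(sprintf("<contour_spec: %d breakpoints, %.3f s, %.2f-%.2f kHz, %s>\n",
              length(x$times), max(x$times), min(x$freqs_khz), max(x$freqs_khz),
              x$interpolation))
  invisible(x)
}

# Phase-integration oscillator: clean instantaneous frequency, no segment-join
# discontinuities. f_inst in Hz at each sample.
phase_osc <- function(f_inst_hz, sample_rate) {
  phase <- 2 * pi * cumsum(f_inst_hz) / sample_rate
  sin(phase)
}

#' Synthesize a frequency-modulated tonal whistle
#'
#' Generates a tonal call whose instantaneous fundamental frequency follows the
#' contour, by phase integration. Optional harmonic overtones are added at
#' integer multiples of the fundamental; harmonic `m` (the `(m-1)`-th overtone)
#' is attenuated by `(m - 1) * harmonic_rolloff` dB relative to the fundamental.
#'
#' @param contour A [contour_spec()].
#' @param sample_rate Sampling rate in Hz; must be at least 2.5x the highest
#'   synthesized frequency (fundamental maximum times `1 + n_harmonics`).
#' @param n_harmonics Number of overtones above the fundamental (>= 0).
#' @param harmonic_rolloff Attenuation per harmonic step, dB.
#' @param snr Band-integrated signal-to-noise ratio in dB over the call band;
#'   `Inf` (default) for a noiseless signal. See [add_noise()].
#' @param seed Integer seed used only when noise is added.
#' @return A [wave_recording()] of the contour's duration, peak-normalized.
#' @examples
#' w <- synth_whistle(contour_spec(c(0, 1.2), c(5, 8)), 96000)
#' @export
synth_whistle <- function(contour, sample_rate = 96000, n_harmonics = 0,
                          harmonic_rolloff = 6, snr = Inf, seed = 1L) {
  stopifnot(inherits(contour, "contour_spec"))
  f_max <- max(contour$freqs_khz) * 1000 * (1 + n_harmonics)
  if (sample_rate < 2.5 * f_max) {
    stop(sprintf("sample_rate %g Hz < 2.5 x highest synthesized frequency %g Hz",
                 sample_rate, f_max), call. = FALSE)
  }
  dur <- max(contour$times)
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- contour_frequency(contour, t) * 1000
  x <- phase_osc(f0, sample_rate)
  if (n_harmonics > 0) {
    for (h in seq_len(n_harmonics)) {
      amp <- 10^(-(h * harmonic_rolloff) / 20)
      x <- x + amp * phase_osc((h + 1) * f0, sample_rate)
    }
  }
  rec <- wave_recording(0.9 * x / max(abs(x)), sample_rate)
  maybe_add_noise(rec, snr, seed, band_khz = range(contour$freqs_khz) * c(0.9, 1.1 * (1 + n_harmonics)))
}

#' Synthesize a burst-pulse sound
#'
#' Burst-pulse sounds are trains of rapidly repeated pulses; spectrographically
#' they appear as a carrier contour flanked by sidebands spaced at the pulse
#' repetition rate. The minimal generator with exactly that structure is a
#' tonal carrier (the call's lowest strong contour) amplitude-modulated by a
#' rectangular pulse train. With duty cycle `d`, sideband `k` sits
#' `20*log10(|sinc(k d)|)` dB below the carrier; the default `d = 0.3` keeps
#' several sideband orders visible on both sides, producing the dense-sideband
#' spectrogram characteristic of these calls.
#'
#' A partial `pulsed_window` restricts the modulation to a time interval,
#' producing whistles pulsed only in the middle, or transition calls that are
#' half pulsed and half tonal.
#'
#' @param contour Carrier [contour_spec()] (kHz).
#' @param pulse_rate Pulse repetition rate in Hz; this is the sideband spacing
#'   target. Must be below the lowest carrier frequency.
#' @param duty_cycle Fraction of each pulse period that is "on", in (0, 1].
#' @param pulsed_window `NULL` for a fully pulsed call, or `c(start, end)` in
#'   seconds for a partially pulsed one.
#' @param sample_rate,snr,seed As in [synth_whistle()].
#' @return A [wave_recording()].
#' @export
synth_burst_pulse <- function(contour, pulse_rate, duty_cycle = 0.3,
                              pulsed_window = NULL, sample_rate = 96000,
                              snr = Inf, seed = 1L) {
  stopifnot(inherits(contour, "contour_spec"))
  if (pulse_rate <= 0) stop("pulse_rate must be positive", call. = FALSE)
  if (pulse_rate >= min(contour$freqs_khz) * 1000) {
    stop("pulse_rate must be below the lowest carrier frequency", call. = FALSE)
  }
  if (duty_cycle <= 0 || duty_cycle > 1) stop("duty_cycle must be in (0, 1]", call. = FALSE)
  dur <- max(contour$times)
  if (!is.null(pulsed_window)) {
    stopifnot(length(pulsed_window) == 2, pulsed_window[1] >= 0,
              pulsed_window[2] <= dur + 1e-9, pulsed_window[2] > pulsed_window[1])
  }
  f_max <- max(contour$freqs_khz) * 1000 + pulse_rate * 8 # sidebands extend the band
  if (sample_rate < 2.5 * f_max) {
    stop("sample_rate too low for carrier plus sidebands", call. = FALSE)
  }
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- contour_frequency(contour, t) * 1000
  carrier <- phase_osc(f0, sample_rate)
  m <- as.numeric((t * pulse_rate) %% 1 < duty_cycle)
  if (!is.null(pulsed_window)) {
    outside <- t < pulsed_window[1] | t >= pulsed_window[2]
    m[outside] <- 1
  }
  x <- carrier * m
  if (max(abs(x)) == 0) stop("degenerate burst-pulse: all-zero signal", call. = FALSE)
  rec <- wave_recording(0.9 * x / max(abs(x)), sample_rate)
  band <- c(max(0.05, min(contour$freqs_khz) - 4 * pulse_rate / 1000),
            max(contour$freqs_khz) + 4 * pulse_rate / 1000)
  maybe_add_noise(rec, snr, seed, band_khz = band)
}

#' Synthesize a Gabor click train or buzz
#'
#' Each click is a Gaussian-windowed cosine (Gabor pulse) of the given centre
#' frequency; `click_duration` is the -3 dB width of the Gaussian envelope.
#' Negative polarity (the default) matches the on-axis waveform reported for
#' odontocete echolocation clicks. The inter-click interval can be constant or
#' shrink geometrically (`ici_ramp < 1`) to emulate a train speeding up into a
#' buzz. An optional reflection appends an attenuated copy of every click at a
#' fixed delay, emulating a surface/bottom reflection.
#'
#' @param n_clicks Number of emitted clicks.
#' @param ici Initial inter-click interval, seconds.
#' @param center_freq_khz Click centre frequency, kHz.
#' @param click_duration -3 dB envelope width, seconds (default 180 us).
#' @param polarity `-1` (default) or `1`.
#' @param ici_ramp Geometric factor applied to successive intervals (1 = constant).
#' @param reflection `NULL`, or `c(delay_s, attenuation_db)` with positive delay
#'   smaller than the smallest interval and attenuation in dB (> 0 attenuates).
#' @param sample_rate,snr,seed As in [synth_whistle()].
#' @return A [wave_recording()].
#' @export
synth_click_train <- function(n_clicks, ici, center_freq_khz,
                              click_duration = 180e-6, polarity = -1,
                              ici_ramp = 1, reflection = NULL,
                              sample_rate = 96000, snr = Inf, seed = 1L) {
  stopifnot(n_clicks >= 1, ici > 0, center_freq_khz > 0)
  if (sample_rate < 2.5 * center_freq_khz * 1000) {
    stop("sample_rate too low for the click centre frequency", call. = FALSE)
  }
  intervals <- ici * ici_ramp^(seq_len(max(0, n_clicks - 1)) - 1)
  if (click_duration >= min(intervals, ici)) {
    stop("click_duration must be smaller than the inter-click interval", call. = FALSE)
  }
  if (!is.null(reflection)) {
    stopifnot(length(reflection) == 2, reflection[1] > 0)
    if (reflection[1] >= min(intervals, ici)) {
      stop("reflection delay must be smaller than the inter-click interval", call. = FALSE)
    }
  }
  click_times <- c(0, cumsum(intervals)) + 2 * ici

  # -3 dB width w of exp(-t^2 / (2 sigma^2)) gives sigma = w / (2 sqrt(2 ln 10^(3/20)))
  sigma <- click_duration / (2 * sqrt(2 * log(10^(3 / 20))))
  half <- 4 * sigma
  tk <- seq(-half, half, by = 1 / sample_rate)
  pulse <- polarity * exp(-tk^2 / (2 * sigma^2)) * cos(2 * pi * center_freq_khz * 1000 * tk)

  total <- max(click_times) + 2 * ici + ifelse(is.null(reflection), 0, reflection[1])
  n <- ceiling(total * sample_rate)
  x <- numeric(n)
  place <- function(x, t0, amp) {
    i0 <- round(t0 * sample_rate) + 1 - (length(tk) - 1) / 2
    idx <- i0:(i0 + length(pulse) - 1)
    keep <- idx >= 1 & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amp * pulse[keep]
    x
  }
  for (tc in click_times) {
    x <- place(x, tc, 1)
    if (!is.null(reflection)) x <- place(x, tc + reflection[1], 10^(-reflection[2] / 20))
  }
  rec <- wave_recording(0.9 * x / max(abs(x)), sample_rate)
  maybe_add_noise(rec, snr, seed,
                  band_khz = center_freq_khz * c(0.5, 1.5))
}

#' Add white Gaussian noise at a target band-integrated SNR
#'
#' The noise variance is chosen so that the ratio of signal power to noise
#' power *within the stated frequency band* equals `snr` dB. White noise spreads
#' its power uniformly over `[0, Nyquist]`, so out-of-band noise is present as
#' in a real recording while the in-band SNR is controlled. Reproducible given
#' `seed`; the global RNG state is left untouched.
#'
#' @param recording A [wave_recording()].
#' @param snr Target band-integrated SNR in dB (finite).
#' @param seed Integer seed.
#' @param band_khz Signal band `c(lo, hi)` in kHz; default the full band.
#' @return A new [wave_recording()] with noise added.
#' @export
add_noise <- function(recording, snr, seed = 1L, band_khz = NULL) {
  stopifnot(inherits(recording, "wave_recording"), is.finite(snr))
  fs <- recording$sample_rate
  x <- recording$samples
  nyq_khz <- fs / 2000
  if (is.null(band_khz)) band_khz <- c(0, nyq_khz)
  band_khz <- pmin(pmax(band_khz, 0), nyq_khz)

  X <- stats::fft(x)
  n <- length(x)
  freqs_khz <- (seq_len(n) - 1) * fs / n / 1000
  half <- freqs_khz <= nyq_khz
  in_band <- half & freqs_khz >= band_khz[1] & freqs_khz <= band_khz[2]
  p_sig_band <- 2 * sum(Mod(X[in_band])^2) / n^2 # band power (two-sided folded)

  band_frac <- (band_khz[2] - band_khz[1]) / nyq_khz
  sigma2 <- p_sig_band / (band_frac * 10^(snr / 10))
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(n, sd = sqrt(sigma2)))
  wave_recording(x + noise, fs, recording$start_offset)
}

maybe_add_noise <- function(rec, snr, seed, band_khz) {
  if (is.infinite(snr)) rec else add_noise(rec, snr, seed, band_khz)
}

#' Sample labelled feature vectors around the published call-type ranges
#'
#' For each call type in the catalog, draws `n_per_group` feature vectors whose
#' parameters are independent Gaussians centred at each parameter's published
#' range midpoint with standard deviation `spread` times the range width,
#' truncated to the range. The published ranges are extremes over few calls, so
#' mass concentrated at the midpoint (rather than uniform over the range) is
#' the realistic reading. Sideband spacing is `NA` for tonal call types. The
#' harmonic flag is set per call type: overtones are a described feature of the
#' whistle, pulsed-middle and transition types, not of the plain burst-pulse
#' types.
#'
#' @param catalog Tibble from [load_reference_catalog()].
#' @param n_per_group Vectors to draw per call type.
#' @param spread Standard deviation as a fraction of the range width, in
#'   (0, 0.5].
#' @param seed Integer seed (reproducible; global RNG untouched).
#' @return A tibble with the measurement columns plus the true `group` label.
#' @export
sample_feature_vectors <- function(catalog, n_per_group = 20, spread = 0.05,
                                   seed = 1L) {
  stopifnot(spread > 0, spread <= 0.5)
  params <- c("min_f", "max_f", "start_f", "end_f", "delta_f", "duration",
              "n_extrema", "n_inflections", "fm_rate", "sideband")
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
      g <- catalog[i, ]
      vals <- purrr::map(params, function(p) {
        lo <- g[[paste0(p, "_lo")]]
        hi <- g[[paste0(p, "_hi")]]
        if (is.na(lo)) return(rep(NA_real_, n_per_group))
        rtruncnorm(n_per_group, (lo + hi) / 2, spread * (hi - lo), lo, hi)
      })
      names(vals) <- params
      tibble::tibble(
        group = g$group_id,
        min_f = vals$min_f, max_f = vals$max_f,
        start_f = vals$start_f, end_f = vals$end_f,
        delta_f = vals$delta_f, duration = vals$duration,
        n_extrema = vals$n_extrema, n_inflections = vals$n_inflections,
        fm_rate = vals$fm_rate,
        has_harmonics = g$call_class %in% c("whistle", "pulsed_middle", "transition"),
        sideband_spacing = vals$sideband,
        call_class = g$call_class
      )
    })
    rows
  })
}

# Truncated normal by rejection; degenerate width collapses to the midpoint.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0 || hi <= lo) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)), mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}
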