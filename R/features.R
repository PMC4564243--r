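# The ten standard call parameters, computed from a contour trace.

#' Smooth a contour trace
#'
#' Median filter followed by a centred moving average on the frequency
#' sequence; times and levels are unchanged. Windows shrink at the endpoints.
#' Removes the residual bin-quantization staircase so that derivative-based
#' counting is stable. `median_len = mean_len = 1` is the identity.
#'
#' @param trace A `contour_trace`.
#' @param median_len,mean_len Window lengths in frames (odd; even values are
#'   rounded up).
#' @return A smoothed `contour_trace`.
#' @export
smooth_contour <- function(trace, median_len = 5, mean_len = 5) {
  stopifnot(nrow(trace) > 0)
  f <- trace$freq_khz
  n <- length(f)
  med <- max(1, median_len + (1 - median_len %% 2))
  if (med > 1 && n >= med) f <- stats::runmed(f, med, endrule = "median")
  k <- (max(1, mean_len + (1 - mean_len %% 2)) - 1) / 2
  if (k > 0) {
    cs <- cumsum(c(0, f))
    lo <- pmax(seq_len(n) - k, 1)
    hi <- pmin(seq_len(n) + k, n)
    f <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  as_contour_trace(trace$time, f, trace$level_db, attr(trace, "gaps_bridged"))
}

# Hysteresis turning-point counter: number of interior reversals of `x` whose
# excursion on both sides reaches `prom`. Endpoints are never counted.
count_turnings <- function(x, prom) {
  n <- length(x)
  if (n < 3) return(0L)
  count <- 0L
  dir <- 0L
  run_max <- x[1]
  run_min <- x[1]
  for (v in x[-1]) {
    run_max <- max(run_max, v)
    run_min <- min(run_min, v)
    if (dir <= 0 && v - run_min >= prom) {
      if (dir == -1L) count <- count + 1L # confirmed local minimum
      dir <- 1L
      run_max <- v
    } else if (dir >= 0 && run_max - v >= prom) {
      if (dir == 1L) count <- count + 1L # confirmed local maximum
      dir <- -1L
      run_min <- v
    }
  }
  count
}

#' Count contour extrema
#'
#' Number of interior stationary points of the frequency contour — points
#' where the slope changes sign — counting only excursions whose frequency
#' prominence reaches `prominence` on both sides (sub-prominence jitter is
#' ignored). Endpoints are never counted.
#'
#' @param trace A (smoothed) `contour_trace` with at least 3 points.
#' @param prominence Minimum excursion in kHz.
#' @return Integer count.
#' @export
count_extrema <- function(trace, prominence = 0.1) {
  stopifnot(nrow(trace) >= 3)
  count_turnings(trace$freq_khz, prominence)
}

#' Count contour inflection points
#'
#' Inflection points are curvature sign changes of the contour, i.e. local
#' extrema of its slope. The count applies the same hysteresis rule as
#' [count_extrema()] to the first-difference (slope) sequence; the slope
#' hysteresis threshold is `prominence` divided by a 50 ms horizon, i.e. a
#' slope excursion is counted when it corresponds to at least `prominence` of
#' frequency change over 50 ms. Endpoints excluded.
#'
#' @param trace A (smoothed) `contour_trace` with at least 3 points.
#' @param prominence Frequency prominence in kHz (see above).
#' @param slope_prominence Direct slope threshold in kHz/s, overriding the
#'   default `prominence / 0.05`.
#' @return Integer count.
#' @export
count_inflections <- function(trace, prominence = 0.1, slope_prominence = NULL) {
  stopifnot(nrow(trace) >= 3)
  slope <- diff(trace$freq_khz) / diff(trace$time)
  # median-filter the slope: frame-to-frame estimation jitter produces
  # spurious reversals that survive plain hysteresis
  if (length(slope) >= 5) slope <- stats::runmed(slope, 5, endrule = "median")
  if (is.null(slope_prominence)) slope_prominence <- prominence / 0.05
  count_turnings(slope, slope_prominence)
}

#' Measure the standard call parameters from a contour trace
#'
#' Computes the ten published call parameters off the smoothed trace:
#' frequency minimum/maximum/start/end (kHz), `delta_f = max_f - min_f`
#' (exact), duration (first to last frame centre, s), numbers of extrema and
#' inflection points, and `fm_rate = n_inflections / duration` (exact, 1/s) —
#' plus the harmonic-overtone flag, the sideband spacing (pulsed calls only,
#' else `NA`) and the structural call class.
#'
#' Between two counted extrema of a smooth contour there is necessarily one
#' curvature change, so the reported inflection count is never below
#' `n_extrema - 1`. For partially pulsed calls (`pulsed_middle`, `transition`)
#' the frequency extremes are measured off the tonal (whistle) frames while
#' duration and the counts cover the entire call, and the sideband spacing is
#' measured off the pulsed section only, following the published convention
#' for those call types.
#'
#' @param trace A `contour_trace` from [extract_contour()].
#' @param spec The `orca_spectrogram` it was traced on.
#' @param prominence Counting prominence in kHz; default 2 frequency bins.
#' @param median_len,mean_len Smoothing windows, see [smooth_contour()].
#' @return A one-row tibble with columns `min_f, max_f, start_f, end_f,
#'   delta_f, duration, n_extrema, n_inflections, fm_rate, has_harmonics,
#'   sideband_spacing, call_class`. A trace with fewer than 3 points yields a
#'   row of `NA`s (unmeasurable), not an error.
#' @export
measure_call <- function(trace, spec, prominence = NULL,
                         median_len = 5, mean_len = 5) {
  if (nrow(trace) < 3) {
    return(tibble::tibble(
      min_f = NA_real_, max_f = NA_real_, start_f = NA_real_, end_f = NA_real_,
      delta_f = NA_real_, duration = NA_real_, n_extrema = NA_integer_,
      n_inflections = NA_integer_, fm_rate = NA_real_, has_harmonics = NA,
      sideband_spacing = NA_real_, call_class = NA_character_
    ))
  }
  if (is.null(prominence)) {
    prominence <- 2 * (spec$bin_freqs[2] - spec$bin_freqs[1]) / 1000
  }
  sm <- smooth_contour(trace, median_len, mean_len)
  cls <- classify_call(spec, trace)
  flags <- pulsed_flags(spec, trace)

  f_for_range <- sm$freq_khz
  if (cls %in% c("pulsed_middle", "transition") && sum(!flags) >= 3) {
    f_for_range <- sm$freq_khz[!flags]
  }
  min_f <- min(f_for_range)
  max_f <- max(f_for_range)
  duration <- sm$time[nrow(sm)] - sm$time[1]
  n_ext <- count_extrema(sm, prominence)
  n_infl <- max(count_inflections(sm, prominence), n_ext - 1L)

  harm <- detect_harmonics(spec, trace)
  sideband <- NA_real_
  if (cls != "whistle") {
    region <- NULL
    if (any(flags)) region <- range(trace$time[flags])
    sb <- measure_sideband_spacing(spec, trace, region = region)
    sideband <- sb$spacing_khz
  }

  tibble::tibble(
    min_f = min_f, max_f = max_f,
    start_f = sm$freq_khz[1], end_f = sm$freq_khz[nrow(sm)],
    delta_f = max_f - min_f,
    duration = duration,
    n_extrema = as.integer(n_ext),
    n_inflections = as.integer(n_infl),
    fm_rate = n_infl / duration,
    has_harmonics = harm$has_harmonics,
    sideband_spacing = sideband,
    call_class = cls
  )
}

#' Measure every annotated call in a recording
#'
#' Convenience wrapper chaining [compute_spectrogram()], [extract_contour()]
#' and [measure_call()] for each annotation (or once for the whole file).
#'
#' @param recording A [wave_recording()].
#' @param annotations Optional tibble from [read_selection_table()]; `NULL`
#'   measures the whole file as one call.
#' @param params [spectrogram_params()].
#' @param ... Passed to [extract_contour()].
#' @return A tibble of measurements, one row per annotation, with the
#'   annotation times prepended. Unmeasurable calls yield `NA` rows.
#' @export
measure_calls <- function(recording, annotations = NULL,
                          params = spectrogram_params(), ...) {
  spec <- compute_spectrogram(recording, params)
  if (is.null(annotations)) {
    tr <- extract_contour(spec, ...)
    return(measure_call(tr, spec))
  }
  purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    tr <- extract_contour(spec, region = annotations[i, ], ...)
    dplyr::bind_cols(
      tibble::tibble(begin_time = annotations$begin_time[i],
                     end_time = annotations$end_time[i]),
      measure_call(tr, spec)
    )
  })
}
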