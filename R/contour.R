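# Ridge extraction and spectral-structure analysis.
#
# A contour trace is a tibble (time s, freq_khz, level_db) of one spectral
# ridge, with the number of interpolated gap frames in attr "gaps_bridged".

empty_trace <- function() {
  structure(
    tibble::tibble(time = numeric(0), freq_khz = numeric(0), level_db = numeric(0)),
    gaps_bridged = 0L, class = c("contour_trace", class(tibble::tibble()))
  )
}

as_contour_trace <- function(time, freq_khz, level_db, gaps_bridged = 0L) {
  structure(
    tibble::tibble(time = time, freq_khz = freq_khz, level_db = level_db),
    gaps_bridged = as.integer(gaps_bridged),
    class = c("contour_trace", class(tibble::tibble()))
  )
}

# Per-frame noise floor: median dB level over the searchable band.
frame_floors <- function(spec, bins) {
  apply(spec$power[, bins, drop = FALSE], 1, stats::median)
}

# Logical matrix of per-frame local spectral maxima (within the given bins).
local_max_matrix <- function(P) {
  n <- ncol(P)
  if (n < 3) return(matrix(FALSE, nrow(P), n))
  left <- cbind(-Inf, P[, -n, drop = FALSE])
  right <- cbind(P[, -1, drop = FALSE], -Inf)
  P > left & P >= right
}

# Quadratic (parabolic) refinement of a peak position from dB values.
parabolic_offset <- function(y1, y2, y3) {
  den <- y1 - 2 * y2 + y3
  d <- ifelse(abs(den) < 1e-12, 0, 0.5 * (y1 - y3) / den)
  pmin(0.5, pmax(-0.5, d))
}

#' Extract the tonal contour of a call from a spectrogram
#'
#' Tracks one spectral ridge: in each frame, candidate peaks are local spectral
#' maxima at least `threshold_db` above the frame's noise floor (the median
#' level over the searched band). Starting from the most prominent accepted
#' peak, the ridge is extended frame by frame under a continuity constraint
#' (at most `max_jump_bins` bins between adjacent frames); frames with no
#' qualifying peak are gaps, and up to `max_gap` consecutive gap frames are
#' bridged by linear interpolation (counted in the `gaps_bridged` attribute).
#' Peak frequencies are refined by parabolic interpolation of the dB spectrum.
#' Ridges spanning less than `min_duration` are rejected.
#'
#' @param spec An `orca_spectrogram`.
#' @param region Optional annotation (one row with `begin_time`, `end_time`,
#'   `low_freq`, `high_freq` in s / Hz) restricting the search; `NULL` searches
#'   the whole spectrogram.
#' @param threshold_db Acceptance margin above the per-frame noise floor (dB).
#' @param max_jump_bins Maximum adjacent-frame frequency jump, in bins.
#' @param jump_penalty_db Stickiness of the tracker in `"strongest"` mode: a
#'   candidate's level is discounted by this many dB per bin of jump from the
#'   previous frame's frequency, so a marginally stronger sideband or harmonic
#'   does not capture the ridge.
#' @param max_gap Maximum number of consecutive bridgeable gap frames.
#' @param min_duration Minimum ridge span in seconds.
#' @param persistence_db A completed ridge is kept only if its median
#'   prominence (level above the frame noise floor) exceeds
#'   `threshold_db + persistence_db`; chains of marginal noise peaks sit just
#'   above `threshold_db` while true ridges sit far above it.
#' @param dyn_range_db Peaks must also lie within this many dB of the frame
#'   maximum; rejects window-sidelobe leakage, which in a clean recording can
#'   exceed the noise floor by more than `threshold_db`.
#' @param ridge `"strongest"` follows the strongest qualifying peak (the
#'   fundamental of a tonal call, or the carrier of a pulsed one);
#'   `"lowest"` follows the lowest qualifying peak.
#' @return A `contour_trace` tibble `(time, freq_khz, level_db)`; empty (zero
#'   rows) when no ridge is found — never an error.
#' @export
extract_contour <- function(spec, region = NULL, threshold_db = 6,
                            max_jump_bins = 3, max_gap = 2,
                            min_duration = 0.04, dyn_range_db = 25,
                            jump_penalty_db = 3, persistence_db = 3,
                            ridge = c("strongest", "lowest")) {
  ridge <- match.arg(ridge)
  stopifnot(inherits(spec, "orca_spectrogram"))
  n_bins <- length(spec$bin_freqs)
  bins <- 2:n_bins # exclude DC
  frames <- seq_along(spec$frame_times)
  if (!is.null(region)) {
    frames <- which(spec$frame_times >= region$begin_time &
                      spec$frame_times <= region$end_time)
    bins <- which(spec$bin_freqs >= max(region$low_freq, spec$bin_freqs[2]) &
                    spec$bin_freqs <= region$high_freq)
    if (length(frames) < 3 || length(bins) < 3) return(empty_trace())
  }
  P <- spec$power[frames, bins, drop = FALSE]
  floors <- frame_floors(spec, bins)[frames]
  fmax <- apply(P, 1, max)
  cand <- local_max_matrix(P) & (P >= floors + threshold_db) &
    (P >= fmax - dyn_range_db)
  if (!any(cand)) return(empty_trace())

  nf <- nrow(P)
  pick <- function(j, prev, lo, hi) {
    # candidate columns of frame j within [lo, hi]; choose per ridge mode
    cols <- which(cand[j, ])
    cols <- cols[cols >= lo & cols <= hi]
    if (length(cols) == 0) return(NA_integer_)
    if (ridge == "strongest") {
      cols[which.max(P[j, cols] - jump_penalty_db * abs(cols - prev))]
    } else {
      min(cols)
    }
  }

  # seed: most prominent candidate (strongest mode), or the most prominent
  # among per-frame lowest candidates (lowest mode)
  prom <- P - floors
  prom[!cand] <- -Inf
  if (ridge == "strongest") {
    seed_frame <- which.max(apply(prom, 1, max))
    seed_col <- which.max(prom[seed_frame, ])
  } else {
    lowest_col <- apply(cand, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    sel <- vapply(seq_len(nf), function(j) {
      if (is.na(lowest_col[j])) -Inf else prom[j, lowest_col[j]]
    }, numeric(1))
    seed_frame <- which.max(sel)
    seed_col <- lowest_col[seed_frame]
  }

  path <- rep(NA_integer_, nf)
  path[seed_frame] <- seed_col
  for (dir in c(1L, -1L)) {
    prev <- seed_col
    gaps <- 0L
    j <- seed_frame + dir
    while (j >= 1 && j <= nf) {
      col <- pick(j, prev, prev - max_jump_bins, prev + max_jump_bins)
      if (is.na(col)) {
        gaps <- gaps + 1L
        if (gaps > max_gap) break
      } else {
        path[j] <- col
        prev <- col
        gaps <- 0L
      }
      j <- j + dir
    }
  }

  found <- which(!is.na(path))
  lo <- min(found); hi <- max(found)
  idx <- lo:hi
  bridged <- sum(is.na(path[idx]))
  cols <- round(stats::approx(found, path[found], xout = idx)$y)

  hop_s <- diff(spec$frame_times[1:2])
  if (length(idx) * hop_s < min_duration || length(idx) < 3) return(empty_trace())
  if (stats::median(P[cbind(idx, cols)] - floors[idx]) < threshold_db + persistence_db) {
    return(empty_trace())
  }

  gbin <- bins[cols] # global bin index
  binw <- spec$bin_freqs[2] - spec$bin_freqs[1]
  fidx <- frames[idx]
  y2 <- spec$power[cbind(fidx, gbin)]
  y1 <- spec$power[cbind(fidx, pmax(gbin - 1, 1))]
  y3 <- spec$power[cbind(fidx, pmin(gbin + 1, n_bins))]
  delta <- parabolic_offset(y1, y2, y3)
  freq_hz <- spec$bin_freqs[gbin] + delta * binw
  as_contour_trace(spec$frame_times[fidx], freq_hz / 1000, y2, bridged)
}

#' Detect harmonic overtones of a traced fundamental
#'
#' An overtone multiple `m` is reported when, in at least half of the trace's
#' frames, the spectrum within `tolerance` of `m` times the fundamental
#' frequency exceeds the frame noise floor by `margin_db`.
#'
#' @param spec An `orca_spectrogram`.
#' @param fundamental A nonempty `contour_trace`.
#' @param tolerance Fractional tolerance around each integer multiple.
#' @param margin_db Detection margin above the frame noise floor, dB.
#' @param max_multiple Highest multiple examined.
#' @return A list: `has_harmonics` (flag), `multiples_found` (integers >= 2)
#'   and `tolerance_used`.
#' @export
detect_harmonics <- function(spec, fundamental, tolerance = 0.03,
                             margin_db = 6, max_multiple = 6,
                             dyn_range_db = 25) {
  stopifnot(nrow(fundamental) > 0)
  n_bins <- length(spec$bin_freqs)
  floors <- frame_floors(spec, 2:n_bins)
  fmax <- apply(spec$power[, 2:n_bins, drop = FALSE], 1, max)
  fidx <- match_frames(spec, fundamental$time)
  nyq <- spec$bin_freqs[n_bins]
  found <- integer(0)
  for (m in 2:max_multiple) {
    target <- m * fundamental$freq_khz * 1000
    usable <- target * (1 - tolerance) < nyq
    if (sum(usable) < 3) next
    hit <- vapply(which(usable), function(i) {
      win <- which(spec$bin_freqs >= target[i] * (1 - tolerance) &
                     spec$bin_freqs <= target[i] * (1 + tolerance))
      if (length(win) == 0) return(FALSE)
      max(spec$power[fidx[i], win]) >=
        max(floors[fidx[i]] + margin_db, fmax[fidx[i]] - dyn_range_db)
    }, logical(1))
    if (mean(hit) >= 0.5) found <- c(found, m)
  }
  list(has_harmonics = length(found) > 0, multiples_found = found,
       tolerance_used = tolerance)
}

match_frames <- function(spec, times) {
  vapply(times, function(t) which.min(abs(spec$frame_times - t)), integer(1))
}

# Per-frame spectral structure along a traced contour: for each trace frame,
# the qualifying non-harmonic parallel peaks (kHz) besides the contour itself.
# A peak p is "harmonic" when p is within tolerance of an integer multiple
# (>= 1) of the contour frequency. Peaks below the contour are never harmonic.
parallel_peaks <- function(spec, trace, tolerance = 0.03, margin_db = 6,
                           dyn_range_db = 25) {
  n_bins <- length(spec$bin_freqs)
  bins <- 2:n_bins
  P <- spec$power[, bins, drop = FALSE]
  floors <- frame_floors(spec, bins)
  fmax <- apply(P, 1, max)
  cand <- local_max_matrix(P) & (P >= floors + margin_db) &
    (P >= fmax - dyn_range_db)
  fidx <- match_frames(spec, trace$time)
  binw <- spec$bin_freqs[2] - spec$bin_freqs[1]
  n_all <- length(spec$bin_freqs)
  purrr::map(seq_len(nrow(trace)), function(i) {
    j <- fidx[i]
    f0 <- trace$freq_khz[i]
    cols <- bins[which(cand[j, ])]
    d <- parabolic_offset(spec$power[j, pmax(cols - 1, 1)],
                          spec$power[j, cols],
                          spec$power[j, pmin(cols + 1, n_all)])
    pk <- (spec$bin_freqs[cols] + d * binw) / 1000
    pk <- pk[abs(pk - f0) > 1.5 * binw / 1000] # drop the contour's own peak
    if (length(pk) == 0) return(numeric(0))
    ratio <- pk / f0
    m <- round(ratio)
    harmonic <- m >= 1 & abs(ratio - m) <= tolerance * pmax(m, 1)
    pk[!harmonic]
  })
}

#' Measure the sideband spacing of a pulsed call
#'
#' Among the spectral contours running parallel to the traced lowest/main
#' contour (local maxima above the frame noise floor that are not harmonics of
#' it), the spacing is the median over frames of the median adjacent-peak
#' frequency difference. For a pulsed sound this equals the pulse repetition
#' rate. Absent (`NA`) when fewer than a quarter of the frames show at least
#' two parallel contours — a plain whistle, with or without harmonics, reports
#' no spacing.
#'
#' @param spec An `orca_spectrogram`.
#' @param lowest A nonempty `contour_trace`.
#' @param region Optional time window `c(start, end)` in seconds (e.g. the
#'   pulsed middle section of a partially pulsed call).
#' @param tolerance,margin_db As in [detect_harmonics()].
#' @return A list: `spacing_khz` (or `NA`), `n_contours_used` (median count of
#'   parallel contours) and `region`.
#' @export
measure_sideband_spacing <- function(spec, lowest, region = NULL,
                                     tolerance = 0.03, margin_db = 6) {
  stopifnot(nrow(lowest) > 0)
  tr <- lowest
  if (!is.null(region)) {
    keep <- tr$time >= region[1] & tr$time <= region[2]
    tr <- tr[keep, , drop = FALSE]
  }
  if (nrow(tr) == 0) {
    return(list(spacing_khz = NA_real_, n_contours_used = 0L, region = region))
  }
  peaks <- parallel_peaks(spec, tr, tolerance, margin_db)
  per_frame <- purrr::map_dbl(seq_along(peaks), function(i) {
    pk <- peaks[[i]]
    if (length(pk) < 2) return(NA_real_)
    all_pk <- sort(unique(c(pk, tr$freq_khz[i])))
    stats::median(diff(all_pk))
  })
  contributing <- which(!is.na(per_frame))
  if (length(contributing) < max(3, 0.25 * nrow(tr))) {
    return(list(spacing_khz = NA_real_, n_contours_used = 0L, region = region))
  }
  list(
    spacing_khz = stats::median(per_frame[contributing]),
    n_contours_used = as.integer(stats::median(lengths(peaks)[contributing]) + 1),
    region = range(tr$time[contributing])
  )
}

# Per-frame pulsed/tonal flags along a trace: pulsed = at least two parallel
# non-harmonic contours present. Lightly median-smoothed to remove one-frame
# flicker.
pulsed_flags <- function(spec, trace, tolerance = 0.03, margin_db = 6) {
  raw <- lengths(parallel_peaks(spec, trace, tolerance, margin_db)) >= 2
  if (length(raw) >= 3) as.logical(stats::runmed(as.numeric(raw), 3) >= 0.5) else raw
}

#' Classify the structure of a traced call
#'
#' Frames are labelled pulsed when parallel non-harmonic contours (sidebands)
#' are present, tonal otherwise. With `p` the pulsed fraction of frames, the
#' call is a `whistle` when `p < 0.2` and a `burst_pulse` when `p > 0.8`.
#' Between those, a pulsed run confined to the middle third with tonal ends is
#' a `pulsed_middle` call, and one pulsed half against one tonal half a
#' `transition`. (The originating study classified calls visually; these
#' thresholds are this implementation's operational definition.)
#'
#' @param spec An `orca_spectrogram`.
#' @param lowest A nonempty `contour_trace`.
#' @param tolerance,margin_db As in [detect_harmonics()].
#' @return One of `"whistle"`, `"burst_pulse"`, `"pulsed_middle"`,
#'   `"transition"`.
#' @export
classify_call <- function(spec, lowest, tolerance = 0.03, margin_db = 6) {
  stopifnot(nrow(lowest) > 0)
  p <- pulsed_flags(spec, lowest, tolerance, margin_db)
  n <- length(p)
  frac <- mean(p)
  if (frac < 0.2) return("whistle")
  if (frac > 0.8) return("burst_pulse")
  third <- floor(n / 3)
  ends <- c(p[seq_len(third)], p[(n - third + 1):n])
  mid <- p[(third + 1):(n - third)]
  if (mean(mid) >= 0.6 && mean(ends) <= 0.25) return("pulsed_middle")
  h1 <- mean(p[seq_len(n %/% 2)])
  h2 <- mean(p[(n %/% 2 + 1):n])
  if (max(h1, h2) >= 0.7 && min(h1, h2) <= 0.3) return("transition")
  if (frac >= 0.5) "burst_pulse" else "whistle"
}

#' Plot a contour trace
#' @param object A `contour_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contour_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$freq_khz,
                                       colour = .data$level_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (s)", y = "Frequency (kHz)", colour = "dB re max") +
    ggplot2::theme_minimal()
}
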