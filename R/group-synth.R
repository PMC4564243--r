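# Synthesize a whole call in the style of one catalog call type: a zigzag
# fundamental whose start/end values, frequency extremes and extremum count sit
# inside the type's published ranges, rendered as a whistle, burst-pulse,
# pulsed-middle or transition call according to the type's class.

#' Build a contour in the style of a catalog call type
#'
#' Constructs a piecewise-linear fundamental contour whose measured parameters
#' land inside the call type's published ranges: it starts and ends strictly
#' inside the frequency extremes, oscillates between the Min f and Max f range
#' midpoints, and has `floor(midpoint)` of the published extrema range as its
#' number of interior extrema. `jitter > 0` perturbs each target within its
#' range (truncated Gaussian, sd = `jitter` x range width).
#'
#' @param group One catalog row ([load_reference_catalog()]).
#' @param jitter Fractional within-range jitter (0 = deterministic midpoints).
#' @param seed Integer seed, used when `jitter > 0`.
#' @return A [contour_spec()].
#' @export
group_contour <- function(group, jitter = 0, seed = 1L) {
  pick <- function(p) {
    lo <- group[[paste0(p, "_lo")]]; hi <- group[[paste0(p, "_hi")]]
    mid <- (lo + hi) / 2
    if (jitter <= 0 || hi <= lo) return(mid)
    withr::with_seed(as.integer(seed) + sum(utf8ToInt(p)),
                     rtruncnorm(1, mid, jitter * (hi - lo), lo, hi))
  }
  f_lo <- pick("min_f"); f_hi <- pick("max_f")
  dur <- pick("duration")
  n_ext <- floor((group$n_extrema_lo + group$n_extrema_hi) / 2)

  # start/end pinned strictly inside [f_lo, f_hi] with enough clearance that
  # boundary reversals survive the prominence gate downstream
  eps <- max(0.12 * (f_hi - f_lo), 0.45)
  if (eps > (f_hi - f_lo) / 2.5) eps <- (f_hi - f_lo) / 2.5
  s <- min(max(pick("start_f"), f_lo + eps), f_hi - eps)
  e <- min(max(pick("end_f"), f_lo + eps), f_hi - eps)

  if (n_ext == 0) {
    # monotone sweep spanning the frequency extremes
    if (s <= e) {
      return(contour_spec(c(0, dur), c(f_lo, f_hi)))
    }
    return(contour_spec(c(0, dur), c(f_hi, f_lo)))
  }
  interior <- vapply(seq_len(n_ext), function(k) {
    if (k %% 2 == 1) f_hi else f_lo
  }, numeric(1))
  if (n_ext >= 2 && !(f_lo %in% interior)) interior[length(interior)] <- f_lo
  # with a single interior extremum the low extreme must come from an endpoint
  if (n_ext == 1) s <- f_lo
  times <- seq(0, dur, length.out = n_ext + 2)
  contour_spec(times, c(s, interior, e))
}

#' Synthesize one call in the style of a catalog call type
#'
#' Renders [group_contour()] with the signal structure of the type's class:
#' whistles get one harmonic overtone; burst-pulse types are fully pulsed at
#' the midpoint of the published sideband-spacing range; pulsed-middle types
#' are pulsed over the middle third; transitions over the first half.
#'
#' @inheritParams group_contour
#' @param sample_rate Hz.
#' @param snr Band-integrated SNR in dB (`Inf` = noiseless).
#' @return A [wave_recording()].
#' @export
synth_group_call <- function(group, sample_rate = 96000, jitter = 0,
                             snr = Inf, seed = 1L) {
  ctr <- group_contour(group, jitter = jitter, seed = seed)
  dur <- max(ctr$times)
  cls <- group$call_class
  if (cls == "whistle") {
    # add one overtone when it fits below the aliasing guard; high-frequency
    # whistles keep only their fundamental
    nh <- if (sample_rate >= 2.5 * 2 * max(ctr$freqs_khz) * 1000) 1 else 0
    return(synth_whistle(ctr, sample_rate, n_harmonics = nh, snr = snr, seed = seed))
  }
  rate_hz <- 1000 * (group$sideband_lo + group$sideband_hi) / 2
  window <- switch(cls,
    burst_pulse = NULL,
    pulsed_middle = c(dur / 3, 2 * dur / 3),
    transition = c(0, dur / 2),
    stop("unknown call class: ", cls)
  )
  synth_burst_pulse(ctr, pulse_rate = rate_hz, pulsed_window = window,
                    sample_rate = sample_rate, snr = snr, seed = seed)
}
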