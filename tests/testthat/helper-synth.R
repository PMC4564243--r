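# Shared fixtures, built in code.

upsweep_5to8 <- function() contour_spec(c(0, 1.2), c(5, 8))

# analytic sine contour f(t) = 8 + 2 sin(2 pi t) kHz over 3 s, densely sampled
sine_trace <- function(dt = 0.005) {
  t <- seq(0, 3, by = dt)
  orcacall:::as_contour_trace(t, 8 + 2 * sin(2 * pi * t), rep(0, length(t)))
}

make_trace <- function(t, f) {
  orcacall:::as_contour_trace(t, f, rep(0, length(t)))
}

# spectrogram bin width (kHz) and hop (s) for the default parameterization
default_binw_khz <- function() 96000 / 512 / 1000
default_hop_s <- function() 256 / 96000

# exhaustive minimum within-SS over all 2-cluster bipartitions
brute_force_wss2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (msk in 1:(2^(n - 1) - 1)) {
    a <- as.logical(bitwAnd(msk, 2^(0:(n - 1))))
    w <- sum(scale(x[a, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(x[!a, , drop = FALSE], scale = FALSE)^2)
    best <- min(best, w)
  }
  best
}
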