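test_that("a constant-frequency whistle is a pure tone of the right length", {
  rec <- synth_whistle(contour_spec(c(0, 1), c(5, 5)), 96000)
  expect_length(rec$samples, 96000)
  S <- Mod(stats::fft(rec$samples))[1:48001]
  f_peak <- (which.max(S) - 1) # 1 Hz resolution over 1 s
  expect_lt(abs(f_peak - 5000), 1)
  expect_error(synth_whistle(contour_spec(c(0, 1), c(45, 45)), 96000), "2.5 x")
})

test_that("harmonic overtones sit at integer multiples with the specified rolloff", {
  rec <- synth_whistle(contour_spec(c(0, 1), c(5, 5)), 96000,
                       n_harmonics = 2, harmonic_rolloff = 6)
  S <- Mod(stats::fft(rec$samples))[1:48001]
  level <- function(f_hz) 20 * log10(max(S[(f_hz - 5):(f_hz + 5) + 1]))
  expect_equal(level(10000) - level(5000), -6, tolerance = 1)
  expect_equal(level(15000) - level(5000), -12, tolerance = 1)
})

test_that("pulsed carriers show sidebands spaced at the pulse rate", {
  rec <- synth_burst_pulse(contour_spec(c(0, 1), c(4, 4)), pulse_rate = 500)
  S <- Mod(stats::fft(rec$samples))[1:48001]
  # adjacent spectral peaks around the carrier, 1 Hz resolution
  pk <- function(f) (f - 60) + which.max(S[(f - 60):(f + 60) + 1]) - 1
  expect_equal(pk(4000) - pk(3500), 500, tolerance = 96000 / 2^17)
  expect_equal(pk(4500) - pk(4000), 500, tolerance = 96000 / 2^17)
  expect_error(synth_burst_pulse(contour_spec(c(0, 1), c(4, 4)), 5000),
               "below the lowest carrier")
})

test_that("duty cycle -> 1 collapses the burst-pulse to a pure tone", {
  bp <- synth_burst_pulse(contour_spec(c(0, 0.5), c(4, 4)), 500, duty_cycle = 0.999)
  tone <- synth_whistle(contour_spec(c(0, 0.5), c(4, 4)), 96000)
  S_bp <- Mod(stats::fft(bp$samples))
  S_t <- Mod(stats::fft(tone$samples))
  n <- length(S_bp) %/% 2
  # sideband region energy (200 Hz away from carrier and more) is negligible
  f <- (seq_len(n) - 1) * 96000 / length(S_bp)
  side <- f > 4200 & f < 4800 | f > 3200 & f < 3800
  carrier <- f > 3950 & f < 4050
  expect_lt(sum(S_bp[side]^2) / sum(S_bp[carrier]^2), 1e-3)
  expect_equal(length(bp$samples), length(tone$samples))
})

test_that("Gabor clicks have the requested envelope width and reflections", {
  rec <- synth_click_train(3, 0.01, 18, click_duration = 180e-6)
  env <- orcacall:::analytic_envelope(rec$samples)
  pk <- which.max(env)
  lev <- env[pk] * 10^(-3 / 20)
  l <- pk; while (env[l - 1] >= lev) l <- l - 1
  r <- pk; while (env[r + 1] >= lev) r <- r + 1
  width <- (r - l) / 96000
  expect_lt(width, 200e-6)
  expect_gt(width, 120e-6)

  # a -10 dB reflection at 0.5 ms appears in the click's autocorrelation
  rec2 <- synth_click_train(1, 0.01, 18, reflection = c(0.5e-3, 10))
  ac <- stats::acf(rec2$samples, lag.max = 96, plot = FALSE, type = "covariance")$acf[, 1, 1]
  lag_win <- 40:60 # 0.42-0.62 ms
  expect_equal((which.max(ac[lag_win + 1]) + lag_win[1] - 1) / 96000,
               0.5e-3, tolerance = 3 / 96000)
})

test_that("added noise hits the requested band-integrated SNR and is reproducible", {
  w <- synth_whistle(contour_spec(c(0, 1), c(5, 8)), 96000)
  band <- c(4.5, 8.8)
  nz1 <- add_noise(w, 10, seed = 3, band_khz = band)
  nz2 <- add_noise(w, 10, seed = 3, band_khz = band)
  expect_identical(nz1$samples, nz2$samples)
  nz3 <- add_noise(w, 10, seed = 4, band_khz = band)
  expect_false(identical(nz1$samples, nz3$samples))

  n <- length(w$samples)
  fr <- (seq_len(n) - 1) * 96000 / n / 1000
  ib <- fr >= band[1] & fr <= band[2]
  p_sig <- sum(Mod(stats::fft(w$samples))[ib]^2)
  p_noise <- sum(Mod(stats::fft(nz1$samples - w$samples))[ib]^2)
  expect_equal(10 * log10(p_sig / p_noise), 10, tolerance = 0.5)
})

test_that("sampled feature vectors respect counts, truncation and printed ranges", {
  cat0 <- load_reference_catalog()
  sv <- sample_feature_vectors(cat0, n_per_group = 20, spread = 0.05, seed = 2)
  expect_equal(nrow(sv), 180)
  expect_true(all(table(sv$group) == 20))
  # truncation contract: every value inside its group's printed range
  long <- dplyr::left_join(sv, cat0, by = c(group = "group_id"))
  for (p in c("min_f", "max_f", "start_f", "end_f", "delta_f", "duration",
              "n_extrema", "n_inflections", "fm_rate")) {
    expect_true(all(long[[p]] >= long[[paste0(p, "_lo")]] &
                      long[[p]] <= long[[paste0(p, "_hi")]]),
                info = p)
  }
  bc03 <- sv$duration[sv$group == "BC03"]
  expect_true(all(bc03 >= 3.9 & bc03 <= 11.3))
  # whistle groups have no sideband spacing
  expect_true(all(is.na(sv$sideband_spacing[sv$call_class == "whistle"])))
  # deterministic given the seed
  expect_identical(sv, sample_feature_vectors(cat0, 20, 0.05, seed = 2))
})
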