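test_that("a noiseless upsweep is traced within one bin at every frame", {
  ctr <- upsweep_5to8()
  sp <- compute_spectrogram(synth_whistle(ctr, 96000))
  tr <- extract_contour(sp)
  expect_gt(nrow(tr), 400)
  truth <- contour_frequency(ctr, tr$time)
  expect_true(all(abs(tr$freq_khz - truth) <= default_binw_khz()))
  expect_true(all(diff(tr$time) > 0))
})

test_that("at 10 dB SNR at least 95% of frames stay within one bin", {
  ctr <- upsweep_5to8()
  rec <- synth_whistle(ctr, 96000, snr = 10, seed = 21)
  tr <- extract_contour(compute_spectrogram(rec))
  expect_gt(nrow(tr), 300)
  truth <- contour_frequency(ctr, tr$time)
  expect_gte(mean(abs(tr$freq_khz - truth) <= default_binw_khz()), 0.95)
})

test_that("pure noise yields an empty trace, not an error", {
  rec <- add_noise(wave_recording(numeric(96000) + 1e-12, 96000), -80, seed = 5)
  tr <- extract_contour(compute_spectrogram(rec))
  expect_equal(nrow(tr), 0)
})

test_that("tracing is translation-equivariant in time", {
  ctr <- contour_spec(c(0, 0.6), c(6, 9))
  rec <- synth_whistle(ctr, 96000)
  sp1 <- compute_spectrogram(rec)
  k_hops <- 10
  shifted <- wave_recording(c(numeric(k_hops * 256), rec$samples), 96000)
  sp2 <- compute_spectrogram(shifted)
  tr1 <- extract_contour(sp1)
  tr2 <- extract_contour(sp2)
  shift <- k_hops * 256 / 96000
  # match frames by shifted time; interior frames must agree exactly (a frame
  # at either boundary may appear or vanish where the window overlaps silence)
  j <- match(round(tr1$time + shift, 9), round(tr2$time, 9))
  matched <- !is.na(j)
  expect_gte(mean(matched), 0.98)
  expect_equal(tr2$freq_khz[j[matched]], tr1$freq_khz[matched], tolerance = 1e-6)
})

test_that("harmonic overtones are reported exactly when synthesized", {
  ctr <- upsweep_5to8()
  sp2 <- compute_spectrogram(synth_whistle(ctr, 96000, n_harmonics = 2))
  tr2 <- extract_contour(sp2)
  rep2 <- detect_harmonics(sp2, tr2)
  expect_true(rep2$has_harmonics)
  expect_equal(rep2$multiples_found, c(2L, 3L))

  sp0 <- compute_spectrogram(synth_whistle(ctr, 96000))
  tr0 <- extract_contour(sp0)
  rep0 <- detect_harmonics(sp0, tr0)
  expect_false(rep0$has_harmonics)
  expect_length(rep0$multiples_found, 0)

  # tightening the tolerance can only shrink the multiples found
  rep_tight <- detect_harmonics(sp2, tr2, tolerance = 0.01)
  expect_true(all(rep_tight$multiples_found %in% rep2$multiples_found))
})

test_that("sideband spacing equals the pulse rate and whistles report none", {
  sp <- compute_spectrogram(synth_burst_pulse(contour_spec(c(0, 1), c(4, 4)), 500))
  tr <- extract_contour(sp)
  sb <- measure_sideband_spacing(sp, tr)
  expect_equal(sb$spacing_khz, 0.5, tolerance = default_binw_khz())
  expect_gte(sb$n_contours_used, 3)

  # amplitude-scaling invariance
  rec2 <- synth_burst_pulse(contour_spec(c(0, 1), c(4, 4)), 500)
  rec2$samples <- rec2$samples * 0.05
  sp2 <- compute_spectrogram(rec2)
  tr2 <- extract_contour(sp2)
  expect_equal(measure_sideband_spacing(sp2, tr2)$spacing_khz, sb$spacing_khz)

  # plain whistle, even with harmonics: absent
  spw <- compute_spectrogram(synth_whistle(upsweep_5to8(), 96000, n_harmonics = 2))
  trw <- extract_contour(spw)
  expect_true(is.na(measure_sideband_spacing(spw, trw)$spacing_khz))
})

test_that("sideband spacing of a partially pulsed call is measured off the pulsed section", {
  ctr <- contour_spec(c(0, 1.2), c(4, 5))
  sp <- compute_spectrogram(synth_burst_pulse(ctr, 800, pulsed_window = c(0.4, 0.8)))
  tr <- extract_contour(sp)
  mid <- measure_sideband_spacing(sp, tr, region = c(0.4, 0.8))
  expect_equal(mid$spacing_khz, 0.8, tolerance = default_binw_khz())
  ends <- measure_sideband_spacing(sp, tr, region = c(0, 0.35))
  expect_true(is.na(ends$spacing_khz))
})

test_that("call structure is classified from the pulsed-frame pattern", {
  spw <- compute_spectrogram(synth_whistle(upsweep_5to8(), 96000, n_harmonics = 2))
  expect_equal(classify_call(spw, extract_contour(spw)), "whistle")

  spb <- compute_spectrogram(synth_burst_pulse(contour_spec(c(0, 1), c(4, 4)), 500))
  expect_equal(classify_call(spb, extract_contour(spb)), "burst_pulse")

  spt <- compute_spectrogram(
    synth_burst_pulse(contour_spec(c(0, 1), c(4, 3)), 500, pulsed_window = c(0, 0.5))
  )
  expect_equal(classify_call(spt, extract_contour(spt)), "transition")

  spm <- compute_spectrogram(
    synth_burst_pulse(contour_spec(c(0, 1.2), c(4, 5)), 800, pulsed_window = c(0.4, 0.8))
  )
  expect_equal(classify_call(spm, extract_contour(spm)), "pulsed_middle")
})
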