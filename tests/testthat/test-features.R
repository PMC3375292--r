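test_that("every note yields exactly 36 measurements in fixed order", {
  expect_length(feature_names(), 36)
  rt <- roundtrip_note(diaemus_profile())
  expect_identical(names(rt$features)[1:36], feature_names())
  expect_gt(rt$features$duration_ms, 0)
  expect_true(all(rt$features[paste0("t_fme_", c("f0", "h1"), "_ms")] >= 0))
  expect_true(all(rt$features[paste0("t_fme_", c("f0", "h1"), "_ms")] <=
                    rt$features$duration_ms))
})

test_that("noiseless round trip recovers generator truth per species", {
  for (prof in list(desmodus_profile(), diaemus_profile(),
                    diphylla_profile())) {
    rt <- roundtrip_note(prof)
    expect_equal(rt$features$duration_ms, prof$duration_ms)  # annotation-based
    f0 <- as.numeric(rt$features[paste0("f0_p", seq(0, 90, 10), "_khz")])
    expect_lt(max(abs(f0 - rt$truth_khz)), 0.48828125)       # one FFT bin
    rel <- as.numeric(rt$features[paste0("rel_int_h", 1:3, "_db")])
    expect_lt(max(abs(rel - prof$harmonic_offsets_db)), 1)   # 1 dB
  }
})

test_that("relative harmonic intensities follow construction on a sweep", {
  w <- synthesize_note(10, data.frame(position = c(0, 1), khz = c(30, 20)),
                       harm_db = c(-3, -6, -9))
  samples <- c(numeric(500), w, numeric(500))
  sp <- compute_spectrogram(samples, 250000)
  note <- c(500, 500 + length(w)) / 250000
  tr <- track_fundamental(sp, note)
  fe <- extract_features(sp, tr, note)
  rel <- as.numeric(fe[paste0("rel_int_h", 1:3, "_db")])
  expect_true(all(abs(rel - c(-3, -6, -9)) < 1))
})

test_that("moderate noise (SNR >= 30 dB) keeps accuracy within two bins", {
  s <- noiseless_note_spec(desmodus_profile())
  s$snr_db <- 30
  set.seed(11)
  fe <- extract_from_specs(s)
  grid <- seq(0, 0.9, 0.1)
  prof <- desmodus_profile()
  truth <- pracma::pchip(prof$f0_anchors_khz$position,
                         prof$f0_anchors_khz$khz, grid)
  f0 <- as.numeric(fe[1, paste0("f0_p", seq(0, 90, 10), "_khz")])
  expect_lt(max(abs(f0 - truth)), 2 * 0.48828125)
})

test_that("a harmonic band with no room below Nyquist goes missing, flagged", {
  # fundamental 70->50 kHz: harmonic 3 band (4.5x f0) tops out above 125 kHz
  w <- suppressWarnings(
    synthesize_note(8, data.frame(position = c(0, 1), khz = c(70, 50)),
                    harm_db = c(0, -5, -10)))
  samples <- c(numeric(500), w, numeric(500))
  sp <- compute_spectrogram(samples, 250000)
  note <- c(500, 500 + length(w)) / 250000
  tr <- track_fundamental(sp, note, search_band_khz = c(40, 80))
  fe <- extract_features(sp, tr, note)
  expect_true(is.na(fe$fme_h3_khz))
  expect_true(is.na(fe$rel_int_h3_db))
  expect_true(3 %in% attr(fe, "clipped_harmonics"))
})

test_that("the amplitude screen excludes quiet notes with a reason", {
  s <- noiseless_note_spec(diaemus_profile())
  rec <- synthesize_recording(s)
  rec$samples <- rec$samples * 0.05   # below the 10% floor
  out <- extract_notes(rec, rec$annotations)
  expect_identical(nrow(out), 0L)
  expect_match(attr(out, "excluded")$reason, "below 10%")
})
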