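test_that("spectrogram geometry matches the analysis protocol", {
  x <- sin(2 * pi * 25000 * (0:49999) / 250000)
  sp <- compute_spectrogram(x, 250000)
  expect_equal(sp$bin_freqs_hz[2], 250000 / 512)          # 488.28125 Hz
  expect_equal(diff(sp$frame_times_s[1:2]) * 250000, 62)  # 50% of 125 samples
  # a constant 25 kHz tone peaks at round(25000/488.28) = bin 51 (1-based 52)
  peak_bins <- apply(sp$magnitude, 1, which.max)
  expect_true(all(peak_bins == round(25000 / (250000 / 512)) + 1))
})

test_that("silence yields an all-zero spectrogram and short input errors", {
  sp <- compute_spectrogram(numeric(1000), 250000)
  expect_true(all(sp$magnitude == 0))
  expect_error(compute_spectrogram(numeric(50), 250000), "shorter")
})

test_that("tracking a linear sweep recovers constant slope and zero concavity", {
  fx <- linear_sweep_fixture()
  tr <- track_fundamental(fx$spect, fx$note)
  fe <- extract_features(fx$spect, tr, fx$note)
  slopes <- as.numeric(fe[paste0("slope_p", seq(20, 80, 10), "_khz_ms")])
  concs <- as.numeric(fe[paste0("conc_p", seq(20, 80, 10), "_khz_ms2")])
  expect_true(all(abs(slopes - (-1.8)) < 0.05))
  # second derivative of a linear chirp is 0; allow finite-difference noise
  expect_true(all(abs(concs) < 0.05))
})

test_that("concavity recovers the curvature of a quadratic chirp", {
  # f(pos) = 36 - 24*pos + 8*pos^2 kHz over 10 ms: in time units
  # f(t) = 36 - 2.4*t + 0.08*t^2 (t in ms), so f''(t) = 0.16 kHz/ms^2
  pos <- seq(0, 1, 0.05)
  an <- data.frame(position = pos, khz = 36 - 24 * pos + 8 * pos^2)
  w <- synthesize_note(10, an, c(-Inf, -Inf, -Inf), contour = "linear")
  samples <- c(numeric(500), w, numeric(500))
  sp <- compute_spectrogram(samples, 250000)
  note <- c(500, 500 + length(w)) / 250000
  tr <- track_fundamental(sp, note)
  fe <- extract_features(sp, tr, note)
  concs <- as.numeric(fe[paste0("conc_p", seq(30, 70, 10), "_khz_ms2")])
  expect_true(all(abs(concs - 0.16) < 0.08))
})

test_that("empty search band errors; out-of-note interval errors", {
  fx <- linear_sweep_fixture()
  expect_error(track_fundamental(fx$spect, fx$note, c(200, 300)), "band")
  expect_error(track_fundamental(fx$spect, c(0.9, 1.0)), "frames")
})

test_that("lowering SNR never raises tracking confidence", {
  s <- noiseless_note_spec(diaemus_profile())
  confs <- vapply(c(Inf, 30, 10, 0), function(snr) {
    s$snr_db <- snr
    set.seed(4)
    rec <- synthesize_recording(s)
    sp <- compute_spectrogram(rec$samples, rec$sampling_rate_hz)
    tr <- track_fundamental(sp, c(rec$annotations$start_s[1],
                                  rec$annotations$end_s[1]))
    mean(tr$frames$confidence)
  }, numeric(1))
  expect_true(all(diff(confs) <= 0))
})
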