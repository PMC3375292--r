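test_that("zero hierarchy variance reproduces the species means exactly", {
  h <- hierarchy_config(2, 2, 5, seed = 3)
  s <- sample_population(desmodus_profile(), h)
  expect_true(all(s$duration_ms == 9.1))
  expect_true(all(s$f0_anchor_1 == 36.2))
  expect_true(all(s$f0_anchor_2 == 23.4))
  expect_true(all(s$f0_anchor_3 == 19.3))
  expect_true(all(s$harm_db_1 == 6.6))
})

test_that("identical config and seed give identical populations", {
  h <- hierarchy_config(2, 3, 8, sd_colony = 0.3, sd_individual = 0.8,
                        sd_within = 1.2, seed = 99)
  a <- sample_population(diaemus_profile(), h)
  b <- sample_population(diaemus_profile(), h)
  expect_identical(a, b)
  h2 <- hierarchy_config(2, 3, 8, sd_colony = 0.3, sd_individual = 0.8,
                         sd_within = 1.2, seed = 100)
  expect_false(identical(sample_population(diaemus_profile(), h2), a))
})

test_that("individual-level variance is realized at the configured scale", {
  # sd_individual = 1 kHz on one anchor, all else 0: the variance of the
  # per-individual anchor means over many replicate populations must be
  # ~1 kHz^2 (within 3 standard errors of a chi-square-based MC error)
  n_rep <- 60
  vars <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    h <- hierarchy_config(2, 2, 2, sd_individual = c(f0_anchor_2 = 1),
                          seed = 5000 + r)
    s <- sample_population(desmodus_profile(), h)
    m <- tapply(s$f0_anchor_2, s$individual, mean)
    vars[r] <- var(m)
  }
  # each replicate variance ~ chi2_3/3; mean over replicates ~ N(1, sqrt(2/3)/sqrt(n_rep))
  se <- sqrt(2 / 3) / sqrt(n_rep)
  expect_lt(abs(mean(vars) - 1), 3 * se)
})

test_that("over-dispersed configurations that break the sweep are rejected", {
  h <- hierarchy_config(1, 1, 3, sd_within = 1e6, seed = 2)
  expect_error(sample_population(desmodus_profile(), h),
               "downward-sweep")
})

test_that("note-count mixture matches the configured distribution", {
  h <- hierarchy_config(1, 4, 364, seed = 77)   # 1456 calls
  s <- sample_population(diaemus_profile(), h)
  per_call <- tapply(s$note_index, s$call_id, max)
  obs <- table(factor(pmin(per_call, 3), levels = 1:3)) / length(per_call)
  expected <- c(0.09, 0.75, 0.16)
  for (i in 1:3) {
    ci <- qnorm(0.995) * sqrt(expected[i] * (1 - expected[i]) / 1456)
    expect_lt(abs(obs[i] - expected[i]), ci + 1e-12)
  }
  # inter-note intervals cluster at the species mean
  iv <- s$inter_note_interval_ms[!is.na(s$inter_note_interval_ms)]
  expect_lt(abs(mean(iv) - 21.5), 0.25)
  expect_true(all(iv > 5))
})

test_that("the optional second-note offset shifts later notes only", {
  h <- hierarchy_config(1, 1, 40, seed = 15)
  s <- sample_population(diaemus_profile(), h,
                         second_note_offset = c(duration_ms = -3))
  expect_true(all(s$duration_ms[s$note_index == 1] == 18.6))
  expect_true(all(abs(s$duration_ms[s$note_index > 1] - 15.6) < 1e-12))
  expect_gt(sum(s$note_index > 1), 0)
})

test_that("a pure linear sweep has the stated instantaneous frequency", {
  # 36 -> 18 kHz over 10 ms: midpoint 27 kHz, read back off the track
  fx <- linear_sweep_fixture()
  tr <- track_fundamental(fx$spect, fx$note)
  expect_lt(abs(tr$khz[6] - 27), 0.489)   # one 488 Hz bin
})

test_that("silenced harmonics leave no energy above the fundamental band", {
  fx <- linear_sweep_fixture()
  hi <- fx$spect$bin_freqs_hz > 2 * 36 * 1000 * 0.75
  in_note <- fx$spect$frame_times_s >= fx$note[1] &
    fx$spect$frame_times_s <= fx$note[2]
  peak_hi <- max(fx$spect$magnitude[in_note, hi])
  peak_f0 <- max(fx$spect$magnitude[in_note, !hi])
  expect_lt(peak_hi / peak_f0, 1e-3)
})

test_that("an aliasing fundamental errors; aliasing harmonics are muted", {
  an <- data.frame(position = c(0, 1), khz = c(130, 120))
  expect_error(synthesize_note(5, an, c(0, 0, 0)), "Nyquist")
  an2 <- data.frame(position = c(0, 1), khz = c(70, 60))
  w <- capture_warnings(synthesize_note(5, an2, c(0, 0, 0)))
  expect_true(any(grepl("partial", w)))
})
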