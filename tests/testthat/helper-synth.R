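# shared fixtures built in code

# one noiseless note from a profile, as a single-row call_spec_tbl
noiseless_note_spec <- function(profile, seed = 1L) {
  h <- hierarchy_config(1, 1, 1, seed = seed)
  s <- sample_population(profile, h, snr_db = Inf)
  s <- s[1, , drop = FALSE]
  attr(s, "anchor_positions") <- profile$f0_anchors_khz$position
  class(s) <- c("call_spec_tbl", "data.frame")
  s
}

# synthesize + measure one noiseless profile note, returning features and
# the pchip ground truth on the 10-position grid
roundtrip_note <- function(profile) {
  s <- noiseless_note_spec(profile)
  rec <- synthesize_recording(s)
  sp <- compute_spectrogram(rec$samples, rec$sampling_rate_hz)
  note <- c(rec$annotations$start_s[1], rec$annotations$end_s[1])
  tr <- track_fundamental(sp, note)
  fe <- extract_features(sp, tr, note)
  grid <- seq(0, 0.9, 0.1)
  truth_khz <- pracma::pchip(profile$f0_anchors_khz$position,
                             profile$f0_anchors_khz$khz, grid)
  list(features = fe, truth_khz = truth_khz, track = tr)
}

# a padded linear sweep plus its spectrogram and note interval
linear_sweep_fixture <- function(f_start_khz = 36, f_end_khz = 18,
                                 duration_ms = 10, pad = 500) {
  w <- synthesize_note(duration_ms,
                       data.frame(position = c(0, 1),
                                  khz = c(f_start_khz, f_end_khz)),
                       harm_db = c(-Inf, -Inf, -Inf))
  samples <- c(numeric(pad), w, numeric(pad))
  sp <- compute_spectrogram(samples, 250000)
  note <- c(pad, pad + length(w)) / 250000
  list(spect = sp, note = note, n = length(w))
}

# balanced one-way Gaussian scores: g groups of n, between sd_b, within sd_w
one_way_scores <- function(g, n, sd_b, sd_w) {
  group <- rep(sprintf("g%02d", seq_len(g)), each = n)
  y <- rep(rnorm(g, 0, sd_b), each = n) + rnorm(g * n, 0, sd_w)
  data.frame(y = y, individual = group,
             colony = "c1", species = "sp1")
}

# feature table with subject structure for DFA/pDFA tests: n_per notes per
# subject, p variables, optional mean shift per test-factor level
subject_feature_table <- function(n_levels = 2, subj_per_level = 4,
                                  n_per = 20, p = 4,
                                  level_shift = 0, subject_sd = 1,
                                  within_sd = 1) {
  rows <- subj_per_level * n_levels * n_per
  lev <- rep(sprintf("L%d", seq_len(n_levels)), each = subj_per_level)
  subj <- sprintf("S%02d", seq_along(lev))
  x <- matrix(rnorm(rows * p, sd = within_sd), rows, p)
  test_factor <- rep(lev, each = n_per)
  control_factor <- rep(subj, each = n_per)
  for (i in seq_along(subj)) {
    idx <- control_factor == subj[i]
    shift <- rnorm(p, sd = subject_sd) +
      level_shift * (match(lev[i], unique(lev)) - 1)
    x[idx, ] <- sweep(x[idx, , drop = FALSE], 2, shift, "+")
  }
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, test_factor = test_factor, control_factor = control_factor)
}
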