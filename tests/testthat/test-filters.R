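make_note_table <- function(starts_ms, ends_ms, note_index, call_id,
                            individual = "A", file = "f1.wav") {
  data.frame(start_s = starts_ms / 1000, end_s = ends_ms / 1000,
             note_index = note_index, call_id = call_id,
             individual = individual, file = file)
}

test_that("first-note selection drops trailing and too-close notes", {
  # a 3-note call with 21.5 ms gaps: only note 1 survives
  tbl <- make_note_table(c(0, 40.1, 80.2), c(18.6, 58.7, 98.8),
                         1:3, "c1")
  expect_identical(select_first_notes(tbl)$note_index, 1L)
  # a single isolated note is kept
  one <- make_note_table(500, 510, 1, "c2")
  expect_identical(nrow(select_first_notes(one)), 1L)
  # two calls 500 ms apart: both first notes kept
  two <- make_note_table(c(0, 10, 500, 510), c(9, 19, 509, 519),
                         c(1, 2, 1, 2), c("c1", "c1", "c2", "c2"))
  kept <- select_first_notes(two)
  expect_identical(kept$call_id, c("c1", "c2"))
  # a first note only 25 ms after the previous call's last note is dropped
  close <- make_note_table(c(0, 34), c(9, 43), c(1, 1), c("c1", "c2"))
  expect_identical(nrow(select_first_notes(close)), 1L)
  expect_error(select_first_notes(two[, -1]), "timing")
})

test_that("first-note selection and the 45-note filter are idempotent", {
  h <- hierarchy_config(1, 2, 30, seed = 12)
  s <- sample_population(diaemus_profile(), h)
  s$file <- paste0(s$individual, ".wav")
  s$start_s <- s$onset_time_s
  s$end_s <- s$onset_time_s + s$duration_ms / 1000
  once <- select_first_notes(s)
  expect_identical(select_first_notes(once), once)
  filt <- min_notes_filter(once, threshold = 10, quiet = TRUE)
  again <- min_notes_filter(filt, threshold = 10, quiet = TRUE)
  expect_identical(as.data.frame(filt), as.data.frame(again))
})

test_that("the minimum-notes filter keeps 45 and drops 44", {
  notes <- data.frame(individual = c(rep("Cindy", 45), rep("Angelica", 44),
                                     rep("Mya", 5)),
                      v = 1)
  out <- min_notes_filter(notes, threshold = 45, quiet = TRUE)
  expect_identical(sort(unique(out$individual)), "Cindy")
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$individual, c("Angelica", "Mya"))
  expect_setequal(dropped$n_notes, c(44L, 5L))
  # empty in, empty out
  empty <- min_notes_filter(notes[0, ], quiet = TRUE)
  expect_identical(nrow(empty), 0L)
})

test_that("double-note pairing concatenates both notes plus the interval", {
  h <- hierarchy_config(1, 2, 60, seed = 13)
  s <- sample_population(diaemus_profile(), h)
  feats <- cbind(as.data.frame(matrix(0, nrow(s), 36,
                                      dimnames = list(NULL, feature_names()))),
                 s[c("call_id", "note_index", "individual", "species",
                     "inter_note_interval_ms")])
  feats$duration_ms <- s$duration_ms
  paired <- select_double_notes(feats)
  per_call <- tapply(s$note_index, s$call_id, max)
  expect_identical(nrow(paired), sum(per_call >= 2))
  expect_true(all(c("duration_ms_n1", "duration_ms_n2",
                    "inter_note_interval_ms") %in% names(paired)))
  expect_true(all(paired$inter_note_interval_ms > 5))
  expect_lt(abs(mean(paired$inter_note_interval_ms) - 21.5), 1)
  # ~75% of Diaemus calls are doubles (9/75/16 mixture -> >= 2 notes 91%)
  expect_gt(nrow(paired) / length(per_call), 0.8)
})
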