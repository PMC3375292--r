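#' Names of the 36 per-note acoustic measurements
#'
#' The measurement vector per note is: duration (1); fundamental frequency
#' at the start and at 10--90% into the note (10); frequency of most
#' energy (FME) of the fundamental and harmonics 1--3 (4); time of each
#' FME relative to note start (4); slope of the fundamental at 20--80% in
#' 10% steps (7); concavity at the same positions (7); and intensity of
#' harmonics 1--3 relative to the fundamental (3).
#'
#' @return character vector of length 36, in fixed column order.
#' @export
feature_names <- function() {
  c("duration_ms",
    paste0("f0_p", seq(0, 90, 10), "_khz"),
    paste0("fme_", c("f0", "h1", "h2", "h3"), "_khz"),
    paste0("t_fme_", c("f0", "h1", "h2", "h3"), "_ms"),
    paste0("slope_p", seq(20, 80, 10), "_khz_ms"),
    paste0("conc_p", seq(20, 80, 10), "_khz_ms2"),
    paste0("rel_int_h", 1:3, "_db"))
}

#' Extract the 36 acoustic measurements for one note
#'
#' Duration is taken from the annotation marks. Fundamental frequencies
#' are read from the track at the 10 standard positions. For each partial
#' k (k = 1 fundamental), the per-frame harmonic band is
#' `k * f0(t) +/- f0(t)/2`; the FME is the frequency of the
#' maximum-magnitude time-frequency cell in that band over the whole note
#' and its time is measured from note start. Slopes are central
#' differences of the track over +/-10% of the duration, concavities
#' second central differences. Relative harmonic intensity is
#' `20*log10` of the ratio of a harmonic band's peak magnitude to the
#' fundamental band's. A harmonic whose band would cross Nyquist gets
#' `NA` measurements and is listed in the `clipped_harmonics` attribute.
#'
#' @param spect a [compute_spectrogram()] result covering the note.
#' @param track a [track_fundamental()] result for the note.
#' @param note numeric length 2: annotation start/end (s).
#' @param n_harmonics harmonics above the fundamental to measure (<= 3).
#' @return one-row data.frame with the [feature_names()] columns.
#' @export
extract_features <- function(spect, track, note, n_harmonics = 3) {
  stopifnot(inherits(spect, "spectrogram"),
            inherits(track, "fundamental_track"), n_harmonics <= 3)
  duration_ms <- (note[2] - note[1]) * 1000
  grid <- track$positions
  f0_grid <- track$khz

  in_note <- which(spect$frame_times_s >= note[1] &
                     spect$frame_times_s <= note[2])
  f0_frames <- interp_extrap(track$frames$time_s, track$frames$khz,
                             spect$frame_times_s[in_note]) * 1000
  nyq <- spect$sampling_rate_hz / 2

  fme_khz <- rep(NA_real_, 4)
  t_fme_ms <- rep(NA_real_, 4)
  peak_mag <- rep(NA_real_, 4)
  clipped <- integer(0)
  for (k in 1:4) {
    if (k > n_harmonics + 1) break
    # frames whose harmonic band fits below Nyquist; a partial with no
    # measurable frame at all gets NA and is flagged
    usable <- which(k * f0_frames + f0_frames / 2 <= nyq)
    if (length(usable) == 0) { clipped <- c(clipped, k - 1L); next }
    best <- c(-Inf, NA, NA)            # magnitude, freq, time
    for (j in usable) {
      ctr <- k * f0_frames[j]
      sel <- which(spect$bin_freqs_hz >= ctr - f0_frames[j] / 2 &
                     spect$bin_freqs_hz <= ctr + f0_frames[j] / 2)
      if (length(sel) == 0) next
      row <- spect$magnitude[in_note[j], ]
      b <- sel[which.max(row[sel])]
      if (row[b] > best[1]) {
        delta <- parabolic_offset(row, b)
        best <- c(row[b],
                  spect$bin_freqs_hz[b] + delta * spect$bin_freqs_hz[2],
                  spect$frame_times_s[in_note[j]])
      }
    }
    if (is.finite(best[1])) {
      peak_mag[k] <- best[1]
      fme_khz[k] <- best[2] / 1000
      t_fme_ms[k] <- (best[3] - note[1]) * 1000
    }
  }
  rel_int <- 20 * log10(peak_mag[2:4] / peak_mag[1])

  pos <- seq(0.2, 0.8, by = 0.1)
  fat <- function(p) f0_grid[match(round(p, 10), round(grid, 10))]
  dt <- duration_ms / 10                # 10% of the note, in ms
  slope <- (fat(pos + 0.1) - fat(pos - 0.1)) / (2 * dt)
  conc <- (fat(pos + 0.1) - 2 * fat(pos) + fat(pos - 0.1)) / dt^2

  out <- as.data.frame(as.list(setNames(
    c(duration_ms, f0_grid, fme_khz, t_fme_ms, slope, conc, rel_int),
    feature_names())))
  attr(out, "clipped_harmonics") <- clipped
  attr(out, "low_confidence") <- isTRUE(attr(track, "low_confidence"))
  out
}

#' Extract features for every annotated note of a recording
#'
#' Slices a short segment around each annotated note (`margin_ms` on both
#' sides), computes its spectrogram, then tracks and measures the note.
#' Notes whose peak amplitude falls outside the unclipped range (10--99%
#' of full scale) are excluded and listed in the `excluded` attribute
#' with a reason.
#'
#' @param recording list with `samples` and `sampling_rate_hz` (as from
#'   [read_wav()] or [synthesize_recording()]).
#' @param annotations data.frame with `start_s`, `end_s` and any label
#'   columns to carry through (label columns are copied onto the output).
#' @param params a [spectrogram_params()].
#' @param search_band_khz fundamental search band.
#' @param n_harmonics harmonics to measure.
#' @param amplitude_screen logical; apply the 10--99% peak-amplitude
#'   screen.
#' @param margin_ms context kept around each note for analysis.
#' @return data.frame: 36 measurement columns then label columns, one row
#'   per retained note.
#' @export
extract_notes <- function(recording, annotations,
                          params = spectrogram_params(),
                          search_band_khz = c(5, 60), n_harmonics = 3,
                          amplitude_screen = TRUE, margin_ms = 2) {
  fs <- recording$sampling_rate_hz
  label_cols <- names(annotations)   # timing columns carried through as labels
  rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(annotations))) {
    note_abs <- c(annotations$start_s[i], annotations$end_s[i])
    idx <- max(1, floor(note_abs[1] * fs) + 1):
      min(length(recording$samples), ceiling(note_abs[2] * fs))
    peak <- max(abs(recording$samples[idx]))
    if (amplitude_screen && (peak < 0.10 || peak > 0.99)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(row = i, peak = peak,
                   reason = if (peak < 0.10) "below 10% amplitude"
                            else "clipped (above 99% amplitude)")
      next
    }
    s0 <- max(0, note_abs[1] - margin_ms / 1000)
    i0 <- floor(s0 * fs) + 1L
    i1 <- min(length(recording$samples),
              ceiling((note_abs[2] + margin_ms / 1000) * fs))
    spect <- compute_spectrogram(recording$samples[i0:i1], fs, params)
    note <- note_abs - (i0 - 1L) / fs
    track <- track_fundamental(spect, note, search_band_khz)
    feats <- extract_features(spect, track, note, n_harmonics)
    rows[[length(rows) + 1L]] <-
      cbind(feats, annotations[i, label_cols, drop = FALSE])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 36 + length(label_cols))),
                    c(feature_names(), label_cols))
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
  out
}

#' Extract features for a whole on-disk dataset
#'
#' Reads `annotations.csv` and the WAV files written by [write_dataset()]
#' and runs [extract_notes()] per file.
#'
#' @param dir dataset directory.
#' @inheritParams extract_notes
#' @return combined feature data.frame (see [extract_notes()]).
#' @export
extract_dataset <- function(dir, params = spectrogram_params(),
                            search_band_khz = c(5, 60), n_harmonics = 3,
                            amplitude_screen = TRUE) {
  ann <- utils::read.csv(file.path(dir, "annotations.csv"))
  parts <- lapply(unique(ann$file), function(f) {
    rec <- read_wav(file.path(dir, f))
    extract_notes(rec, ann[ann$file == f, , drop = FALSE], params,
                  search_band_khz, n_harmonics, amplitude_screen)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "excluded") <- do.call(rbind, lapply(parts, attr, "excluded"))
  out
}

#' Extract features directly from call specs, without audio files
#'
#' Convenience path used throughout the analyses: synthesizes each call
#' in memory (notes plus inter-note intervals, no inter-call silence) and
#' measures every note, skipping the WAV round trip. Annotation times in
#' the output stay on the recording's absolute time axis.
#'
#' @param specs a `call_spec_tbl`.
#' @param sampling_rate_hz synthesis sampling rate.
#' @inheritParams extract_notes
#' @return combined feature data.frame (see [extract_notes()]).
#' @export
extract_from_specs <- function(specs, params = spectrogram_params(),
                               search_band_khz = c(5, 60), n_harmonics = 3,
                               amplitude_screen = TRUE,
                               sampling_rate_hz = 250000) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed <- attr(specs, "seed")
  set.seed(if (is.null(seed)) 0L else seed + 1000L)
  parts <- lapply(unique(specs$call_id), function(k) {
    sub <- specs[specs$call_id == k, , drop = FALSE]
    attr(sub, "anchor_positions") <- attr(specs, "anchor_positions")
    off <- min(sub$onset_time_s)
    sub$onset_time_s <- sub$onset_time_s - off
    rec <- synthesize_recording(sub, sampling_rate_hz)
    out <- extract_notes(rec, rec$annotations, params, search_band_khz,
                         n_harmonics, amplitude_screen)
    out$start_s <- out$start_s + off
    out$end_s <- out$end_s + off
    out$onset_time_s <- out$onset_time_s + off
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "excluded") <- do.call(rbind, lapply(parts, attr, "excluded"))
  out
}
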