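#' Sample a synthetic call population with nested random effects
#'
#' Draws ground-truth note parameters for a population of calls with the
#' nested variance structure the signature analyses assume: every acoustic
#' parameter equals the species mean plus a colony effect, an individual
#' effect, and a per-note effect, each Gaussian with the standard
#' deviation configured in `hierarchy`. Colony and individual effects are
#' drawn once and reused across all notes of that colony/individual;
#' within-call notes share the call's individual effect but get fresh
#' per-note effects. Perturbed fundamental anchors must still describe a
#' downward sweep; note-level effects violating it are redrawn up to 100
#' times before the configuration is rejected as too variable for the
#' profile.
#'
#' `notes_per_individual` counts calls (first notes) per individual; each
#' call then contains 1+ notes according to the profile's note-count
#' distribution, with inter-note intervals drawn from
#' Normal(profile mean, `interval_sd_ms`) truncated above `min_interval_ms`.
#'
#' @param profile a [species_profile()].
#' @param hierarchy a [hierarchy_config()].
#' @param population population label attached to every note (e.g.
#'   `"captive"` or `"wild"`).
#' @param snr_db per-note signal-to-noise ratio for later synthesis, in dB
#'   (`Inf` = noiseless).
#' @param interval_sd_ms,min_interval_ms dispersion and truncation of the
#'   inter-note interval.
#' @param inter_call_gap_ms silent gap between calls in a recording.
#' @param second_note_offset optional named numeric: a fixed shift added
#'   to the acoustic parameters of every note after the first within a
#'   call (e.g. `c(duration_ms = -2)`). Default none; whether later
#'   notes differ systematically is an open question, so no offset is
#'   assumed.
#'
#' @return a data.frame of class `call_spec_tbl`, one row per note, with
#'   label columns (`species`, `population`, `colony`, `individual`,
#'   `sex`, `session`, `call_id`, `note_index`), timing (`onset_time_s`,
#'   `inter_note_interval_ms`), `snr_db`, and ground-truth acoustic
#'   parameters (`duration_ms`, `f0_anchor_*` in kHz, `harm_db_*`).
#'   The anchor relative positions are kept in the `anchor_positions`
#'   attribute.
#' @export
sample_population <- function(profile, hierarchy, population = "pop1",
                              snr_db = 30, interval_sd_ms = 1,
                              min_interval_ms = 5,
                              inter_call_gap_ms = 500,
                              second_note_offset = NULL) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(hierarchy, "hierarchy_config"))
  mu <- profile_param_vector(profile)
  pn <- names(mu)
  sd_c <- expand_sd(hierarchy$sd_colony, pn, "sd_colony")
  sd_i <- expand_sd(hierarchy$sd_individual, pn, "sd_individual")
  sd_w <- expand_sd(hierarchy$sd_within, pn, "sd_within")
  note2_shift <- if (is.null(second_note_offset)) numeric(length(mu))
                 else expand_sd(second_note_offset, pn, "second_note_offset")
  positions <- profile$f0_anchors_khz$position
  anchor_idx <- grep("^f0_anchor_", pn)
  note_counts <- as.integer(names(profile$notes_per_call_dist))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(hierarchy$seed)

  rows <- vector("list", 0)
  sexes <- c("F", "M")
  subj <- 0L
  for (co in seq_len(hierarchy$n_colonies)) {
    colony_eff <- stats::rnorm(length(mu), 0, sd_c)
    colony_id <- sprintf("%s_%s_C%d", profile$name, population, co)
    for (ind in seq_len(hierarchy$individuals_per_colony)) {
      subj <- subj + 1L
      ind_eff <- stats::rnorm(length(mu), 0, sd_i)
      ind_id <- sprintf("%s_I%d", colony_id, ind)
      sex <- sexes[(subj - 1L) %% 2L + 1L]
      session_of <- rep(seq_len(hierarchy$n_sessions),
                        length.out = hierarchy$notes_per_individual)
      t_cursor <- rep(0, hierarchy$n_sessions)
      for (cl in seq_len(hierarchy$notes_per_individual)) {
        n_notes <- sample(note_counts, 1, prob = profile$notes_per_call_dist)
        call_id <- sprintf("%s_call%03d", ind_id, cl)
        ses <- session_of[cl]
        for (nt in seq_len(n_notes)) {
          base_mu <- if (nt > 1) mu + note2_shift else mu
          p <- draw_note_params(base_mu, colony_eff, ind_eff, sd_w,
                                positions, anchor_idx, profile$name)
          interval <- if (nt < n_notes) {
            iv <- stats::rnorm(1, profile$inter_note_interval_ms, interval_sd_ms)
            max(iv, min_interval_ms)
          } else NA_real_
          rows[[length(rows) + 1L]] <- c(
            list(species = profile$name, population = population,
                 colony = colony_id, individual = ind_id, sex = sex,
                 session = ses, call_id = call_id, note_index = nt,
                 onset_time_s = t_cursor[ses] / 1000,
                 inter_note_interval_ms = interval, snr_db = snr_db),
            as.list(p))
          t_cursor[ses] <- t_cursor[ses] + p[["duration_ms"]] +
            (if (is.na(interval)) inter_call_gap_ms else interval)
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  structure(out, anchor_positions = positions, seed = hierarchy$seed,
            class = c("call_spec_tbl", "data.frame"))
}

# note parameters = mean + colony + individual + note effect, with the
# downward-sweep constraint enforced by redrawing the note effect
draw_note_params <- function(mu, colony_eff, ind_eff, sd_w,
                             positions, anchor_idx, species) {
  base <- mu + colony_eff + ind_eff
  for (attempt in 1:100) {
    p <- base + stats::rnorm(length(mu), 0, sd_w)
    core <- p[anchor_idx][positions <= 0.9 + 1e-9]
    if (p[["duration_ms"]] > 0 && all(diff(core) < 0) && all(p[anchor_idx] > 0))
      return(p)
  }
  stop("cannot preserve the downward-sweep invariant for species '", species,
       "' after 100 redraws: variance too large for the profile")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthesize the waveform of a single note
#'
#' Renders a downward FM sweep as a sum of up to four partials. The
#' instantaneous fundamental follows a monotone piecewise-cubic
#' interpolant through the contour anchors (or linear interpolation on
#' request); partial k (k = 1 fundamental) is `a_k * sin(k * phase)` with
#' `20*log10(a_k / a_1)` equal to the configured harmonic offset. A
#' raised-cosine amplitude ramp covers the first and last 10% of the note.
#' Harmonics whose band would cross the Nyquist frequency are dropped with
#' a warning naming the partial; a fundamental at or above Nyquist is an
#' error.
#'
#' @param duration_ms note duration (ms).
#' @param anchors data.frame with `position` and `khz` columns.
#' @param harm_db harmonic offsets in dB (length 3); `-Inf` silences a
#'   harmonic.
#' @param sampling_rate_hz sampling rate.
#' @param contour `"pchip"` (monotone cubic, default) or `"linear"`.
#' @param ramp_fraction raised-cosine onset/offset length as a fraction of
#'   the note duration.
#' @return numeric waveform, peak amplitude 1.
#' @export
synthesize_note <- function(duration_ms, anchors, harm_db,
                            sampling_rate_hz = 250000,
                            contour = c("pchip", "linear"),
                            ramp_fraction = 0.1) {
  contour <- match.arg(contour)
  n <- max(2L, round(duration_ms / 1000 * sampling_rate_hz))
  tt <- (seq_len(n) - 1) / sampling_rate_hz
  anchor_t <- anchors$position * duration_ms / 1000
  f0 <- if (contour == "pchip" && nrow(anchors) > 2) {
    pracma::pchip(anchor_t, anchors$khz * 1000, tt)
  } else {
    stats::approx(anchor_t, anchors$khz * 1000, xout = tt, rule = 2)$y
  }
  nyq <- sampling_rate_hz / 2
  if (max(f0) >= nyq)
    stop("fundamental reaches ", round(max(f0)), " Hz, at or above Nyquist (",
         nyq, " Hz)")
  phase <- 2 * pi * cumsum(f0) / sampling_rate_hz
  amps <- c(1, 10^(harm_db / 20))
  wave <- numeric(n)
  for (k in seq_along(amps)) {
    if (amps[k] == 0) next
    if (k * min(f0) >= nyq) {
      warning("partial ", k, " lies entirely at or above Nyquist (min ",
              round(k * min(f0)), " Hz); dropped", call. = FALSE)
      next
    }
    # mute the partial wherever it would alias, with a smooth taper just
    # below Nyquist to avoid switching clicks
    gate <- pmin(1, pmax(0, (nyq - k * f0) / (0.02 * nyq)))
    wave <- wave + amps[k] * gate * sin(k * phase)
  }
  wave <- wave * raised_cosine_env(n, ramp_fraction)
  wave / max(abs(wave))
}

raised_cosine_env <- function(n, frac) {
  env <- rep(1, n)
  m <- max(1L, floor(n * frac))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  env[seq_len(m)] <- ramp
  env[n + 1 - seq_len(m)] <- ramp
  env
}

#' Synthesize an annotated recording from call specs
#'
#' Renders every note of one recording (typically one individual and
#' session) at its scheduled onset, adds white Gaussian noise according to
#' each spec's `snr_db` (defined as peak note power over broadband noise
#' power), and returns the waveform with note annotations.
#'
#' @param specs rows of a `call_spec_tbl` sharing one recording.
#' @param sampling_rate_hz sampling rate.
#' @param tail_s silence appended after the last note.
#' @return list with `samples` (peak-normalized to 0.9), `sampling_rate_hz`
#'   and `annotations` (data.frame: `start_s`, `end_s`, plus all spec
#'   columns).
#' @export
synthesize_recording <- function(specs, sampling_rate_hz = 250000,
                                 tail_s = 0.005) {
  stopifnot(nrow(specs) >= 1)
  positions <- attr(specs, "anchor_positions")
  if (is.null(positions)) stop("specs must carry an anchor_positions attribute")
  anchor_cols <- grep("^f0_anchor_", names(specs), value = TRUE)
  end_s <- specs$onset_time_s + specs$duration_ms / 1000
  n_total <- ceiling((max(end_s) + tail_s) * sampling_rate_hz)
  wave <- numeric(n_total)
  for (i in seq_len(nrow(specs))) {
    anchors <- data.frame(position = positions,
                          khz = as.numeric(specs[i, anchor_cols]))
    note <- synthesize_note(specs$duration_ms[i], anchors,
                            as.numeric(specs[i, paste0("harm_db_", 1:3)]),
                            sampling_rate_hz)
    at <- round(specs$onset_time_s[i] * sampling_rate_hz) + 1L
    idx <- at:(at + length(note) - 1L)
    wave[idx] <- wave[idx] + note
  }
  snr <- min(specs$snr_db)
  if (is.finite(snr)) {
    peak_pow <- max(abs(wave))^2 / 2
    sigma <- sqrt(peak_pow / 10^(snr / 10))
    wave <- wave + stats::rnorm(n_total, 0, sigma)
  }
  ann <- cbind(data.frame(start_s = specs$onset_time_s, end_s = end_s),
               as.data.frame(specs))
  list(samples = 0.9 * wave / max(abs(wave)),
       sampling_rate_hz = sampling_rate_hz, annotations = ann)
}

#' Write a synthetic dataset as WAV files plus an annotation table
#'
#' Groups call specs by (individual, session) into one recording each,
#' synthesizes and writes the WAV files, and writes `annotations.csv`
#' with one row per note: file, start/end time (seconds, 6 decimals), all
#' labels, and all ground-truth parameters. Output is reproducible: the
#' noise seed is derived from the population seed.
#'
#' @param specs a `call_spec_tbl` from [sample_population()] (or several
#'   concatenated with [rbind_specs()]).
#' @param out_dir output directory, created if missing.
#' @param sampling_rate_hz sampling rate.
#' @return invisibly, the annotation data.frame (with `file` column).
#' @export
write_dataset <- function(specs, out_dir, sampling_rate_hz = 250000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann_path <- file.path(out_dir, "annotations.csv")
  if (nrow(specs) == 0) {
    empty <- data.frame(file = character(), start_s = character())
    utils::write.csv(empty, ann_path, row.names = FALSE)
    return(invisible(empty))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed <- attr(specs, "seed")
  set.seed(if (is.null(seed)) 0L else seed + 1000L)
  key <- interaction(specs$individual, specs$session, drop = TRUE)
  anns <- list()
  for (k in levels(key)) {
    sub <- specs[key == k, , drop = FALSE]
    attr(sub, "anchor_positions") <- attr(specs, "anchor_positions")
    rec <- synthesize_recording(sub, sampling_rate_hz)
    fname <- sprintf("%s_s%s.wav", sub$individual[1], sub$session[1])
    write_wav(rec$samples, file.path(out_dir, fname), sampling_rate_hz)
    anns[[k]] <- cbind(data.frame(file = fname), rec$annotations)
  }
  ann <- do.call(rbind, anns)
  rownames(ann) <- NULL
  num <- vapply(ann, is.numeric, logical(1))
  ann_out <- ann
  ann_out[num] <- lapply(ann_out[num], function(x) round(x, 6))
  utils::write.csv(ann_out, ann_path, row.names = FALSE)
  attr(ann, "anchor_positions") <- attr(specs, "anchor_positions")
  invisible(ann)
}

#' Combine call-spec tables from several populations
#'
#' @param ... `call_spec_tbl` objects with identical anchor layouts.
#' @return a single `call_spec_tbl`.
#' @export
rbind_specs <- function(...) {
  parts <- list(...)
  pos <- attr(parts[[1]], "anchor_positions")
  for (p in parts)
    if (!isTRUE(all.equal(attr(p, "anchor_positions"), pos)))
      stop("all populations must share the same anchor positions")
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  structure(out, anchor_positions = pos, seed = attr(parts[[1]], "seed"),
            class = c("call_spec_tbl", "data.frame"))
}
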