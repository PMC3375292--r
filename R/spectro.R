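#' Spectrogram analysis parameters
#'
#' Defaults follow the measurement protocol for these calls: 0.5 ms
#' Blackman analysis windows zero-padded to 512-point FFTs (488 Hz bin
#' spacing at 250 kHz) with 50% overlap.
#'
#' @param window_ms analysis window length (ms).
#' @param window_type `"blackman"`, `"hanning"`, or `"hamming"`.
#' @param fft_points FFT length; the window is zero-padded up to it.
#' @param overlap_fraction fractional overlap between windows in \[0, 1).
#' @return a list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_ms = 0.5, window_type = "blackman",
                               fft_points = 512L, overlap_fraction = 0.5) {
  stopifnot(window_ms > 0, fft_points >= 2,
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(window_ms = window_ms, window_type = window_type,
                 fft_points = as.integer(fft_points),
                 overlap_fraction = overlap_fraction),
            class = "spectrogram_params")
}

window_vector <- function(type, n) {
  switch(type,
         blackman = signal::blackman(n),
         hanning = signal::hanning(n),
         hamming = signal::hamming(n),
         stop("unknown window type: ", type))
}

#' Compute a magnitude spectrogram
#'
#' Short-time Fourier transform with the configured window, zero-padding
#' and overlap. Frame times are window centers measured from the start of
#' the waveform; bin spacing is `sampling_rate_hz / fft_points`.
#'
#' @param samples numeric waveform.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param params a [spectrogram_params()].
#' @return object of class `spectrogram`: list with `magnitude`
#'   (frames x bins), `frame_times_s`, `bin_freqs_hz`, `sampling_rate_hz`,
#'   `params`.
#' @export
compute_spectrogram <- function(samples, sampling_rate_hz,
                                params = spectrogram_params()) {
  wl <- round(params$window_ms / 1000 * sampling_rate_hz)
  if (length(samples) < wl)
    stop("waveform (", length(samples), " samples) shorter than one ",
         params$window_ms, " ms window (", wl, " samples)")
  if (wl > params$fft_points)
    stop("window (", wl, " samples) longer than fft_points (",
         params$fft_points, ")")
  win <- window_vector(params$window_type, wl)
  step <- max(1L, round(wl * (1 - params$overlap_fraction)))
  starts <- seq(1L, length(samples) - wl + 1L, by = step)
  nfft <- params$fft_points
  nbins <- nfft %/% 2L + 1L
  frames <- matrix(0, nrow = nfft, ncol = length(starts))
  for (j in seq_along(starts))
    frames[seq_len(wl), j] <- samples[starts[j]:(starts[j] + wl - 1L)] * win
  mag <- Mod(stats::mvfft(frames))[seq_len(nbins), , drop = FALSE]
  structure(list(magnitude = t(mag),
                 frame_times_s = (starts - 1 + (wl - 1) / 2) / sampling_rate_hz,
                 bin_freqs_hz = (seq_len(nbins) - 1) * sampling_rate_hz / nfft,
                 sampling_rate_hz = sampling_rate_hz,
                 params = params),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, %.1f Hz bins, %.3f ms step\n",
              nrow(x$magnitude), ncol(x$magnitude),
              x$bin_freqs_hz[2], diff(x$frame_times_s[1:2]) * 1000))
  invisible(x)
}

# linear interpolation with linear extrapolation past both ends
interp_extrap <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

#' Track the fundamental frequency of one note
#'
#' Band-limited peak tracking: within the search band, the strongest frame
#' anchors the track, which is then extended frame-by-frame in both
#' directions under a continuity constraint (at most `max_jump_bins` bins
#' between consecutive frames). Each peak is refined by 3-point parabolic
#' interpolation for sub-bin precision, and the per-frame track is
#' resampled by linear interpolation (with linear extrapolation at the
#' note edges) onto the standard relative-position grid 0, 0.1, ..., 0.9.
#'
#' A frame counts as below the noise floor when its in-band peak is less
#' than `floor_factor` times the median in-band magnitude of that frame;
#' if more than 30% of frames are, the track is flagged low-confidence
#' (attribute `low_confidence`), not an error.
#'
#' @param spect a [compute_spectrogram()] result.
#' @param note numeric length 2: note start and end time (s).
#' @param search_band_khz numeric length 2: band searched for the
#'   fundamental.
#' @param max_jump_bins continuity constraint between consecutive frames.
#' @param floor_factor noise-floor multiple for the confidence flag.
#' @param rel_threshold_db a spectral peak qualifies as a fundamental
#'   candidate if it is within this many dB of the frame's in-band
#'   maximum; the lowest-frequency qualified peak seeds the track (the
#'   fundamental is the lowest partial, but not always the strongest).
#' @return object of class `fundamental_track`: list with `positions`
#'   (0--0.9 grid), `khz` at each position, `confidence` per position, and
#'   `frames` (per-frame `time_s`, `khz`, `confidence`).
#' @export
track_fundamental <- function(spect, note, search_band_khz = c(5, 60),
                              max_jump_bins = 3L, floor_factor = 2,
                              rel_threshold_db = 20) {
  stopifnot(inherits(spect, "spectrogram"), length(note) == 2,
            note[2] > note[1])
  band_hz <- sort(search_band_khz) * 1000
  bins <- which(spect$bin_freqs_hz >= band_hz[1] &
                  spect$bin_freqs_hz <= band_hz[2])
  if (length(bins) == 0) stop("empty search band")
  in_note <- which(spect$frame_times_s >= note[1] &
                     spect$frame_times_s <= note[2])
  if (length(in_note) == 0)
    stop("no spectrogram frames inside the note interval")
  m <- spect$magnitude[in_note, bins, drop = FALSE]
  nf <- nrow(m)
  # fundamental candidate per frame: lowest local maximum within
  # rel_threshold_db of the frame's band maximum
  cand <- t(apply(m, 1, lowest_qualified_peak,
                  ratio = 10^(-rel_threshold_db / 20)))
  peak_bin <- integer(nf)
  seed_frame <- which.max(cand[, 2])
  peak_bin[seed_frame] <- cand[seed_frame, 1]
  if (seed_frame < nf)
    for (j in (seed_frame + 1):nf)
      peak_bin[j] <- constrained_peak(m[j, ], peak_bin[j - 1], max_jump_bins)
  if (seed_frame > 1)
    for (j in (seed_frame - 1):1)
      peak_bin[j] <- constrained_peak(m[j, ], peak_bin[j + 1], max_jump_bins)
  # parabolic refinement in full-spectrum bin coordinates
  khz <- numeric(nf)
  conf <- numeric(nf)
  dbin <- spect$bin_freqs_hz[2]
  for (j in seq_len(nf)) {
    b <- bins[peak_bin[j]]
    delta <- parabolic_offset(spect$magnitude[in_note[j], ], b)
    khz[j] <- (spect$bin_freqs_hz[b] + delta * dbin) / 1000
    conf[j] <- m[j, peak_bin[j]] / (stats::median(m[j, ]) + .Machine$double.eps)
  }
  duration <- note[2] - note[1]
  rel <- (spect$frame_times_s[in_note] - note[1]) / duration
  grid <- seq(0, 0.9, by = 0.1)
  out <- structure(
    list(positions = grid,
         khz = interp_extrap(rel, khz, grid),
         confidence = interp_extrap(rel, conf, grid),
         frames = data.frame(time_s = spect$frame_times_s[in_note],
                             khz = khz, confidence = conf),
         note = note),
    class = "fundamental_track")
  attr(out, "low_confidence") <- mean(conf < floor_factor) > 0.30
  out
}

# c(bin, magnitude) of the lowest-frequency local maximum within `ratio`
# of the row maximum; falls back to the global maximum
lowest_qualified_peak <- function(row, ratio) {
  thr <- max(row) * ratio
  n <- length(row)
  is_peak <- row >= thr &
    row >= c(-Inf, row[-n]) & row >= c(row[-1], -Inf)
  b <- which(is_peak)[1]
  if (is.na(b)) b <- which.max(row)
  c(b, row[b])
}

constrained_peak <- function(row, prev, max_jump) {
  lo <- max(1L, prev - max_jump)
  hi <- min(length(row), prev + max_jump)
  lo + which.max(row[lo:hi]) - 1L
}

# offset in bins (-0.5..0.5) of the parabola through the peak and neighbors
parabolic_offset <- function(row, b) {
  if (b <= 1 || b >= length(row)) return(0)
  a <- row[b - 1]; c0 <- row[b]; d <- row[b + 1]
  den <- a - 2 * c0 + d
  if (den == 0) return(0)
  off <- 0.5 * (a - d) / den
  max(-0.5, min(0.5, off))
}
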