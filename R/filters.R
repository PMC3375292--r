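#' Keep only well-separated first notes
#'
#' Retains notes with `note_index == 1` whose onset is at least
#' `min_gap_ms` after the previous note's offset within the same
#' recording (`file` column if present, otherwise individual x session).
#' Row order is preserved. Applying the filter twice equals applying it
#' once.
#'
#' @param notes feature or annotation data.frame with `note_index`,
#'   `start_s`, `end_s` columns.
#' @param min_gap_ms minimum silence before a retained note (ms).
#' @return the filtered data.frame.
#' @export
select_first_notes <- function(notes, min_gap_ms = 30) {
  if (nrow(notes) == 0) return(notes)
  need <- c("note_index", "start_s", "end_s")
  miss <- setdiff(need, names(notes))
  if (length(miss))
    stop("missing timing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(notes$start_s) || anyNA(notes$end_s))
    stop("missing note timing")
  rec <- if ("file" %in% names(notes)) notes$file
         else interaction(notes$individual, notes$session, drop = TRUE)
  keep <- logical(nrow(notes))
  for (r in unique(rec)) {
    idx <- which(rec == r)
    idx <- idx[order(notes$start_s[idx])]
    prev_end <- -Inf
    for (i in idx) {
      gap_ok <- (notes$start_s[i] - prev_end) * 1000 >= min_gap_ms
      keep[i] <- notes$note_index[i] == 1 && gap_ok
      prev_end <- max(prev_end, notes$end_s[i])
    }
  }
  out <- notes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop individuals with too few notes
#'
#' Removes all notes from any individual contributing fewer than
#' `threshold` notes; an individual with exactly `threshold` notes is
#' kept. The dropped individuals and their counts are attached as the
#' `dropped` attribute (a data.frame) and reported with a message.
#'
#' @param notes feature data.frame with an `individual` column.
#' @param threshold minimum notes per retained individual.
#' @param quiet suppress the message.
#' @return the filtered data.frame with a `dropped` attribute.
#' @export
min_notes_filter <- function(notes, threshold = 45, quiet = FALSE) {
  if (nrow(notes) == 0) {
    attr(notes, "dropped") <- data.frame(individual = character(),
                                         n_notes = integer())
    return(notes)
  }
  counts <- table(notes$individual)
  low <- names(counts)[counts < threshold]
  report <- data.frame(individual = low,
                       n_notes = as.integer(counts[low]),
                       row.names = NULL)
  if (!quiet && nrow(report))
    message("min_notes_filter: dropped ", nrow(report), " individual(s): ",
            paste(sprintf("%s (%d)", report$individual, report$n_notes),
                  collapse = ", "))
  out <- notes[!(notes$individual %in% low), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- report
  out
}

#' Build paired feature rows for double-note calls
#'
#' For every call with at least two notes, concatenates the measurement
#' vectors of the first and second note (suffixes `_n1`, `_n2`) and adds
#' the interval between them, yielding the variable set used when both
#' notes of a double-note call are analyzed together. Single-note calls
#' are excluded.
#'
#' @param notes feature data.frame with `call_id` and `note_index`
#'   columns and the [feature_names()] measurements; needs either an
#'   `inter_note_interval_ms` column or `start_s`/`end_s` to compute the
#'   interval.
#' @return data.frame: one row per multi-note call with 72 measurement
#'   columns, `inter_note_interval_ms`, and the call's label columns.
#' @export
select_double_notes <- function(notes) {
  fn <- feature_names()
  label_cols <- setdiff(names(notes), c(fn, "note_index"))
  out <- list()
  for (id in unique(notes$call_id)) {
    sub <- notes[notes$call_id == id, , drop = FALSE]
    sub <- sub[order(sub$note_index), , drop = FALSE]
    if (nrow(sub) < 2) next
    n1 <- sub[1, fn]; n2 <- sub[2, fn]
    names(n1) <- paste0(fn, "_n1"); names(n2) <- paste0(fn, "_n2")
    interval <- if ("inter_note_interval_ms" %in% names(sub) &&
                    !is.na(sub$inter_note_interval_ms[1]))
      sub$inter_note_interval_ms[1]
    else (sub$start_s[2] - sub$end_s[1]) * 1000
    out[[id]] <- cbind(n1, n2,
                       data.frame(inter_note_interval_ms = interval),
                       sub[1, setdiff(label_cols, "inter_note_interval_ms"),
                           drop = FALSE])
  }
  if (!length(out)) {
    res <- notes[0, c(fn, label_cols), drop = FALSE]
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
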