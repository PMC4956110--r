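#' Note error rate (Levenshtein)
#'
#' The note error rate is the total Levenshtein distance between the true and
#' output note-label sequences divided by the total number of notes in the
#' true sequences — the analogue of word error rate in speech recognition.
#' Rates are pooled: distances and lengths are summed over all paired
#' sequences before dividing.
#'
#' @param true_seqs,out_seqs Paired collections of label sequences. Each
#'   sequence may be a character vector of labels or a `song_annotation`
#'   (whose label sequence is used). A single sequence is also accepted.
#' @return The pooled note error rate, a fraction in `[0, Inf)` (it can exceed
#'   1 when outputs contain many insertions).
#' @examples
#' note_error_rate(list(c("A","B","A","B"), c("A","A","B")),
#'                 list(c("A","B","B"),     c("A","A","B")))  # 1/7
#' @export
note_error_rate <- function(true_seqs, out_seqs) {
  true_seqs <- as_label_seqs(true_seqs)
  out_seqs <- as_label_seqs(out_seqs)
  if (length(true_seqs) != length(out_seqs))
    stop("length-mismatch: collections must be paired")
  alphabet <- unique(c(unlist(true_seqs), unlist(out_seqs)))
  enc <- function(s) intToUtf8(match(s, alphabet) + 256L)
  dist <- sum(mapply(function(a, b) utils::adist(enc(a), enc(b)),
                     true_seqs, out_seqs))
  total <- sum(lengths(true_seqs))
  if (total == 0) stop("length-mismatch: no true notes")
  dist / total
}

as_label_seqs <- function(x) {
  if (inherits(x, "song_annotation")) return(list(annotation_labels(x)))
  if (is.character(x)) return(list(x))
  lapply(x, function(s)
    if (inherits(s, "song_annotation")) annotation_labels(s) else as.character(s))
}

as_annotation_list <- function(x) {
  if (inherits(x, "song_annotation")) list(x) else x
}

#' Match correctly recognized intervals between truth and prediction
#'
#' For each true note, the output note with the same class (unless
#' `ignore_classes`) and the longest overlap is matched, each output note
#' matching at most one true note; conflicts are resolved greedily in
#' descending overlap order. The overlaps of matched pairs are the correctly
#' recognized note intervals; true-silence frames in which the prediction
#' assigns no class are the correctly recognized silent intervals.
#'
#' @param truth,pred `song_annotation` objects on the same timeline.
#' @param ignore_classes Collapse all note classes to one before matching.
#' @param optimal Use exhaustive optimal assignment instead of the greedy
#'   rule (only feasible for small annotations; used to audit the greedy
#'   matching).
#' @return A list of class `match_result` with elements `pairs` (data frame
#'   of matched true/pred indices and overlaps), `note_frames`,
#'   `silent_frames` and `timeline`.
#' @export
match_correct_intervals <- function(truth, pred, ignore_classes = FALSE,
                                    optimal = FALSE) {
  if (annotation_timeline(truth) != annotation_timeline(pred))
    stop("incompatible-annotations: timeline mismatch")
  cls <- unique(c(truth$label, pred$label))
  if (optimal) return(match_intervals_optimal(truth, pred, ignore_classes))
  m <- cpp_match_intervals(truth$onset, truth$offset,
                           match(truth$label, cls),
                           pred$onset, pred$offset, match(pred$label, cls),
                           annotation_timeline(truth), ignore_classes)
  structure(list(pairs = data.frame(true_idx = m$true_idx,
                                    pred_idx = m$pred_idx,
                                    overlap = m$overlap),
                 note_frames = m$note_frames,
                 silent_frames = m$silent_frames,
                 timeline = annotation_timeline(truth)),
            class = "match_result")
}

## Exhaustive maximum-total-overlap one-to-one matching (audit tool).
match_intervals_optimal <- function(truth, pred, ignore_classes) {
  ov_len <- function(i, j)
    max(0L, min(truth$offset[i], pred$offset[j]) -
          max(truth$onset[i], pred$onset[j]))
  cand <- list()
  for (i in seq_len(nrow(truth))) for (j in seq_len(nrow(pred))) {
    if (!ignore_classes && truth$label[i] != pred$label[j]) next
    ov <- ov_len(i, j)
    if (ov > 0L) cand[[length(cand) + 1L]] <- c(i, j, ov)
  }
  best <- list(total = 0, sel = integer(0))
  n <- length(cand)
  if (n > 24L) stop("optimal matching only supported for small annotations")
  recurse <- function(k, t_used, p_used, total, sel) {
    if (k > n) {
      if (total > best$total) best <<- list(total = total, sel = sel)
      return()
    }
    recurse(k + 1L, t_used, p_used, total, sel)
    ci <- cand[[k]]
    if (!(ci[1] %in% t_used) && !(ci[2] %in% p_used))
      recurse(k + 1L, c(t_used, ci[1]), c(p_used, ci[2]),
              total + ci[3], c(sel, k))
  }
  recurse(1L, integer(0), integer(0), 0, integer(0))
  sel <- best$sel
  pairs <- if (length(sel))
    data.frame(true_idx = vapply(cand[sel], `[`, 0, 1),
               pred_idx = vapply(cand[sel], `[`, 0, 2),
               overlap = vapply(cand[sel], `[`, 0, 3))
  else data.frame(true_idx = integer(), pred_idx = integer(),
                  overlap = integer())
  covered <- union(unlist(mapply(seq2, truth$onset, truth$offset,
                                 SIMPLIFY = FALSE)),
                   unlist(mapply(seq2, pred$onset, pred$offset,
                                 SIMPLIFY = FALSE)))
  structure(list(pairs = pairs, note_frames = best$total,
                 silent_frames = annotation_timeline(truth) - length(covered),
                 timeline = annotation_timeline(truth)),
            class = "match_result")
}

seq2 <- function(a, b) if (b > a) seq.int(a, b - 1L) else integer(0)

#' Joint classification/timing error rates
#'
#' The note & timing error rate is one minus the fraction of the timeline
#' covered by correctly recognized intervals: overlaps of class-respecting
#' matched note pairs plus true-silence frames left unlabelled by the
#' prediction. The timing error rate is the same quantity with all note
#' classes collapsed to one, measuring pure boundary accuracy. Collections
#' are pooled by summing correct lengths and timelines before dividing.
#'
#' @param truth,pred A `song_annotation` or paired lists of them.
#' @return A fraction in `[0, 1]`.
#' @examples
#' tr <- song_annotation(10, 50, "A", 100)
#' pr <- song_annotation(c(10, 32), c(30, 50), c("A", "A"), 100)
#' note_timing_error_rate(tr, pr)  # 0.20
#' @export
note_timing_error_rate <- function(truth, pred) {
  pooled_interval_error(truth, pred, ignore_classes = FALSE)
}

#' @rdname note_timing_error_rate
#' @export
timing_error_rate <- function(truth, pred) {
  pooled_interval_error(truth, pred, ignore_classes = TRUE)
}

pooled_interval_error <- function(truth, pred, ignore_classes) {
  truth <- as_annotation_list(truth); pred <- as_annotation_list(pred)
  if (length(truth) != length(pred))
    stop("length-mismatch: collections must be paired")
  correct <- 0; total <- 0
  for (k in seq_along(truth)) {
    m <- match_correct_intervals(truth[[k]], pred[[k]],
                                 ignore_classes = ignore_classes)
    correct <- correct + m$note_frames + m$silent_frames
    total <- total + m$timeline
  }
  1 - correct / total
}

interval_midpoints <- function(ann) (ann$onset + ann$offset) / 2

## Nearest output note (by midpoint distance) for every true note.
## Returns a list with the index of the nearest output note (NA if pred is
## empty) and whether the nearest note was ambiguous (two notes exactly
## equidistant).
nearest_output_notes <- function(truth, pred) {
  mt <- interval_midpoints(truth); mp <- interval_midpoints(pred)
  idx <- rep(NA_integer_, length(mt)); amb <- rep(FALSE, length(mt))
  for (i in seq_along(mt)) {
    if (!length(mp)) next
    d <- abs(mp - mt[i])
    j <- which.min(d)
    idx[i] <- j
    amb[i] <- sum(d == d[j]) > 1L
  }
  list(idx = idx, ambiguous = amb)
}

#' Identification error rate
#'
#' A true note counts as incorrectly recognized when the nearest output note
#' (by interval-midpoint distance) carries a different class, when two output
#' notes are exactly equidistant, or when there is no output note at all. The
#' rate is the fraction of incorrect true notes, pooled over sequences.
#'
#' @inheritParams note_timing_error_rate
#' @return A fraction in `[0, 1]`.
#' @export
identification_error_rate <- function(truth, pred) {
  truth <- as_annotation_list(truth); pred <- as_annotation_list(pred)
  if (length(truth) != length(pred))
    stop("length-mismatch: collections must be paired")
  bad <- 0; total <- 0
  for (k in seq_along(truth)) {
    tr <- truth[[k]]; pr <- pred[[k]]
    nn <- nearest_output_notes(tr, pr)
    wrong <- is.na(nn$idx) | nn$ambiguous |
      (!is.na(nn$idx) & pr$label[replace(nn$idx, is.na(nn$idx), 1L)] != tr$label)
    bad <- bad + sum(wrong)
    total <- total + nrow(tr)
  }
  if (total == 0) stop("length-mismatch: no true notes")
  bad / total
}

#' Duration error rates of notes and silent gaps
#'
#' Notes: over the correctly identified true notes (complement of the
#' incorrect notes of [identification_error_rate()]), the summed absolute
#' duration difference to their nearest output notes, divided by the summed
#' duration of those true notes. Gaps: true and output inter-note silent gaps
#' are paired as mutual nearest neighbours by midpoint; the summed absolute
#' duration differences (unpaired true gaps contribute their full duration)
#' are divided by the total true gap duration.
#'
#' @inheritParams note_timing_error_rate
#' @return Named numeric vector `c(notes = ..., gaps = ...)`; a term is `NA`
#'   (with a warning for notes) when its denominator is empty.
#' @export
duration_error_rates <- function(truth, pred) {
  truth <- as_annotation_list(truth); pred <- as_annotation_list(pred)
  if (length(truth) != length(pred))
    stop("length-mismatch: collections must be paired")
  note_num <- 0; note_den <- 0
  gap_num <- 0; gap_den <- 0
  for (k in seq_along(truth)) {
    tr <- truth[[k]]; pr <- pred[[k]]
    nn <- nearest_output_notes(tr, pr)
    ok <- !is.na(nn$idx) & !nn$ambiguous &
      pr$label[replace(nn$idx, is.na(nn$idx), 1L)] == tr$label
    if (any(ok)) {
      dt <- note_durations(tr)[ok]
      dp <- note_durations(pr)[nn$idx[ok]]
      note_num <- note_num + sum(abs(dt - dp))
      note_den <- note_den + sum(dt)
    }
    tg <- annotation_gaps(tr); pg <- annotation_gaps(pr)
    if (nrow(tg)) {
      gap_den <- gap_den + sum(tg$offset - tg$onset)
      if (nrow(pg)) {
        mt <- (tg$onset + tg$offset) / 2; mp <- (pg$onset + pg$offset) / 2
        t2p <- vapply(mt, function(m) which.min(abs(mp - m)), 0L)
        p2t <- vapply(mp, function(m) which.min(abs(mt - m)), 0L)
        mutual <- which(p2t[t2p] == seq_along(mt))
        dt <- tg$offset - tg$onset; dp <- pg$offset - pg$onset
        gap_num <- gap_num + sum(abs(dt[mutual] - dp[t2p[mutual]])) +
          sum(dt[setdiff(seq_along(mt), mutual)])
      } else {
        gap_num <- gap_num + sum(tg$offset - tg$onset)
      }
    }
  }
  notes <- if (note_den > 0) note_num / note_den else {
    warning("no correctly identified notes; note duration ER undefined")
    NA_real_
  }
  gaps <- if (gap_den > 0) gap_num / gap_den else NA_real_
  c(notes = notes, gaps = gaps)
}

#' Full error report for truth/prediction annotation pairs
#'
#' Computes all six evaluation measures: note ER, timing ER, note & timing
#' ER, identification ER, and the duration ERs of notes and silent gaps.
#'
#' @inheritParams note_timing_error_rate
#' @return An `error_report` object (named list of the six rates).
#' @export
error_report <- function(truth, pred) {
  structure(list(
    note_er = note_error_rate(truth, pred),
    timing_er = timing_error_rate(truth, pred),
    note_timing_er = note_timing_error_rate(truth, pred),
    identification_er = identification_error_rate(truth, pred),
    duration_er = duration_error_rates(truth, pred)
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report>\n")
  cat(sprintf("  note ER          : %6.2f%%\n", 100 * x$note_er))
  cat(sprintf("  timing ER        : %6.2f%%\n", 100 * x$timing_er))
  cat(sprintf("  note & timing ER : %6.2f%%\n", 100 * x$note_timing_er))
  cat(sprintf("  identification ER: %6.2f%%\n", 100 * x$identification_er))
  cat(sprintf("  duration ER notes: %6.2f%%   gaps: %6.2f%%\n",
              100 * x$duration_er[["notes"]], 100 * x$duration_er[["gaps"]]))
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, ...) {
  data.frame(note_er = x$note_er, timing_er = x$timing_er,
             note_timing_er = x$note_timing_er,
             identification_er = x$identification_er,
             duration_er_notes = x$duration_er[["notes"]],
             duration_er_gaps = x$duration_er[["gaps"]])
}
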