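#' Detect note intervals by amplitude, gap, and duration thresholding
#'
#' Three passes in fixed order: (1) frames with envelope strictly above
#' `amp_thr` form non-background intervals; (2) silent gaps strictly shorter
#' than `gap_thr` frames between them are concatenated; (3) intervals
#' strictly shorter than `dur_thr` frames are discarded. With `gap_thr = 0`
#' the merge pass is a no-op.
#'
#' @param env An `amplitude_envelope` (or numeric vector), one value per
#'   1-ms frame.
#' @param thr A `threshold_set` from [threshold_set()] or [fit_thresholds()].
#' @return An integer matrix with columns `onset`, `offset` (half-open,
#'   0-based frames), class `interval_list`.
#' @examples
#' env <- c(0, 5, 5, 0, 5, 5, 5, 0, 0, 2)
#' detect_note_intervals(env, threshold_set(1, 0, 2))  # [1,3) and [4,7)
#' @export
detect_note_intervals <- function(env, thr) {
  stopifnot(length(env) > 0)
  iv <- runs_above(as.numeric(env) > thr$amp_thr)
  iv <- merge_gaps(iv, thr$gap_thr)
  iv <- iv[iv[, 2L] - iv[, 1L] >= thr$dur_thr, , drop = FALSE]
  structure(iv, class = c("interval_list", class(iv)))
}

runs_above <- function(above) {
  r <- rle(above)
  off <- cumsum(r$lengths)
  on <- off - r$lengths
  cbind(onset = on[r$values], offset = off[r$values])
}

merge_gaps <- function(iv, gap_thr) {
  if (nrow(iv) < 2L || gap_thr <= 0) return(iv)
  keep_gap <- iv[-1L, 1L] - iv[-nrow(iv), 2L] >= gap_thr  # gaps that survive
  grp <- cumsum(c(TRUE, keep_gap))
  cbind(onset = as.vector(tapply(iv[, 1L], grp, min)),
        offset = as.vector(tapply(iv[, 2L], grp, max)))
}

#' Thresholds for boundary detection
#'
#' @param amp_thr Amplitude threshold in envelope units (summed log
#'   magnitude); frames strictly above it are non-background.
#' @param gap_thr Gap threshold in ms; silent gaps strictly shorter are
#'   merged.
#' @param dur_thr Duration threshold in ms; intervals strictly shorter are
#'   discarded.
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(amp_thr, gap_thr = 0, dur_thr = 0) {
  stopifnot(gap_thr >= 0, dur_thr >= 0)
  structure(list(amp_thr = amp_thr, gap_thr = gap_thr, dur_thr = dur_thr),
            class = "threshold_set")
}

#' Fit boundary-detection thresholds on training data
#'
#' Exhaustive grid search for the threshold triple minimizing the pooled
#' timing error rate of the detected intervals against the training
#' annotations. The grid covers 64 quantiles of the pooled envelope values
#' for the amplitude threshold, 0-30 ms for the gap threshold and 0-50 ms in
#' 5 ms steps for the duration threshold; ties are broken toward the smaller
#' amplitude, then gap, then duration threshold. The objective is evaluated
#' with the same interval-matching implementation as
#' [timing_error_rate()].
#'
#' @param training List of `list(envelope =, annotation =)` pairs; the
#'   annotations must live on the envelope frame grid.
#' @param gap_grid,dur_grid Optional replacement grids (ms).
#' @return The winning `threshold_set`, with the achieved training timing ER
#'   attached as attribute `timing_er`.
#' @export
fit_thresholds <- function(training, gap_grid = 0:30,
                           dur_grid = seq(0L, 50L, by = 5L)) {
  if (!length(training)) stop("no-training-data: empty training set")
  envs <- lapply(training, `[[`, "envelope")
  anns <- lapply(training, `[[`, "annotation")
  for (k in seq_along(training))
    if (length(envs[[k]]) != annotation_timeline(anns[[k]]))
      stop("incompatible-annotations: annotation not on the envelope grid")
  amp_grid <- unique(stats::quantile(unlist(envs), probs = (1:64) / 65,
                                     names = FALSE, type = 7))
  timelines <- vapply(anns, annotation_timeline, 0L)
  total_frames <- sum(timelines)

  gap_grid <- as.integer(gap_grid); dur_grid <- as.integer(dur_grid)
  best <- list(er = Inf, amp = NA, gap = NA, dur = NA)
  for (amp in amp_grid) {
    correct <- 0
    for (k in seq_along(envs)) {
      iv <- runs_above(as.numeric(envs[[k]]) > amp)
      correct <- correct + cpp_threshold_grid(iv[, 1L], iv[, 2L],
                                              anns[[k]]$onset,
                                              anns[[k]]$offset,
                                              timelines[k], gap_grid,
                                              dur_grid)
    }
    er <- 1 - correct / total_frames
    mi <- which(er < best$er - 1e-12, arr.ind = TRUE)
    if (nrow(mi)) {
      ## grids ascend, so the first minimum among the improvements realises
      ## the smaller-gap-then-smaller-duration tie-break
      mi <- mi[order(mi[, 1L], mi[, 2L]), , drop = FALSE]
      top <- mi[which.min(er[mi]), ]
      best <- list(er = er[top[1L], top[2L]], amp = amp,
                   gap = gap_grid[top[1L]], dur = dur_grid[top[2L]])
    }
  }
  structure(threshold_set(best$amp, best$gap, best$dur),
            timing_er = best$er)
}

#' Convert detected intervals to an annotation
#'
#' Detected intervals carry no class, so a reserved placeholder label is
#' used. Intervals are reported on the same grid they were detected on.
#'
#' @param iv An `interval_list`.
#' @param timeline Timeline length in frames.
#' @param label Reserved label for unclassified intervals.
#' @return A `song_annotation`.
#' @export
intervals_to_annotation <- function(iv, timeline, label = ".detected") {
  song_annotation(iv[, 1L], iv[, 2L], rep(label, nrow(iv)),
                  timeline = timeline)
}
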