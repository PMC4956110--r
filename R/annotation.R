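#' Note annotation for a single sound sequence
#'
#' An annotation is an ordered list of non-overlapping note intervals on the
#' 1-ms frame grid, each carrying a note-class label, together with the total
#' timeline length of the sequence. All intervals are half-open
#' `[onset, offset)` with 0-based frame indices, so a note of duration `d`
#' frames occupies `onset, onset+1, ..., onset+d-1`.
#'
#' @param onset,offset Integer vectors of note onsets and offsets (frames,
#'   0-based, half-open). Must be sorted and non-overlapping.
#' @param label Character (or factor) vector of note-class labels, one per note.
#' @param timeline Total sequence length in frames; all offsets must be
#'   `<= timeline`.
#' @return An object of class `song_annotation`: a data frame with columns
#'   `onset`, `offset`, `label` and attribute `timeline`.
#' @examples
#' ann <- song_annotation(c(10, 60), c(40, 90), c("a", "b"), timeline = 120)
#' ann
#' @export
song_annotation <- function(onset = integer(), offset = integer(),
                            label = character(), timeline) {
  onset <- as.integer(round(onset))
  offset <- as.integer(round(offset))
  label <- as.character(label)
  if (length(onset) != length(offset) || length(onset) != length(label))
    stop("onset, offset and label must have the same length")
  if (any(offset <= onset))
    stop("invalid-annotation: every note must satisfy onset < offset")
  if (length(onset) > 1L) {
    o <- order(onset)
    onset <- onset[o]; offset <- offset[o]; label <- label[o]
    if (any(onset[-1L] < offset[-length(offset)]))
      stop("invalid-annotation: notes overlap")
  }
  timeline <- as.integer(round(timeline))
  if (length(onset) && (any(onset < 0L) || any(offset > timeline)))
    stop("invalid-annotation: notes outside [0, timeline)")
  structure(
    data.frame(onset = onset, offset = offset, label = label,
               stringsAsFactors = FALSE),
    timeline = timeline,
    class = c("song_annotation", "data.frame")
  )
}

#' @export
print.song_annotation <- function(x, ...) {
  cat(sprintf("<song_annotation> %d notes, timeline %d frames\n",
              nrow(x), annotation_timeline(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more notes\n", nrow(x) - 10L))
  invisible(x)
}

#' Timeline length of an annotation
#' @param ann A `song_annotation`.
#' @return Length of the annotated sequence in frames.
#' @export
annotation_timeline <- function(ann) attr(ann, "timeline")

#' Label sequence of an annotation
#' @param ann A `song_annotation`.
#' @return Character vector of note labels in temporal order.
#' @export
annotation_labels <- function(ann) ann$label

note_durations <- function(ann) ann$offset - ann$onset

## Silent gaps strictly between consecutive notes (leading/trailing silence is
## unbounded and not a gap).
annotation_gaps <- function(ann) {
  if (nrow(ann) < 2L) return(data.frame(onset = integer(), offset = integer()))
  on <- ann$offset[-nrow(ann)]
  off <- ann$onset[-1L]
  keep <- off > on
  data.frame(onset = on[keep], offset = off[keep])
}

## Shift between annotation time (ms) and spectrogram frame index: a
## spectrogram frame starts at its anchor sample but describes its centre,
## fft_size/(2*hop) frames later.
frame_centre_shift <- function(params = spectrogram_params()) {
  as.integer(params$fft_size / (2L * params$hop))
}

#' Convert an annotation from the millisecond grid to the spectrogram frame grid
#'
#' Spectrogram frame `t` is anchored at sample `t * hop` but describes the
#' window centred `fft_size/2` samples later, so annotations given in
#' milliseconds are shifted back by `fft_size/(2*hop)` frames (8 at defaults)
#' when used as frame labels, and shifted forward again when decoded frame
#' runs are reported as annotations.
#'
#' @param ann A `song_annotation` on the millisecond grid.
#' @param n_frames Number of spectrogram frames of the sequence.
#' @param params [spectrogram_params()] in force.
#' @return A `song_annotation` on the frame grid (timeline `n_frames`).
#' @seealso [frame_grid_to_annotation()]
#' @export
annotation_to_frame_grid <- function(ann, n_frames,
                                     params = spectrogram_params()) {
  s <- frame_centre_shift(params)
  on <- pmax(ann$onset - s, 0L)
  off <- pmin(ann$offset - s, n_frames)
  keep <- off > on
  song_annotation(on[keep], off[keep], ann$label[keep], timeline = n_frames)
}

#' @rdname annotation_to_frame_grid
#' @param timeline Timeline length (ms) of the reported annotation.
#' @export
frame_grid_to_annotation <- function(ann, timeline,
                                     params = spectrogram_params()) {
  s <- frame_centre_shift(params)
  on <- pmin(pmax(ann$onset + s, 0L), timeline)
  off <- pmin(ann$offset + s, timeline)
  keep <- off > on
  song_annotation(on[keep], off[keep], ann$label[keep], timeline = timeline)
}

#' Read and write tab-separated label files
#'
#' Annotations are exchanged as tab-separated label tracks with one line per
#' note: onset (s), offset (s), label. This is the dialect Audacity and most
#' annotation tools read and write. On disk times are seconds; in memory they
#' are 1-ms frames.
#'
#' @param path File path.
#' @param timeline_s Timeline length in seconds (required on read; the label
#'   file itself does not record it). Defaults to the last offset.
#' @return `read_labels` returns a `song_annotation`; `write_labels` returns
#'   `path` invisibly.
#' @export
read_labels <- function(path, timeline_s = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("onset", "offset", "label"),
                           colClasses = c("numeric", "numeric", "character"))
  if (is.null(timeline_s)) timeline_s <- if (nrow(tab)) max(tab$offset) else 0
  song_annotation(round(tab$onset * 1000), round(tab$offset * 1000),
                  tab$label, timeline = round(timeline_s * 1000))
}

#' @rdname read_labels
#' @param ann A `song_annotation` (1-ms frame grid).
#' @export
write_labels <- function(ann, path) {
  tab <- data.frame(onset = sprintf("%.6f", ann$onset / 1000),
                    offset = sprintf("%.6f", ann$offset / 1000),
                    label = ann$label)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
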