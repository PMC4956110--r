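#' Specification of a synthetic note class
#'
#' Each note class is rendered as a harmonic stack: a fundamental with
#' `harmonics` partials (amplitudes decaying as 1/k), optional linear
#' frequency modulation, and a raised-cosine onset/offset ramp. The
#' fundamental and all partials must stay inside the 1-8 kHz analysis band
#' so that every class is visible to the spectrogram front end.
#'
#' @param label Class label.
#' @param fundamental Fundamental frequency in Hz.
#' @param harmonics Number of partials (including the fundamental).
#' @param fm_slope Linear frequency-modulation slope in Hz/ms.
#' @param dur_range Duration range in ms, `c(min, max)`.
#' @param amplitude Relative peak amplitude.
#' @param breath_db Level (dB relative to `amplitude`) of the broadband
#'   aspiration component mixed into the note. Vocal sounds are never pure
#'   tones; this wideband footprint is what amplitude envelopes respond to.
#' @return A `note_class_spec` list.
#' @export
note_class_spec <- function(label, fundamental, harmonics = 2L,
                            fm_slope = 0, dur_range = c(60, 140),
                            amplitude = 1, breath_db = -20) {
  top <- (fundamental + abs(fm_slope) * dur_range[2L]) * harmonics
  if (fundamental <= 1000 || top >= 8000)
    stop("invalid-config: partials of class ", label,
         " leave the (1, 8) kHz band")
  structure(list(label = as.character(label), fundamental = fundamental,
                 harmonics = as.integer(harmonics), fm_slope = fm_slope,
                 dur_range = dur_range, amplitude = amplitude,
                 breath_db = breath_db),
            class = "note_class_spec")
}

#' Default synthetic note classes
#'
#' Note classes with fundamentals spread over 1.1-2.6 kHz, two or three
#' partials, and alternating up/down frequency modulation, emulating the
#' spectral diversity of song notes. Durations span 40-180 ms across
#' classes, inside the 30-200 ms range typical of song notes.
#'
#' @param n Number of classes (2-12).
#' @return List of [note_class_spec()] objects labelled `"a"`, `"b"`, ...
#' @export
default_note_classes <- function(n = 8L) {
  stopifnot(n >= 2L, n <= 12L)
  f0 <- seq(1150, 2600, length.out = n)
  harm <- rep(c(2L, 3L, 2L), length.out = n)
  slope <- rep(c(0, 2, -2, 1), length.out = n)
  dmin <- round(seq(40, 120, length.out = n))
  dmax <- dmin + round(seq(40, 60, length.out = n))
  lapply(seq_len(n), function(i) {
    ## keep every partial inside the analysis band
    top <- f0[i] + abs(slope[i]) * dmax[i]
    note_class_spec(letters[i], f0[i], max(1L, min(harm[i],
                                                   floor(7900 / top))),
                    slope[i], c(dmin[i], dmax[i]))
  })
}

#' Generator configuration for synthetic song datasets
#'
#' The generator emulates the structure the annotator is built for: songs
#' are bouts of 8-15 notes drawn from a second-order Markov syntax, rendered
#' as harmonic stacks separated by silent gaps and embedded in stationary
#' Gaussian noise. The gap distribution is a mixture: with probability
#' `p_zero_gap` a near-zero gap (0-2 ms, the regime where amplitude
#' thresholding cannot see a boundary), otherwise uniform on `gap_range_ms`.
#'
#' @param classes List of [note_class_spec()]s (`n >= 2`).
#' @param syntax A `syntax_model` over the same labels; default: a random
#'   sparse second-order syntax drawn from the seed.
#' @param gap_range_ms Range of ordinary inter-note gaps (ms).
#' @param p_zero_gap Probability of a near-zero (0-2 ms) gap.
#' @param noise_snr_db Signal-to-noise ratio in dB (note RMS vs noise RMS).
#' @param total_minutes Approximate total audio duration to generate.
#' @param notes_per_song Range of notes per song bout.
#' @param pad_ms Range of leading/trailing silence per bout (ms).
#' @param sample_rate Audio sample rate (Hz).
#' @param seed Master seed; the dataset is a deterministic function of the
#'   configuration.
#' @return A `generator_config` list.
#' @export
generator_config <- function(classes = default_note_classes(8L),
                             syntax = NULL, gap_range_ms = c(5, 120),
                             p_zero_gap = 0.05, noise_snr_db = 30,
                             total_minutes = 3, notes_per_song = c(8L, 15L),
                             pad_ms = c(60, 150), sample_rate = 32000,
                             seed = 1L) {
  labels <- vapply(classes, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("invalid-config: duplicate class labels")
  if (is.null(syntax)) syntax <- random_syntax(labels, seed)
  if (!setequal(syntax$classes, labels))
    stop("invalid-config: syntax alphabet differs from the class labels")
  structure(list(classes = classes, labels = labels, syntax = syntax,
                 gap_range_ms = gap_range_ms, p_zero_gap = p_zero_gap,
                 noise_snr_db = noise_snr_db, total_minutes = total_minutes,
                 notes_per_song = notes_per_song, pad_ms = pad_ms,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "generator_config")
}

## A reproducible, clearly non-uniform second-order syntax: Dirichlet-ish
## rows obtained from scaled exponentials, sharpened so some transitions
## dominate.
random_syntax <- function(labels, seed) {
  n <- length(labels)
  trans <- with_seed(seed * 7L + 3L, {
    a <- array(stats::rexp(n^3)^2, dim = c(n, n, n))
    a
  })
  for (x in seq_len(n)) for (y in seq_len(n))
    trans[x, y, ] <- trans[x, y, ] / sum(trans[x, y, ])
  dimnames(trans) <- list(labels, labels, labels)
  structure(list(classes = labels, alpha = 0, trans = trans, counts = NULL),
            class = "syntax_model")
}

render_note <- function(spec, dur_ms, sample_rate) {
  ns <- round(dur_ms * sample_rate / 1000)
  t <- (seq_len(ns) - 1L) / sample_rate
  f <- spec$fundamental + spec$fm_slope * 1000 * t  # slope per ms
  phase <- 2 * pi * cumsum(f) / sample_rate
  x <- numeric(ns)
  for (k in seq_len(spec$harmonics)) x <- x + sin(k * phase) / k
  x <- x + 10^(spec$breath_db / 20) * stats::rnorm(ns)
  ramp_n <- min(round(0.003 * sample_rate), floor(ns / 2))
  env <- rep(1, ns)
  if (ramp_n > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- r
    env[ns + 1L - seq_len(ramp_n)] <- r  # mirrored: fades back to zero
  }
  spec$amplitude * x * env
}

#' Generate a synthetic song dataset
#'
#' Produces a list of song bouts, each a waveform plus an exact annotation
#' on the 1-ms grid. Note sequences are sampled from the configured
#' second-order syntax; notes are rendered as harmonic stacks with
#' class-specific durations and frequency modulation, separated by sampled
#' gaps, padded with silence, and embedded in Gaussian background noise at
#' the configured SNR. Deterministic for a given configuration (seed
#' included).
#'
#' @param cfg A [generator_config()].
#' @return A `song_dataset`: list of `list(wave, annotation, labels)` with
#'   the configuration attached as an attribute.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  sr <- cfg$sample_rate
  max_note_ms <- max(vapply(cfg$classes, function(cl) cl$dur_range[2L], 0))
  bout_budget_ms <- cfg$notes_per_song[2L] *
    (max_note_ms + cfg$gap_range_ms[2L]) + 2 * cfg$pad_ms[2L]
  if (bout_budget_ms > cfg$total_minutes * 60000)
    stop("invalid-config: a single bout can exceed the total duration budget")
  with_seed(cfg$seed, {
    specs <- cfg$classes
    names(specs) <- cfg$labels
    ## note RMS (concatenated class exemplars) fixes the noise level
    probe <- unlist(lapply(specs, function(s)
      render_note(s, mean(s$dur_range), sr)))
    sigma <- sqrt(mean(probe^2)) / 10^(cfg$noise_snr_db / 20)
    total_ms <- 0
    out <- list()
    while (total_ms < cfg$total_minutes * 60000) {
      len <- sample(cfg$notes_per_song[1L]:cfg$notes_per_song[2L], 1L)
      labs <- simulate(cfg$syntax, nsim = 1L, lengths = len,
                       sample_lengths = FALSE)[[1L]]
      durs <- vapply(labs, function(l) {
        dr <- specs[[l]]$dur_range
        sample(dr[1L]:dr[2L], 1L)
      }, 0L)
      gaps <- ifelse(stats::runif(len - 1L) < cfg$p_zero_gap,
                     sample(0:2, len - 1L, replace = TRUE),
                     sample(cfg$gap_range_ms[1L]:cfg$gap_range_ms[2L],
                            len - 1L, replace = TRUE))
      lead <- sample(cfg$pad_ms[1L]:cfg$pad_ms[2L], 1L)
      tail_ <- sample(cfg$pad_ms[1L]:cfg$pad_ms[2L], 1L)
      onsets <- lead + c(0, cumsum(durs[-len] + gaps))
      offsets <- onsets + durs
      timeline <- offsets[len] + tail_
      wave <- stats::rnorm(timeline * sr / 1000, sd = sigma)
      for (i in seq_len(len)) {
        note <- render_note(specs[[labs[i]]], durs[i], sr)
        a <- onsets[i] * sr / 1000
        wave[(a + 1L):(a + length(note))] <-
          wave[(a + 1L):(a + length(note))] + note
      }
      ann <- song_annotation(onsets, offsets, labs, timeline = timeline)
      out[[length(out) + 1L]] <- list(wave = wave, annotation = ann)
      total_ms <- total_ms + timeline
    }
    structure(out, config = cfg, class = "song_dataset")
  })
}

#' @export
print.song_dataset <- function(x, ...) {
  mins <- sum(vapply(x, function(s) annotation_timeline(s$annotation), 0L)) / 60000
  notes <- sum(vapply(x, function(s) nrow(s$annotation), 0L))
  cat(sprintf("<song_dataset> %d bouts, %.1f min, %d notes, %d classes\n",
              length(x), mins, notes, length(attr(x, "config")$labels)))
  invisible(x)
}

#' Extract song sequences from a continuous annotation
#'
#' Implements the song extraction and segmentation rules used to turn raw
#' annotations (which may contain non-singing calls and unclassifiable
#' notes) into note sequences: (1) classes making up less than 1% of all
#' notes are relabelled unclassifiable; (2) maximal runs separated by calls
#' or by silent gaps of at least 300 ms, with more than seven notes, become
#' songs; (3) songs are split at (and cleansed of) unclassifiable notes;
#' (4) fragments with fewer than three notes are discarded; (5) fragments
#' with more than 15 notes are split greedily into chunks of at most 15.
#'
#' @param ann A `song_annotation` possibly containing reserved labels.
#' @param call_label,unclassifiable_label Reserved labels.
#' @param max_gap_ms Gap threshold separating songs.
#' @param min_song_notes Minimum run length for a song (strict `>`, i.e. 8
#'   with the default 7).
#' @param min_fragment_notes Minimum fragment length kept after splitting.
#' @param max_notes Maximum notes per returned sequence.
#' @return List of `song_annotation` fragments (original timeline retained).
#' @export
extract_songs <- function(ann, call_label = ".call",
                          unclassifiable_label = ".unk",
                          max_gap_ms = 300, min_song_notes = 7L,
                          min_fragment_notes = 3L, max_notes = 15L) {
  if (!nrow(ann)) return(list())
  lab <- ann$label
  ## (1) rare classes -> unclassifiable
  is_note <- lab != call_label
  tot <- sum(is_note)
  if (tot > 0) {
    cnt <- table(lab[is_note & lab != unclassifiable_label])
    rare <- names(cnt)[cnt < 0.01 * tot]
    lab[lab %in% rare] <- unclassifiable_label
  }
  ## (2) split at calls and long gaps
  gap_before <- c(Inf, ann$onset[-1L] - ann$offset[-nrow(ann)])
  run_id <- cumsum(gap_before >= max_gap_ms | lab == call_label |
                     c(FALSE, lab[-length(lab)] == call_label))
  songs <- list()
  for (r in split(seq_len(nrow(ann)), run_id)) {
    r <- r[lab[r] != call_label]
    if (length(r) <= min_song_notes) next
    ## (3) split at unclassifiable notes
    frag_id <- cumsum(lab[r] == unclassifiable_label)
    for (fr in split(r, frag_id)) {
      fr <- fr[lab[fr] != unclassifiable_label]
      if (length(fr) < min_fragment_notes) next          # (4)
      while (length(fr) > max_notes) {                   # (5) greedy chunks
        songs[[length(songs) + 1L]] <- fr[seq_len(max_notes)]
        fr <- fr[-seq_len(max_notes)]
      }
      if (length(fr) >= min_fragment_notes)
        songs[[length(songs) + 1L]] <- fr
    }
  }
  lapply(songs, function(idx)
    song_annotation(ann$onset[idx], ann$offset[idx], lab[idx],
                    timeline = annotation_timeline(ann)))
}

#' Random balanced fold assignment
#'
#' @param sequences List of sequences (any type) or an integer count.
#' @param k Number of folds.
#' @param seed Seed (applied locally).
#' @return Integer vector of fold labels `1..k`, one per sequence.
#' @export
split_folds <- function(sequences, k = 3L, seed = 1L) {
  ns <- if (is.numeric(sequences) && length(sequences) == 1L) sequences
        else length(sequences)
  if (ns < k) stop("too-few-sequences: fewer sequences than folds")
  with_seed(seed * 17L + k, {
    ord <- sample.int(ns)
    fold <- integer(ns)
    fold[ord] <- rep_len(seq_len(k), ns)
    fold
  })
}

#' Select a random training subset of a given duration
#'
#' Sequences are accumulated in random order until the total duration first
#' reaches the budget, emulating training sets of a fixed number of minutes
#' drawn from the non-validation data.
#'
#' @param sequences List of elements with durations (see `durations_ms`).
#' @param minutes Duration budget in minutes.
#' @param seed Seed (applied locally).
#' @param durations_ms Numeric vector of durations; defaults to the
#'   annotation timelines for a `song_dataset`-shaped list.
#' @return Integer indices of the selected sequences.
#' @export
select_training_subset <- function(sequences, minutes, seed = 1L,
                                   durations_ms = NULL) {
  if (is.null(durations_ms))
    durations_ms <- vapply(sequences, function(s)
      annotation_timeline(s$annotation), 0L)
  budget <- minutes * 60000
  if (sum(durations_ms) < budget)
    stop("insufficient-duration: available audio shorter than the budget")
  with_seed(seed * 23L + 5L, {
    ord <- sample.int(length(durations_ms))
    cum <- cumsum(durations_ms[ord])
    take <- seq_len(which(cum >= budget)[1L])
    sort(ord[take])
  })
}
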