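#' Decode an interval-level label sequence with the syntax model
#'
#' For the arrangement in which boundaries are detected first, each detected
#' interval carries an averaged score vector over the note classes. The
#' decoder maximizes the summed log syntax probability plus log score over
#' all label sequences by the Viterbi algorithm over (previous two classes)
#' contexts. The first and second notes use uniform transition probabilities
#' (`1/n`); ties are broken toward the lower class index.
#'
#' @param model A `syntax_model`.
#' @param interval_scores Matrix (intervals x n classes) or list of n-vectors
#'   of per-interval scores (averaged classifier posteriors or converted
#'   emissions).
#' @return Character vector of decoded class labels (empty for no intervals),
#'   with the total log score as attribute `logp`.
#' @export
decode_interval_sequence <- function(model, interval_scores) {
  if (is.list(interval_scores))
    interval_scores <- do.call(rbind, interval_scores)
  if (is.null(interval_scores) || nrow(interval_scores) == 0L)
    return(structure(character(0), logp = 0))
  n <- length(model$classes)
  stopifnot(ncol(interval_scores) == n)
  TT <- nrow(interval_scores)
  ls <- log(interval_scores)
  ltr <- log(model$trans)
  lu <- -log(n)
  ## state = (prev class p in 0..n [0 = initial], current class c)
  delta <- matrix(-Inf, n + 1L, n)
  psi <- array(NA_integer_, dim = c(n + 1L, n, TT))
  delta[1L, ] <- lu + ls[1L, ]
  if (TT >= 2L) for (t in 2:TT) {
    nd <- matrix(-Inf, n + 1L, n)
    for (cc in seq_len(n)) for (z in seq_len(n)) {
      ## transition (p, cc) -> (cc, z)
      best <- -Inf; arg <- NA_integer_
      for (p in 0:n) {
        v <- delta[p + 1L, cc] + if (p == 0L) lu else ltr[p, cc, z]
        if (v > best) { best <- v; arg <- p }
      }
      v <- best + ls[t, z]
      if (v > nd[cc + 1L, z]) { nd[cc + 1L, z] <- v; psi[cc + 1L, z, t] <- arg }
    }
    delta <- nd
  }
  fin <- which(delta == max(delta), arr.ind = TRUE)[1L, ]
  labels <- integer(TT)
  p <- fin[1L] - 1L; cc <- fin[2L]
  labels[TT] <- cc
  if (TT >= 2L) for (t in TT:2) {
    pp <- psi[p + 1L, cc, t]
    labels[t - 1L] <- p
    cc <- p; p <- pp
  }
  structure(model$classes[labels], logp = max(delta))
}

#' Decode a frame-level state path with the sub-state HMM
#'
#' Viterbi decoding of the maximum-log-score hidden state path given a
#' per-frame emission table (classifier posteriors, optionally converted by
#' [convert_posterior_to_emission()]). Ties are broken toward the lower state
#' index. The left-to-right sub-state structure guarantees every decoded note
#' passes through sub-states 1, 2, 3 in order, so a note boundary can only
#' appear at a 3-to-1 (or silence-to-1) transition.
#'
#' @param hmm A `substate_hmm`.
#' @param emissions Matrix (`3n+1` rows x frames) of emission scores; rows
#'   `3*(k-1)+1:3` are the three sub-divisions of class `k`, the last row is
#'   silence.
#' @return A `state_path`: integer vector of state indices with attributes
#'   `logp` and `hmm`.
#' @export
decode_frame_sequence <- function(hmm, emissions) {
  if (any(colSums(emissions) == 0))
    stop("degenerate-emissions: all-zero emission column")
  stopifnot(nrow(emissions) == 3L * length(hmm$classes) + 1L)
  r <- cpp_viterbi(hmm$init_log, hmm$edges, hmm$edge_logp,
                   log(emissions), hmm$emit)
  structure(r$path, logp = r$logp, hmm = hmm, class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  hmm <- attr(x, "hmm")
  st <- hmm$states[unclass(x), ]
  cat(sprintf("<state_path> %d frames, log score %.3f\n",
              length(x), attr(x, "logp")))
  cat(" ", paste0(utils::head(paste0(st$ctx_y, st$sub), 25L), collapse = " "),
      if (length(x) > 25L) "...\n" else "\n")
  invisible(x)
}

#' Convert a decoded state path to a note annotation
#'
#' A note onset is the first frame of a first-sub-division state following a
#' third sub-division, a silence state or the start of the path; its offset
#' is one past the last frame of the following third-sub-division run. The
#' note class is the class whose parts the states emit. Paths that end inside
#' a note are closed at the end of that note's state run.
#'
#' @param path A `state_path` from [decode_frame_sequence()].
#' @param validate Check that consecutive states are permitted transitions.
#' @return A `song_annotation` on the frame grid of the emission table.
#' @export
path_to_annotation <- function(path, validate = TRUE) {
  hmm <- attr(path, "hmm")
  idx <- unclass(path)
  if (validate && length(idx) > 1L) {
    key <- paste(hmm$edges[, 1L], hmm$edges[, 2L])
    steps <- paste(idx[-length(idx)], idx[-1L])
    if (!all(steps %in% key))
      stop("invalid-path: contains a forbidden state transition")
  }
  st <- hmm$states[idx, ]
  silence <- st$sub == "s"
  ## new note where a sub-1 frame starts a new state run
  new_note <- !silence & st$sub == "1" &
    c(TRUE, idx[-1L] != idx[-length(idx)])
  ## a 1->1 self transition continues the note; state change into sub-1 starts
  note_id <- cumsum(new_note)
  note_id[silence] <- 0L
  keep <- note_id > 0L
  if (!any(keep))
    return(song_annotation(timeline = length(idx)))
  on <- tapply(which(keep), note_id[keep], min) - 1L
  off <- tapply(which(keep), note_id[keep], max)
  lab <- st$ctx_y[tapply(which(keep), note_id[keep], min)]
  song_annotation(on, off, lab, timeline = length(idx))
}
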