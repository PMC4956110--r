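#' Fit a song annotator
#'
#' `song_annotator()` is the package's central fitting function. Given
#' training songs (waveforms with note annotations) it fits every stage of
#' the chosen arrangement of boundary detection (BD), local classification
#' (LC) and global sequencing (GS):
#'
#' * `"BD_LC_GS"` — boundaries by amplitude/duration thresholding of the
#'   spectral amplitude envelope, then a convolutional frame classifier over
#'   note classes, then interval-level Viterbi decoding under the
#'   second-order syntax.
#' * `"LC_BDGS"` — a frame classifier over three sub-divisions per class
#'   plus silence, then joint boundary detection and sequencing by Viterbi
#'   decoding of the sub-state hidden Markov model.
#' * `"LCGS_BDGS"` — as `LC_BDGS` but with the widened (303 ms) input
#'   window whose inserted layer lets the network see about three notes of
#'   context.
#'
#' Fitted components: spectrogram normalization statistics, boundary
#' thresholds (first arrangement only), the three-member classifier
#' ensemble, the smoothed second-order syntax model (smoothing constant
#' chosen by cross-validation within the training data), and the choice of
#' whether classifier posteriors are converted to emission likelihoods by
#' Bayes' rule (also chosen within the training data).
#'
#' @param x Training songs: a `song_dataset` or list of
#'   `list(wave, annotation)` pairs (waveform plus [song_annotation()] on
#'   the 1-ms grid).
#' @param arrangement `"BD_LC_GS"`, `"LC_BDGS"` or `"LCGS_BDGS"`.
#' @param classes Optional class alphabet (default: labels present in `x`).
#' @param params [spectrogram_params()].
#' @param config [train_config()] for the classifier ensemble.
#' @param alpha_grid Candidate smoothing constants for the syntax model.
#' @param bayes_select Choose the posterior-to-emission conversion by inner
#'   validation (`TRUE`) or force it off (`FALSE`).
#' @param per_row_norm Per-frequency-row normalization instead of global.
#' @param verbose Log progress.
#' @return An object of class `song_annotator`.
#' @seealso [predict.song_annotator()], [run_arrangement()]
#' @export
song_annotator <- function(x, arrangement = c("LC_BDGS", "BD_LC_GS",
                                              "LCGS_BDGS"),
                           classes = NULL, params = spectrogram_params(),
                           config = train_config(),
                           alpha_grid = c(0, 1e-3, 1e-2, 1e-1, 1),
                           bayes_select = TRUE, per_row_norm = FALSE,
                           verbose = FALSE) {
  arrangement <- match.arg(arrangement)
  stopifnot(length(x) >= 1L)
  anns <- lapply(x, `[[`, "annotation")
  if (is.null(classes))
    classes <- sort(unique(unlist(lapply(anns, annotation_labels))))
  n <- length(classes)

  if (verbose) message("computing spectrograms")
  raw <- lapply(x, function(s) compute_spectrogram(s$wave, params))
  stats <- fit_normalization(raw, per_row = per_row_norm)
  specs <- lapply(raw, apply_normalization, stats = stats)
  ann_fg <- mapply(function(a, sp) annotation_to_frame_grid(a, ncol(sp), params),
                   anns, raw, SIMPLIFY = FALSE)

  thresholds <- NULL
  if (arrangement == "BD_LC_GS") {
    if (verbose) message("fitting boundary-detection thresholds")
    envs <- lapply(raw, envelope_from_spectrogram)
    thresholds <- fit_thresholds(mapply(function(e, a)
      list(envelope = e, annotation = a), envs, ann_fg, SIMPLIFY = FALSE))
  }

  arch <- build_architecture(arrangement, n)
  labels <- mapply(function(a, sp)
    derive_frame_labels(a, arrangement, classes, ncol(sp)),
    ann_fg, specs, SIMPLIFY = FALSE)

  if (verbose) message("training classifier ensemble")
  ensemble <- train_ensemble(specs, labels, arch, config,
                             normalization = stats, classes = classes,
                             verbose = verbose)

  label_seqs <- lapply(anns, annotation_labels)
  alpha <- select_alpha(label_seqs, alpha_grid, classes,
                        seed = config$seed)
  syntax <- fit_syntax_model(label_seqs, alpha, classes)
  hmm <- if (arrangement != "BD_LC_GS") build_substate_hmm(syntax)

  priors <- class_priors(labels, arch$n_outputs)

  obj <- structure(list(arrangement = arrangement, classes = classes,
                        params = params, normalization = stats,
                        thresholds = thresholds, ensemble = ensemble,
                        syntax = syntax, hmm = hmm, priors = priors,
                        alpha = alpha, bayes = FALSE, config = config),
                   class = "song_annotator")

  if (bayes_select) {
    if (verbose) message("selecting posterior-to-emission conversion")
    obj$bayes <- select_bayes_flag(obj, x, raw, specs, ann_fg, label_seqs,
                                   verbose = verbose)
  }
  obj
}

## Empirical output-class frame frequencies on the training fold (label 0,
## the untrainable frames of BD_LC_GS, is excluded).
class_priors <- function(labels, n_outputs) {
  tab <- tabulate(unlist(labels)[unlist(labels) > 0L], nbins = n_outputs)
  p <- tab / sum(tab)
  pmax(p, 1e-6) / sum(pmax(p, 1e-6))
}

## Smoothing constant by 3-fold CV on held-out sequence log-likelihood.
select_alpha <- function(label_seqs, alpha_grid, classes, folds = 3L,
                         seed = 1L) {
  if (length(label_seqs) < folds) return(alpha_grid[1L])
  fold <- split_folds(label_seqs, folds, seed = seed * 11L + 1L)
  ll <- vapply(alpha_grid, function(a) {
    tot <- 0
    for (f in seq_len(folds)) {
      m <- fit_syntax_model(label_seqs[fold != f], a, classes)
      tot <- tot + sum(vapply(label_seqs[fold == f], syntax_loglik,
                              0, model = m))
    }
    tot
  }, 0)
  alpha_grid[which.max(ll)]  # ties: earlier (smaller) alpha wins
}

syntax_loglik <- function(s, model) {
  n <- length(model$classes)
  idx <- match(s, model$classes)
  ll <- min(length(s), 2L) * log(1 / n)
  if (length(idx) >= 3L)
    for (t in 3:length(idx))
      ll <- ll + log(model$trans[idx[t - 2L], idx[t - 1L], idx[t]])
  ll
}

## Decode one sequence from its (raw spectrogram, score matrix) under the
## annotator's arrangement. Returns a frame-grid annotation.
decode_scores <- function(object, scores, raw_spec, bayes = object$bayes) {
  TT <- ncol(scores)
  if (object$arrangement == "BD_LC_GS") {
    env <- envelope_from_spectrogram(raw_spec)
    iv <- detect_note_intervals(env, object$thresholds)
    if (nrow(iv) == 0L)
      return(song_annotation(timeline = TT))
    sc <- t(apply(iv, 1L, function(ab)
      rowMeans(scores[, (ab[1L] + 1L):ab[2L], drop = FALSE])))
    sc <- t(convert_posterior_to_emission(t(sc), object$priors, bayes))
    labs <- decode_interval_sequence(object$syntax, sc)
    song_annotation(iv[, 1L], iv[, 2L], labs, timeline = TT)
  } else {
    em <- convert_posterior_to_emission(scores, object$priors, bayes)
    path <- decode_frame_sequence(object$hmm, em)
    path_to_annotation(path, validate = FALSE)
  }
}

## Inner selection of the Bayes conversion: decode each ensemble member's
## sub-validation sequences with the conversion on and off and keep the
## setting with the lower pooled note & timing ER. Syntax is refitted on the
## member's sub-training sequences so no sub-validation labels leak in.
select_bayes_flag <- function(object, x, raw, specs, ann_fg, label_seqs,
                              verbose = FALSE) {
  truth <- list(); pred_off <- list(); pred_on <- list()
  for (m in seq_along(object$ensemble$members)) {
    sub_val <- object$ensemble$history[[m]]$sub_val
    msyn <- fit_syntax_model(label_seqs[-sub_val], object$alpha,
                             object$classes)
    mobj <- object
    mobj$syntax <- msyn
    if (object$arrangement != "BD_LC_GS")
      mobj$hmm <- build_substate_hmm(msyn)
    for (i in sub_val) {
      sc <- member_frame_scores(object$ensemble$arch,
                                object$ensemble$members[[m]],
                                specs[[i]], mode = "fast")
      truth[[length(truth) + 1L]] <- ann_fg[[i]]
      pred_off[[length(pred_off) + 1L]] <-
        decode_scores(mobj, sc, raw[[i]], bayes = FALSE)
      pred_on[[length(pred_on) + 1L]] <-
        decode_scores(mobj, sc, raw[[i]], bayes = TRUE)
    }
  }
  er_off <- note_timing_error_rate(truth, pred_off)
  er_on <- note_timing_error_rate(truth, pred_on)
  if (verbose)
    message(sprintf("  note & timing ER without conversion %.3f, with %.3f",
                    er_off, er_on))
  er_on < er_off  # ties: keep posteriors unconverted
}

#' Annotate new audio with a fitted song annotator
#'
#' Computes the normalized spectrogram, the ensemble-averaged per-frame
#' class scores, and decodes them according to the fitted arrangement.
#'
#' @param object A fitted `song_annotator`.
#' @param newdata A waveform (numeric vector), a list of waveforms, or a
#'   `song_dataset` (whose waves are used).
#' @param type `"annotation"` (default) or `"scores"` (the per-frame
#'   `score_matrix`).
#' @param mode Score computation mode: `"dense"` (exact shift-and-stitch)
#'   or `"fast"` (stride-8 with nearest fill).
#' @param ... Unused.
#' @return A `song_annotation` on the 1-ms grid (or score matrix), or a
#'   list of them when `newdata` holds several waveforms.
#' @export
predict.song_annotator <- function(object, newdata,
                                   type = c("annotation", "scores"),
                                   mode = c("dense", "fast"), ...) {
  type <- match.arg(type); mode <- match.arg(mode)
  single <- is.numeric(newdata)
  waves <- if (single) list(newdata)
           else lapply(newdata, function(s) if (is.list(s)) s$wave else s)
  out <- lapply(waves, function(w) {
    raw <- compute_spectrogram(w, object$params)
    spec <- apply_normalization(raw, object$normalization)
    scores <- predict_frame_scores(object$ensemble, spec, mode = mode)
    if (type == "scores") return(scores)
    ann_fg <- decode_scores(object, scores, raw)
    frame_grid_to_annotation(ann_fg,
                             timeline = round(length(w) * 1000 /
                                                object$params$sample_rate),
                             params = object$params)
  })
  if (single) out[[1L]] else out
}

#' @export
print.song_annotator <- function(x, ...) {
  cat(sprintf("<song_annotator> arrangement %s, %d note classes\n",
              x$arrangement, length(x$classes)))
  cat(sprintf("  syntax smoothing alpha = %g; Bayes conversion %s\n",
              x$alpha, if (x$bayes) "on" else "off"))
  if (!is.null(x$thresholds))
    cat(sprintf("  thresholds: amp %.2f, gap %d ms, dur %d ms\n",
                x$thresholds$amp_thr, as.integer(x$thresholds$gap_thr),
                as.integer(x$thresholds$dur_thr)))
  print(x$ensemble)
  invisible(x)
}

#' @export
summary.song_annotator <- function(object, ...) {
  out <- list(arrangement = object$arrangement, classes = object$classes,
              alpha = object$alpha, bayes = object$bayes,
              thresholds = object$thresholds,
              sub_validation_errors = vapply(object$ensemble$history,
                                             function(h) h$val_err, 0))
  print(object)
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = " ")))
  invisible(out)
}

#' Simulate note sequences from a fitted annotator's syntax model
#'
#' @param object A `song_annotator`.
#' @param nsim Number of sequences.
#' @param seed Optional seed.
#' @param ... Passed to [simulate.syntax_model()].
#' @return List of label sequences.
#' @export
simulate.song_annotator <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$syntax, nsim = nsim, seed = seed, ...)
}

#' Plot a spectrogram with predicted (and optionally true) annotations
#'
#' @param x A fitted `song_annotator`.
#' @param wave Waveform to annotate and display.
#' @param truth Optional true `song_annotation` drawn above the prediction.
#' @param mode Score mode passed to [predict.song_annotator()].
#' @param ... Further arguments to [graphics::image()].
#' @export
plot.song_annotator <- function(x, wave, truth = NULL, mode = "fast", ...) {
  raw <- compute_spectrogram(wave, x$params)
  pred <- predict(x, wave, mode = mode)
  graphics::image(z = t(unclass(raw)), x = seq_len(ncol(raw)),
                  y = ((seq_len(nrow(raw)) - 1) * x$params$sample_rate /
                         x$params$fft_size + x$params$band_low) / 1000,
                  col = grey.colors(64, rev = TRUE),
                  xlab = "time (ms)", ylab = "frequency (kHz)", ...)
  draw_ann <- function(a, y0, col) {
    if (!nrow(a)) return()
    graphics::rect(a$onset, y0, a$offset, y0 + 0.25, col = col, border = NA)
    graphics::text((a$onset + a$offset) / 2, y0 + 0.45, a$label, cex = 0.7)
  }
  draw_ann(pred, 0.3, "steelblue")
  if (!is.null(truth)) draw_ann(truth, 1.1, "tomato")
  invisible(pred)
}
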