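#' Build the convolutional classifier architecture
#'
#' The frame classifier is a fully convolutional network over normalized
#' spectrogram windows: three blocks of (5x5 or 4x4) convolution, 1x1 CCCP
#' (cascaded cross-channel parametric pooling) convolution and 2x2 stride-2
#' max-pooling, then a 240-channel convolution spanning the whole remaining
#' height (11 rows) and 9 frames, and a 1x1 softmax convolution. The input
#' window is 96 frames (111 ms, roughly one note) for the `BD_LC_GS` and
#' `LC_BDGS` arrangements. The `LCGS_BDGS` arrangement widens the window to
#' 288 frames (303 ms, roughly three notes) by inserting one extra 25-frame
#' convolution before the softmax layer, letting the network see syntax
#' context. The output has `n` channels (the note classes) for `BD_LC_GS`
#' and `3n + 1` (three sub-divisions per class plus silence) for the other
#' two arrangements.
#'
#' @param arrangement One of `"BD_LC_GS"`, `"LC_BDGS"`, `"LCGS_BDGS"`.
#' @param n_note_classes Number of note classes, `>= 2`.
#' @param n_cccp Number of CCCP layers per block (1 by default).
#' @return An `architecture_spec`; its `layers` compose to a 1x1 output on
#'   the declared input window (checked at construction).
#' @examples
#' arch <- build_architecture("BD_LC_GS", 8)
#' arch$layers[[10]]$w  # temporal width of the fourth convolutional layer: 9
#' @export
build_architecture <- function(arrangement = c("BD_LC_GS", "LC_BDGS",
                                               "LCGS_BDGS"),
                               n_note_classes, n_cccp = 1L) {
  if (length(arrangement) != 1L ||
      !arrangement %in% c("BD_LC_GS", "LC_BDGS", "LCGS_BDGS"))
    stop("unknown-arrangement: ", paste(arrangement, collapse = "/"))
  stopifnot(n_note_classes >= 2L)
  n <- as.integer(n_note_classes)
  n_outputs <- if (arrangement == "BD_LC_GS") n else 3L * n + 1L
  input_width <- if (arrangement == "LCGS_BDGS") 288L else 96L

  conv <- function(c_out, h, w, act = "relu")
    list(kind = "conv", h = h, w = w, c_out = c_out, activation = act)
  pool <- list(kind = "maxpool")
  layers <- list()
  blocks <- list(c(5L, 5L), c(5L, 5L), c(4L, 4L))
  for (b in blocks) {
    layers <- c(layers, list(conv(16L, b[1L], b[2L])))
    for (k in seq_len(n_cccp)) layers <- c(layers, list(conv(16L, 1L, 1L)))
    layers <- c(layers, list(pool))
  }
  layers <- c(layers, list(conv(240L, 11L, 9L)))
  if (arrangement == "LCGS_BDGS")
    layers <- c(layers, list(conv(240L, 1L, 25L)))
  layers <- c(layers, list(conv(n_outputs, 1L, 1L, act = "softmax")))

  arch <- structure(list(arrangement = arrangement, input_height = 112L,
                         input_width = input_width, n_note_classes = n,
                         n_outputs = n_outputs, layers = annotate_c_in(layers)),
                    class = "architecture_spec")
  tr <- shape_trace(arch)
  fin <- tr[nrow(tr), ]
  if (fin[["h"]] != 1L || fin[["w"]] != 1L)
    stop("architecture does not compose to a 1x1 output on its input window")
  arch
}

annotate_c_in <- function(layers) {
  c_in <- 1L
  for (i in seq_along(layers)) {
    if (layers[[i]]$kind == "conv") {
      layers[[i]]$c_in <- c_in
      c_in <- layers[[i]]$c_out
    }
  }
  layers
}

#' Shape trace of an architecture
#'
#' Composes the layer shape transforms over the declared input window,
#' returning the spatial size after every layer.
#'
#' @param arch An `architecture_spec`.
#' @param H,W Input size to trace (defaults: the declared window).
#' @return Data frame with columns `layer`, `kind`, `h`, `w`.
#' @export
shape_trace <- function(arch, H = arch$input_height, W = arch$input_width) {
  h <- H; w <- W
  out <- data.frame(layer = 0L, kind = "input", h = h, w = w)
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$kind == "maxpool") { h <- h %/% 2L; w <- w %/% 2L }
    else { h <- h - l$h + 1L; w <- w - l$w + 1L }
    if (h < 1L || w < 1L) stop("input-too-short: shape collapses at layer ", i)
    out <- rbind(out, data.frame(layer = i, kind = l$kind, h = h, w = w))
  }
  out
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s: %dx%d input, %d outputs\n",
              x$arrangement, x$input_height, x$input_width, x$n_outputs))
  for (l in x$layers) {
    if (l$kind == "maxpool") cat("  maxpool 2x2 /2\n")
    else cat(sprintf("  conv %dch %dx%d %s\n", l$c_out, l$h, l$w,
                     l$activation))
  }
  invisible(x)
}

#' Receptive-field duration of an input window
#'
#' A window of `w` 1-ms frames anchored at its first sample spans
#' `(w-1)*hop + fft_size` samples of audio.
#'
#' @param input_width Window width in frames.
#' @param params [spectrogram_params()].
#' @return Duration in ms.
#' @export
receptive_field_ms <- function(input_width, params = spectrogram_params()) {
  ((input_width - 1) * params$hop + params$fft_size) /
    params$sample_rate * 1000
}

#' Derive per-frame training labels from an annotation
#'
#' For `BD_LC_GS` the network learns note classes only: frames inside a note
#' get the note's class, frames outside get label 0 (excluded from the
#' loss). For the sub-state arrangements every note of duration `d` frames is
#' split into three parts at `floor(d*k/3)` (k = 1, 2); frame labels are
#' `3*(class-1)+part`, and silence frames get class `3n+1`.
#'
#' @param ann A `song_annotation` on the spectrogram frame grid.
#' @param arrangement Arrangement name.
#' @param classes Class alphabet (defines class indices).
#' @param n_frames Number of spectrogram frames (defaults to the annotation
#'   timeline).
#' @return Integer vector of length `n_frames`.
#' @export
derive_frame_labels <- function(ann, arrangement, classes,
                                n_frames = annotation_timeline(ann)) {
  if (nrow(ann) && max(ann$offset) > n_frames)
    stop("invalid-annotation: notes beyond the frame grid")
  n <- length(classes)
  sub_divided <- arrangement != "BD_LC_GS"
  lab <- rep(if (sub_divided) 3L * n + 1L else 0L, n_frames)
  for (i in seq_len(nrow(ann))) {
    cls <- match(ann$label[i], classes)
    if (is.na(cls)) stop("unknown-class: ", ann$label[i])
    on <- ann$onset[i]; d <- ann$offset[i] - ann$onset[i]
    if (!sub_divided) {
      lab[(on + 1L):(on + d)] <- cls
    } else {
      cut1 <- floor(d / 3); cut2 <- floor(2 * d / 3)
      base <- 3L * (cls - 1L)
      if (cut1 > 0) lab[(on + 1L):(on + cut1)] <- base + 1L
      if (cut2 > cut1) lab[(on + cut1 + 1L):(on + cut2)] <- base + 2L
      lab[(on + cut2 + 1L):(on + d)] <- base + 3L
    }
  }
  lab
}

#' He initialization of network parameters
#'
#' Weights are sampled from a zero-mean Gaussian with standard deviation
#' `sqrt(2 / fan_in)` where `fan_in = c_in * h * w`; biases start at zero.
#' Deterministic for a given seed.
#'
#' @param arch An `architecture_spec`.
#' @param seed Integer seed.
#' @return List of per-layer parameter lists (`W`, `b`), `NULL` for pooling
#'   layers.
#' @export
initialize_parameters <- function(arch, seed) {
  with_seed(seed, lapply(arch$layers, function(l) {
    if (l$kind == "maxpool") return(NULL)
    fan_in <- l$c_in * l$h * l$w
    list(W = matrix(stats::rnorm(l$c_out * fan_in, sd = sqrt(2 / fan_in)),
                    nrow = l$c_out),
         b = rep(0, l$c_out))
  }))
}

## Reflect-pad matrix columns (no edge repetition).
reflect_pad_cols <- function(m, left, right) {
  n <- ncol(m)
  if (n < max(left, right) + 1L)
    stop("input-too-short: sequence shorter than half the input window")
  li <- if (left > 0L) seq(left + 1L, 2L) else integer(0)
  ri <- if (right > 0L) seq(n - 1L, n - right) else integer(0)
  m[, c(li, seq_len(n), ri), drop = FALSE]
}

cnn_temporal_stride <- 8L  # three 2x2 stride-2 pools

## Strided network outputs on a padded spectrogram, in position blocks to
## bound memory. Returns (n_outputs x n_positions); position j (0-based)
## sees padded columns [8j, 8j + win).
strided_scores <- function(arch, params, padded, n_pos,
                           block = 512L) {
  win <- arch$input_width
  out <- matrix(NA_real_, arch$n_outputs, n_pos)
  j0 <- 0L
  while (j0 < n_pos) {
    j1 <- min(j0 + block, n_pos)
    cols <- (8L * j0 + 1L):min(8L * (j1 - 1L) + win, ncol(padded))
    r <- cpp_cnn_forward(arch$layers, params, padded[, cols, drop = FALSE])
    out[, (j0 + 1L):j1] <- r$out[, seq_len(j1 - j0), drop = FALSE]
    j0 <- j1
  }
  out
}

## Frame scores of a single parameter set. mode "dense": exact shift-and-
## stitch over the 8 temporal phases; "fast": stride-8 evaluation with
## nearest-neighbour fill.
member_frame_scores <- function(arch, params, spec,
                                mode = c("dense", "fast")) {
  mode <- match.arg(mode)
  TT <- ncol(spec)
  pad <- arch$input_width %/% 2L
  padded <- reflect_pad_cols(unclass(spec), pad, pad + cnn_temporal_stride - 1L)
  if (mode == "fast") {
    n_pos <- (ncol(padded) - arch$input_width) %/% 8L + 1L
    s <- strided_scores(arch, params, padded, n_pos)
    j <- pmin(round((seq_len(TT) - 1L) / 8L), n_pos - 1L)
    s[, j + 1L, drop = FALSE]
  } else {
    out <- matrix(NA_real_, arch$n_outputs, TT)
    for (p in 0:7) {
      sub <- padded[, (p + 1L):ncol(padded), drop = FALSE]
      n_pos <- (ncol(sub) - arch$input_width) %/% 8L + 1L
      frames <- p + 8L * (seq_len(n_pos) - 1L)
      keep <- frames < TT
      if (!any(keep)) next
      s <- strided_scores(arch, params, sub, n_pos)
      out[, frames[keep] + 1L] <- s[, keep, drop = FALSE]
    }
    out
  }
}

#' Per-frame class scores from a classifier ensemble
#'
#' For every 1-ms frame the ensemble outputs the softmax class scores of the
#' input window centred on that frame, averaged over the three members.
#' Dense per-frame coverage despite the network's temporal stride of 8 is
#' obtained by shift-and-stitch (`mode = "dense"`, exact); `mode = "fast"`
#' evaluates at stride 8 and fills intermediate frames with the nearest
#' computed column. Edges are reflect-padded so every frame has a centred
#' window.
#'
#' @param ensemble A `classifier_ensemble` from [train_ensemble()].
#' @param spec A normalized `song_spectrogram` (use the ensemble's
#'   normalization statistics).
#' @param mode `"dense"` or `"fast"`.
#' @return A `score_matrix` (`n_outputs` x frames); columns sum to one.
#' @export
predict_frame_scores <- function(ensemble, spec, mode = c("dense", "fast")) {
  mode <- match.arg(mode)
  acc <- NULL
  for (params in ensemble$members) {
    s <- member_frame_scores(ensemble$arch, params, spec, mode)
    acc <- if (is.null(acc)) s else acc + s
  }
  structure(acc / length(ensemble$members),
            class = c("score_matrix", "matrix", "array"))
}

#' Training configuration for the frame classifier
#'
#' Defaults follow the full training protocol: 8 log-spaced learning-rate
#' candidates in `[0.001, 0.04]` probed (with 4 initialization seeds each)
#' for 32 iterations, then full training at the winning rate for as long as
#' the sub-validation error keeps decreasing (patience of 5 evaluations, one
#' evaluation per 50 iterations), halving the rate when it stops, three
#' halvings in total. Mini-batches are random training sequences totalling at
#' most `batch_s` seconds. Scaled-down configurations for quick experiments
#' simply reduce these counts.
#'
#' @param lr_candidates Learning-rate candidates (default 8 log-spaced values
#'   in `[0.001, 0.04]`).
#' @param seeds_per_rate Initialization seeds probed per rate.
#' @param probe_iters Iterations per probe candidate.
#' @param halvings Learning-rate halvings after the probe.
#' @param patience Evaluations without improvement before a halving.
#' @param eval_every Iterations between sub-validation evaluations.
#' @param batch_s Mini-batch budget in seconds of audio.
#' @param max_iters Hard iteration cap per member (safety stop).
#' @param eval_budget_s Cap (seconds) on the sub-validation audio used for
#'   the error evaluations during training.
#' @param seed Master seed for data splits, batch order and probed
#'   initializations.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_candidates = NULL, seeds_per_rate = 4L,
                         probe_iters = 32L, halvings = 3L, patience = 5L,
                         eval_every = 50L, batch_s = 32, max_iters = 4000L,
                         eval_budget_s = Inf, seed = 1L) {
  if (is.null(lr_candidates))
    lr_candidates <- exp(seq(log(0.001), log(0.04), length.out = 8L))
  stopifnot(probe_iters > 0, halvings >= 0, patience > 0, eval_every > 0,
            batch_s > 0, seeds_per_rate > 0)
  structure(list(lr_candidates = lr_candidates,
                 seeds_per_rate = as.integer(seeds_per_rate),
                 probe_iters = as.integer(probe_iters),
                 halvings = as.integer(halvings),
                 patience = as.integer(patience),
                 eval_every = as.integer(eval_every),
                 batch_s = batch_s, max_iters = as.integer(max_iters),
                 eval_budget_s = eval_budget_s, seed = as.integer(seed)),
            class = "train_config")
}

## Pad a training sequence and extract its stride-8 position labels.
prep_train_seq <- function(spec, labels, arch) {
  TT <- ncol(spec)
  pad <- arch$input_width %/% 2L
  padded <- reflect_pad_cols(unclass(spec), pad, pad + cnn_temporal_stride - 1L)
  n_pos <- (ncol(padded) - arch$input_width) %/% 8L + 1L
  frames <- 8L * (seq_len(n_pos) - 1L)
  lab <- ifelse(frames < TT, labels[pmin(frames, TT - 1L) + 1L], 0L)
  list(x = padded, y = as.integer(lab), frames = TT)
}

sgd_update <- function(params, grads, lr, scale) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    params[[i]]$W <- params[[i]]$W - lr * scale * grads[[i]]$dW
    params[[i]]$b <- params[[i]]$b - lr * scale * grads[[i]]$db
  }
  params
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(acc))
    if (!is.null(acc[[i]])) {
      acc[[i]]$dW <- acc[[i]]$dW + g[[i]]$dW
      acc[[i]]$db <- acc[[i]]$db + g[[i]]$db
    }
  acc
}

## One SGD iteration over a random mini-batch; returns updated params.
sgd_iteration <- function(arch, params, train_prepped, lr, batch_frames) {
  ord <- sample.int(length(train_prepped))
  total <- 0L; batch <- integer(0)
  for (i in ord) {
    d <- train_prepped[[i]]$frames
    if (length(batch) && total + d > batch_frames) next
    batch <- c(batch, i); total <- total + d
    if (total >= batch_frames) break
  }
  acc <- NULL; n_tot <- 0L
  for (i in batch) {
    g <- cpp_cnn_grad(arch$layers, params, train_prepped[[i]]$x,
                      train_prepped[[i]]$y)
    if (!is.finite(g$loss)) return(structure(params, diverged = TRUE))
    acc <- accumulate_grads(acc, g$grads)
    n_tot <- n_tot + g$n
  }
  if (n_tot == 0L) return(params)
  sgd_update(params, acc, lr, 1 / n_tot)
}

## Strided classification error on prepped sequences (label 0 ignored).
strided_error <- function(arch, params, prepped) {
  wrong <- 0L; n <- 0L
  for (d in prepped) {
    keep <- d$y > 0L
    if (!any(keep)) next
    n_pos <- length(d$y)
    s <- strided_scores(arch, params, d$x, n_pos)
    pred <- max.col(t(s[, keep, drop = FALSE]), ties.method = "first")
    wrong <- wrong + sum(pred != d$y[keep])
    n <- n + sum(keep)
  }
  if (n == 0L) return(NA_real_)
  wrong / n
}

train_one_member <- function(arch, train_prepped, val_prepped, cfg,
                             member_seed, verbose = FALSE,
                             init_params = NULL, fixed_lr = NULL) {
  batch_frames <- round(cfg$batch_s * 1000)
  ## --- probe phase: joint (learning rate, seed) search ---
  if (is.null(fixed_lr)) {
    cand <- expand.grid(seed_k = seq_len(cfg$seeds_per_rate),
                        lr = cfg$lr_candidates)
    best <- list(err = Inf, lr = cfg$lr_candidates[1L], seed = member_seed)
    for (ci in seq_len(nrow(cand))) {
      seed_c <- member_seed + 104729L * cand$seed_k[ci]
      params <- if (is.null(init_params)) initialize_parameters(arch, seed_c)
                else init_params
      set.seed(seed_c + 1L)
      cand_best <- Inf
      for (it in seq_len(cfg$probe_iters)) {
        params <- sgd_iteration(arch, params, train_prepped, cand$lr[ci],
                                batch_frames)
        if (isTRUE(attr(params, "diverged"))) { cand_best <- Inf; break }
        err <- strided_error(arch, params, val_prepped)
        if (!is.na(err) && err < cand_best) cand_best <- err
      }
      if (verbose)
        message(sprintf("  probe lr=%.4f seed=%d: best err %.3f",
                        cand$lr[ci], seed_c, cand_best))
      if (cand_best < best$err)
        best <- list(err = cand_best, lr = cand$lr[ci], seed = seed_c)
    }
    if (!is.finite(best$err) && is.null(init_params))
      stop("training-failed: loss diverged at every candidate rate")
    lr <- best$lr
    params <- if (is.null(init_params)) initialize_parameters(arch, best$seed)
              else init_params
    set.seed(best$seed + 2L)
  } else {
    lr <- fixed_lr
    params <- init_params
    set.seed(member_seed + 2L)
  }
  ## --- full training with halvings ---
  best_err <- Inf; best_params <- params
  halvings_left <- cfg$halvings; bad_evals <- 0L; it <- 0L
  repeat {
    for (k in seq_len(cfg$eval_every)) {
      it <- it + 1L
      params <- sgd_iteration(arch, params, train_prepped, lr, batch_frames)
      if (isTRUE(attr(params, "diverged"))) {
        params <- best_params
        bad_evals <- cfg$patience  # force a halving
        break
      }
    }
    err <- strided_error(arch, params, val_prepped)
    if (verbose)
      message(sprintf("  iter %d lr=%.5f val err %.3f", it, lr, err))
    if (!is.na(err) && err < best_err - 1e-9) {
      best_err <- err; best_params <- params; bad_evals <- 0L
    } else bad_evals <- bad_evals + 1L
    if (bad_evals >= cfg$patience) {
      if (halvings_left == 0L) break
      lr <- lr / 2; halvings_left <- halvings_left - 1L; bad_evals <- 0L
    }
    if (it >= cfg$max_iters) break
  }
  list(params = best_params, val_err = best_err, lr = lr)
}

## Cap the evaluation set by a duration budget (first sequences kept).
cap_eval_set <- function(prepped, budget_s) {
  if (!is.finite(budget_s)) return(prepped)
  tot <- 0; keep <- integer(0)
  for (i in seq_along(prepped)) {
    keep <- c(keep, i); tot <- tot + prepped[[i]]$frames / 1000
    if (tot >= budget_s) break
  }
  prepped[keep]
}

#' Train the three-member classifier ensemble
#'
#' The training fold is split into three sub-folds; for each of the three
#' train-on-two-thirds / validate-on-one-third combinations, a (learning
#' rate, initialization seed) pair is selected by probing every candidate
#' for a fixed number of iterations, and the network is then trained at the
#' winning rate with the staged halving schedule of [train_config()]. For
#' the `LCGS_BDGS` arrangement the network without the inserted wide layer
#' is trained first; the layer is then inserted and the whole stack
#' fine-tuned. At recognition time the three members' softmax outputs are
#' averaged.
#'
#' @param spectrograms List of normalized `song_spectrogram`s (training fold).
#' @param labels List of per-frame integer label vectors from
#'   [derive_frame_labels()].
#' @param arch An `architecture_spec`.
#' @param cfg A [train_config()].
#' @param normalization The `normalization_stats` the spectrograms were
#'   normalized with (stored for prediction).
#' @param classes Class alphabet (stored).
#' @param verbose Log progress.
#' @return A `classifier_ensemble` with three `members`.
#' @export
train_ensemble <- function(spectrograms, labels, arch, cfg = train_config(),
                           normalization = NULL, classes = NULL,
                           verbose = FALSE) {
  stopifnot(length(spectrograms) == length(labels))
  ns <- length(spectrograms)
  if (ns < 6L)
    stop("too-few-sequences: need at least 2 sequences per sub-split")
  fold <- with_seed(cfg$seed * 31L + 7L,
                    (sample.int(ns) %% 3L) + 1L)
  is_lcgs <- arch$arrangement == "LCGS_BDGS"
  narrow <- if (is_lcgs) build_architecture("LC_BDGS", arch$n_note_classes)
  if (!is_lcgs)
    prepped <- lapply(seq_len(ns), function(i)
      prep_train_seq(spectrograms[[i]], labels[[i]], arch))
  members <- vector("list", 3L)
  history <- vector("list", 3L)
  for (m in 1:3) {
    tr_idx <- which(fold != m); va_idx <- which(fold == m)
    if (verbose) message(sprintf("member %d: %d train / %d validation sequences",
                                 m, length(tr_idx), length(va_idx)))
    member_seed <- cfg$seed * 131L + m
    if (is_lcgs) {
      prep_n <- function(idx, a) lapply(idx, function(i)
        prep_train_seq(spectrograms[[i]], labels[[i]], a))
      tr_n <- prep_n(tr_idx, narrow)
      va_n <- cap_eval_set(prep_n(va_idx, narrow), cfg$eval_budget_s)
      pre <- train_one_member(narrow, tr_n, va_n, cfg, member_seed,
                              verbose = verbose)
      ## insert the wide layer (fresh He init) and fine-tune the full stack
      ins_pos <- length(arch$layers) - 1L
      ins_par <- with_seed(member_seed + 13L, {
        l <- arch$layers[[ins_pos]]
        fan_in <- l$c_in * l$h * l$w
        list(W = matrix(stats::rnorm(l$c_out * fan_in,
                                     sd = sqrt(2 / fan_in)), nrow = l$c_out),
             b = rep(0, l$c_out))
      })
      full_params <- append(pre$params, list(ins_par), after = ins_pos - 1L)
      tr_w <- prep_n(tr_idx, arch)
      va_w <- cap_eval_set(prep_n(va_idx, arch), cfg$eval_budget_s)
      fit <- train_one_member(arch, tr_w, va_w, cfg, member_seed + 17L,
                              verbose = verbose, init_params = full_params,
                              fixed_lr = pre$lr)
    } else {
      fit <- train_one_member(arch, prepped[tr_idx],
                              cap_eval_set(prepped[va_idx], cfg$eval_budget_s),
                              cfg, member_seed, verbose = verbose)
    }
    members[[m]] <- fit$params
    history[[m]] <- list(val_err = fit$val_err, final_lr = fit$lr,
                         sub_val = va_idx)
  }
  structure(list(arch = arch, members = members,
                 normalization = normalization, classes = classes,
                 config = cfg, history = history),
            class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  errs <- vapply(x$history, function(h) h$val_err, 0)
  cat(sprintf("<classifier_ensemble> %s, %d members, sub-validation errors %s\n",
              x$arch$arrangement, length(x$members),
              paste(sprintf("%.3f", errs), collapse = " / ")))
  invisible(x)
}
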