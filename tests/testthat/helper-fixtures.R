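# Shared fixtures. Expensive objects are memoized per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# A tone embedded in silence, annotated; enough for envelope/threshold tests.
toy_tone_song <- function(freq = 2000, on_ms = 100, dur_ms = 80,
                          total_ms = 300, amp = 0.4, sr = 32000) {
  wave <- numeric(total_ms * sr / 1000)
  idx <- (on_ms * sr / 1000 + 1):((on_ms + dur_ms) * sr / 1000)
  wave[idx] <- amp * sin(2 * pi * freq * seq_along(idx) / sr)
  list(wave = wave,
       annotation = song_annotation(on_ms, on_ms + dur_ms, "a", total_ms))
}

# Random annotation pairs that look like realistic recognizer output: the
# prediction is the truth with jittered boundaries, plus occasional class
# swaps, dropped and inserted notes.
random_annotation_pair <- function(n_notes = 8, timeline = 2000,
                                   classes = c("a", "b", "c")) {
  on <- sort(sample(seq(5, timeline - 120, by = 1), n_notes))
  dur <- sample(30:90, n_notes, replace = TRUE)
  off <- pmin(on + dur, c(on[-1] - 2, timeline))
  keep <- off - on >= 10
  on <- on[keep]; off <- off[keep]
  lab <- sample(classes, length(on), replace = TRUE)
  truth <- song_annotation(on, off, lab, timeline)
  jit <- function(v) v + sample(-8:8, length(v), replace = TRUE)
  p_on <- jit(on); p_off <- jit(off)
  p_on <- pmax(p_on, 0); p_off <- pmin(pmax(p_off, p_on + 5), timeline)
  p_lab <- ifelse(stats::runif(length(lab)) < 0.15,
                  sample(classes, length(lab), replace = TRUE), lab)
  drop <- stats::runif(length(p_on)) < 0.1
  p_on <- p_on[!drop]; p_off <- p_off[!drop]; p_lab <- p_lab[!drop]
  o <- order(p_on)
  p_on <- p_on[o]; p_off <- p_off[o]; p_lab <- p_lab[o]
  ## sequentially clip any jitter-induced overlaps, dropping degenerates
  keep <- logical(length(p_on)); last <- 0L
  for (i in seq_along(p_on)) {
    p_on[i] <- max(p_on[i], last)
    if (p_off[i] - p_on[i] >= 3 && p_off[i] <= timeline) {
      keep[i] <- TRUE
      last <- p_off[i]
    }
  }
  pred <- song_annotation(p_on[keep], p_off[keep], p_lab[keep], timeline)
  list(truth = truth, pred = pred)
}

# Independent decoding oracles: exhaustive enumeration over all label
# sequences / state paths, sharing only the model's probabilities with the
# decoders under test.

brute_interval_decode <- function(model, scores) {
  n <- length(model$classes)
  TT <- nrow(scores)
  combs <- expand.grid(rep(list(seq_len(n)), TT))
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(combs))) {
    lab <- as.integer(combs[r, ])
    lp <- 0
    for (t in seq_len(TT)) {
      lp <- lp + log(scores[t, lab[t]]) +
        if (t <= 2) log(1 / n) else log(model$trans[lab[t - 2], lab[t - 1], lab[t]])
    }
    if (lp > best + 1e-12) { best <- lp; arg <- lab }
  }
  list(labels = model$classes[arg], logp = best)
}

brute_frame_decode <- function(hmm, emissions) {
  M <- songscribe:::transition_matrix(hmm)
  lM <- log(M); lem <- log(emissions)
  TT <- ncol(emissions)
  best <- -Inf; arg <- NULL
  ## depth-first enumeration over all legal state paths
  rec <- function(prefix, lp, t) {
    s <- prefix[t]
    lp <- lp + lem[hmm$emit[s], t]
    if (t == TT) {
      if (lp > best + 1e-12) { best <<- lp; arg <<- prefix }
      return()
    }
    for (nx in which(is.finite(lM[s, ])))
      rec(c(prefix, nx), lp + lM[s, nx], t + 1)
  }
  for (s0 in which(is.finite(hmm$init_log)))
    rec(s0, hmm$init_log[s0], 1)
  list(path = arg, logp = best)
}

# Brute-force Levenshtein distance by exhaustive recursion (test oracle).
brute_edit_distance <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(brute_edit_distance(a[-1], b) + 1,
      brute_edit_distance(a, b[-1]) + 1,
      brute_edit_distance(a[-1], b[-1]) + (a[1] != b[1]))
}

# Tiny dataset + micro training configuration for pipeline smoke tests.
micro_dataset <- function(seed = 3, minutes = 1.1, n_classes = 2) {
  generate_dataset(generator_config(classes = default_note_classes(n_classes),
                                    total_minutes = minutes, seed = seed))
}

micro_train_config <- function(seed = 1) {
  train_config(lr_candidates = 0.02, seeds_per_rate = 1, probe_iters = 2,
               halvings = 1, patience = 1, eval_every = 4, batch_s = 2,
               max_iters = 16, eval_budget_s = 2, seed = seed)
}

# The scaled-down study configuration used by the end-to-end benchmark: 5
# note classes, ~3.5 minutes of audio (2 min training subsets, ~1 min
# validation folds), 30 dB SNR.
benchmark_generator <- function(seed, p_zero_gap = 0.05, minutes = 3.5) {
  generator_config(classes = default_note_classes(5),
                   total_minutes = minutes, p_zero_gap = p_zero_gap,
                   noise_snr_db = 30, seed = seed)
}

benchmark_train_config <- function(seed = 1) {
  train_config(lr_candidates = c(0.005, 0.02), seeds_per_rate = 1,
               probe_iters = 4, halvings = 3, patience = 2, eval_every = 8,
               batch_s = 2, max_iters = 64, eval_budget_s = 2, seed = seed)
}

# Lighter schedule for the qualitative checks (arrangement ordering,
# training-budget direction), where only large effects are asserted.
light_train_config <- function(seed = 1) {
  cfg <- benchmark_train_config(seed)
  cfg$max_iters <- 40L
  cfg
}

# Cached end-to-end runs shared between acceptance criteria.
benchmark_main_run <- function() {
  memo("bench_main", {
    ds <- generate_dataset(benchmark_generator(seed = 11))
    run_arrangement(ds, "LCGS_BDGS", train_minutes = 2, folds = 3, seed = 1,
                    config = benchmark_train_config(), score_mode = "fast")
  })
}

benchmark_zero_gap_runs <- function() {
  memo("bench_zero_gap", {
    ds <- generate_dataset(benchmark_generator(seed = 12, p_zero_gap = 0.4,
                                               minutes = 2.4))
    lapply(c(BD_LC_GS = "BD_LC_GS", LC_BDGS = "LC_BDGS"), function(a)
      run_arrangement(ds, a, train_minutes = 1.3, folds = 3, seed = 2,
                      config = light_train_config(2),
                      score_mode = "fast"))
  })
}
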