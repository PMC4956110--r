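#' Cross-validated evaluation of one arrangement
#'
#' Runs the full pipeline with k-fold cross-validation over the song
#' sequences of a dataset: in each fold a training subset of the requested
#' duration is drawn from the non-validation sequences, every stage
#' (normalization, thresholds where applicable, classifier ensemble, syntax
#' model and its hyper-parameters) is fitted strictly within that subset,
#' and the held-out sequences are annotated and scored with all six error
#' measures. Rates are pooled over folds by summing numerators and
#' denominators (equivalently, by scoring the concatenated collections).
#'
#' @param dataset A `song_dataset` (or list of `list(wave, annotation)`).
#' @param arrangement `"BD_LC_GS"`, `"LC_BDGS"` or `"LCGS_BDGS"`.
#' @param train_minutes Training-subset duration per fold (minutes).
#' @param folds Number of cross-validation folds.
#' @param seed Master seed: folds, subsets and all training randomness
#'   derive from it.
#' @param config [train_config()]; its seed is overridden per fold from
#'   `seed`.
#' @param score_mode Frame-score mode for validation decoding (`"dense"`
#'   exact, `"fast"` stride-8).
#' @param verbose Log progress.
#' @param ... Passed to [song_annotator()].
#' @return An `arrangement_run`: per-fold and pooled `error_report`s, the
#'   chosen hyper-parameters, and provenance (seed, fold assignment).
#' @export
run_arrangement <- function(dataset, arrangement, train_minutes = 2,
                            folds = 3L, seed = 1L, config = train_config(),
                            score_mode = c("dense", "fast"),
                            verbose = FALSE, ...) {
  score_mode <- match.arg(score_mode)
  fold <- split_folds(dataset, folds, seed = seed)
  per_fold <- vector("list", folds)
  hyper <- vector("list", folds)
  truth_all <- list(); pred_all <- list()
  for (f in seq_len(folds)) {
    if (verbose) message(sprintf("fold %d/%d [%s]", f, folds, arrangement))
    pool <- which(fold != f)
    sub <- pool[select_training_subset(dataset[pool], train_minutes,
                                       seed = seed * 101L + f)]
    cfg <- config
    cfg$seed <- as.integer(seed * 1009L + f)
    fit <- song_annotator(dataset[sub], arrangement, config = cfg,
                          verbose = verbose, ...)
    val <- which(fold == f)
    pred <- predict(fit, dataset[val], mode = score_mode)
    truth <- lapply(dataset[val], `[[`, "annotation")
    per_fold[[f]] <- error_report(truth, pred)
    hyper[[f]] <- list(alpha = fit$alpha, bayes = fit$bayes,
                       thresholds = fit$thresholds,
                       training_sequences = sub)
    truth_all <- c(truth_all, truth); pred_all <- c(pred_all, pred)
  }
  structure(list(arrangement = arrangement, folds = fold,
                 train_minutes = train_minutes, seed = seed,
                 per_fold = per_fold,
                 pooled = error_report(truth_all, pred_all),
                 hyper = hyper, truth = truth_all, pred = pred_all),
            class = "arrangement_run")
}

#' @export
print.arrangement_run <- function(x, ...) {
  cat(sprintf("<arrangement_run> %s, %d folds, %g min training\n",
              x$arrangement, length(x$per_fold), x$train_minutes))
  cat("pooled errors:\n")
  print(x$pooled)
  invisible(x)
}

#' Compare arrangements on identical folds
#'
#' Runs each requested arrangement with the same dataset, fold assignment
#' and seeds, and tabulates the pooled error rates.
#'
#' @inheritParams run_arrangement
#' @param arrangements Character vector of arrangements to run.
#' @return An `arrangement_comparison`: list of `arrangement_run`s plus a
#'   `table` data frame (one row per arrangement, six error columns).
#' @export
compare_arrangements <- function(dataset,
                                 arrangements = c("BD_LC_GS", "LC_BDGS",
                                                  "LCGS_BDGS"),
                                 train_minutes = 2, folds = 3L, seed = 1L,
                                 config = train_config(),
                                 score_mode = c("dense", "fast"),
                                 verbose = FALSE, ...) {
  score_mode <- match.arg(score_mode)
  runs <- lapply(arrangements, function(a)
    run_arrangement(dataset, a, train_minutes = train_minutes, folds = folds,
                    seed = seed, config = config, score_mode = score_mode,
                    verbose = verbose, ...))
  names(runs) <- arrangements
  structure(list(runs = runs, table = comparison_table(runs)),
            class = "arrangement_comparison")
}

## One row of pooled error rates per named arrangement run.
comparison_table <- function(runs) {
  tab <- do.call(rbind, lapply(runs, function(r) as.data.frame(r$pooled)))
  cbind(arrangement = names(runs), tab, row.names = NULL)
}

#' @export
print.arrangement_comparison <- function(x, ...) {
  cat("<arrangement_comparison>\n")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], function(v) sprintf("%.2f%%", 100 * v))
  print(tab, row.names = FALSE)
  invisible(x)
}
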