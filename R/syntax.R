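#' Fit a second-order Markov syntax model with additive smoothing
#'
#' Song syntax is modelled as a second-order Markov chain over note classes:
#' the probability of note class Z depends on the two preceding classes
#' (X, Y). Empirical conditional frequencies `P0(Z|XY)` are smoothed by
#' adding a constant before renormalizing:
#' `P(Z|XY) = (P0(Z|XY) + alpha) / sum_Z'(P0(Z'|XY) + alpha)`.
#' Contexts never observed in training, and the initial-state contexts
#' (first and second note of a sequence), are uniform over the `n` classes.
#'
#' @param label_sequences A list of character vectors of note labels (or
#'   `song_annotation`s, whose label sequences are used).
#' @param alpha Smoothing constant, `>= 0`.
#' @param classes Optional class alphabet; defaults to the sorted labels seen.
#' @return A `syntax_model` with elements `classes`, `alpha` and `trans`, an
#'   `n x n x n` array indexed `[X, Y, Z]`.
#' @examples
#' m <- fit_syntax_model(list(c("A","A","B","A","A","B")), alpha = 0.5)
#' m$trans["A", "A", "B"]  # 0.75
#' @export
fit_syntax_model <- function(label_sequences, alpha = 0, classes = NULL) {
  stopifnot(alpha >= 0)
  seqs <- as_label_seqs(label_sequences)
  labs <- unlist(seqs)
  if (is.null(classes)) classes <- sort(unique(labs))
  if (length(bad <- setdiff(labs, classes)))
    stop("unknown-class: ", paste(bad, collapse = ", "))
  n <- length(classes)
  counts <- array(0, dim = c(n, n, n), dimnames = list(classes, classes, classes))
  for (s in seqs) {
    idx <- match(s, classes)
    if (length(idx) >= 3L)
      for (t in 3:length(idx))
        counts[idx[t - 2L], idx[t - 1L], idx[t]] <-
          counts[idx[t - 2L], idx[t - 1L], idx[t]] + 1
  }
  trans <- array(1 / n, dim = dim(counts), dimnames = dimnames(counts))
  for (x in seq_len(n)) for (y in seq_len(n)) {
    tot <- sum(counts[x, y, ])
    if (tot > 0) {
      p0 <- counts[x, y, ] / tot
      trans[x, y, ] <- (p0 + alpha) / (1 + n * alpha)
    }
  }
  structure(list(classes = classes, alpha = alpha, trans = trans,
                 counts = counts),
            class = "syntax_model")
}

#' @export
print.syntax_model <- function(x, ...) {
  cat(sprintf("<syntax_model> %d classes, alpha = %g\n",
              length(x$classes), x$alpha))
  invisible(x)
}

#' Simulate note sequences from a syntax model
#'
#' The first and second notes are drawn uniformly (the initial-state
#' convention of the model); later notes follow `P(Z|XY)`.
#'
#' @param object A `syntax_model`.
#' @param nsim Number of sequences.
#' @param seed Optional seed, applied locally.
#' @param lengths Integer vector (recycled) of sequence lengths, or a range
#'   `c(min, max)` to sample from when `sample_lengths = TRUE`.
#' @param sample_lengths Sample each length uniformly from `lengths`.
#' @param ... Unused.
#' @return A list of character label vectors.
#' @export
simulate.syntax_model <- function(object, nsim = 1, seed = NULL,
                                  lengths = c(8L, 15L),
                                  sample_lengths = TRUE, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- length(object$classes)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    len <- if (sample_lengths) sample(lengths[1]:lengths[2], 1L)
           else lengths[(k - 1L) %% length(lengths) + 1L]
    idx <- integer(len)
    for (t in seq_len(len)) {
      p <- if (t <= 2L) rep(1 / n, n)
           else object$trans[idx[t - 2L], idx[t - 1L], ]
      idx[t] <- sample.int(n, 1L, prob = p)
    }
    out[[k]] <- object$classes[idx]
  }
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  code
}

#' Serialize a syntax model to a plain-text table
#'
#' One line per (X, Y, Z) triple: context labels, successor label,
#' probability, tab-separated with a header.
#'
#' @param model A `syntax_model`.
#' @param path File path.
#' @export
write_syntax_model <- function(model, path) {
  g <- expand.grid(X = model$classes, Y = model$classes, Z = model$classes,
                   stringsAsFactors = FALSE)
  g$prob <- mapply(function(x, y, z) model$trans[x, y, z], g$X, g$Y, g$Z)
  utils::write.table(cbind(g, alpha = model$alpha), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_syntax_model
#' @export
read_syntax_model <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "character", "numeric", "numeric"))
  classes <- sort(unique(tab$X))
  n <- length(classes)
  trans <- array(NA_real_, dim = c(n, n, n),
                 dimnames = list(classes, classes, classes))
  trans[cbind(tab$X, tab$Y, tab$Z)] <- tab$prob
  structure(list(classes = classes, alpha = tab$alpha[1L], trans = trans,
                 counts = NULL),
            class = "syntax_model")
}

#' Build the sub-state HMM for joint boundary detection and sequencing
#'
#' Every syntax context (X, Y) becomes four left-to-right connected hidden
#' states: three emitting the beginning/middle/end thirds of note Y and a
#' fourth emitting the silence after it. Self/advance probabilities of the
#' first two sub-states are 0.5 each; from the third sub-state the chain
#' stays, moves to silence (`1/(n+2)` each) or starts the next note
#' (`n/(n+2) * P(Z|XY)`); from the silence sub-state it stays (`1/(n+1)`) or
#' starts the next note (`n/(n+1) * P(Z|XY)`). Contexts whose first element
#' is the initial state `e` use uniform successor probabilities, and an extra
#' silence-emitting start state `(e,e)` precedes the first note. Transitions
#' from later sub-states back to earlier ones do not exist (structural
#' zeros), which is what lets the decoder place note boundaries.
#'
#' @param model A `syntax_model`.
#' @return A `substate_hmm`: list with `states` (data frame: `ctx_x`,
#'   `ctx_y`, `sub` in `1:3` or `"s"`), `emit` (1-based row of the emission
#'   table each state emits: `3*(class-1)+sub` for note parts, `3n+1` for
#'   silence), `edges` (matrix from,to), `edge_logp`, and `init_log`.
#' @export
build_substate_hmm <- function(model) {
  classes <- model$classes
  n <- length(classes)
  e0 <- ".e"  # reserved initial-state symbol (cannot collide with labels)
  if (e0 %in% classes) stop("invalid-config: class label '.e' is reserved")
  states <- data.frame(
    ctx_x = c(e0, rep(c(e0, classes), each = 4L * n)),
    ctx_y = c(e0, rep(rep(classes, each = 4L), times = n + 1L)),
    sub = c("s", rep(c("1", "2", "3", "s"), times = n * (n + 1L))),
    stringsAsFactors = FALSE)
  S <- nrow(states)
  sid <- function(x, y, sub)
    which(states$ctx_x == x & states$ctx_y == y & states$sub == sub)
  emit <- ifelse(states$sub == "s", 3L * n + 1L,
                 3L * (match(states$ctx_y, classes) - 1L) +
                   as.integer(ifelse(states$sub == "s", 1L, states$sub)))
  emit[1L] <- 3L * n + 1L

  from <- integer(0); to <- integer(0); p <- numeric(0)
  add <- function(f, t, pr) {
    from <<- c(from, f); to <<- c(to, t); p <<- c(p, pr)
  }
  first_sub <- function(y, z) sid(y, z, "1")
  ## start state (e,e): silence, then first note with uniform class
  add(1L, 1L, 1 / (n + 1))
  for (z in classes) add(1L, sid(e0, z, "1"), 1 / (n + 1))
  for (x in c(e0, classes)) for (y in classes) {
    s1 <- sid(x, y, "1"); s2 <- sid(x, y, "2")
    s3 <- sid(x, y, "3"); ss <- sid(x, y, "s")
    add(s1, s1, 0.5); add(s1, s2, 0.5)
    add(s2, s2, 0.5); add(s2, s3, 0.5)
    pz <- if (x == e0) rep(1 / n, n) else model$trans[x, y, ]
    add(s3, s3, 1 / (n + 2)); add(s3, ss, 1 / (n + 2))
    for (zi in seq_len(n))
      add(s3, first_sub(y, classes[zi]), n / (n + 2) * pz[zi])
    add(ss, ss, 1 / (n + 1))
    for (zi in seq_len(n))
      add(ss, first_sub(y, classes[zi]), n / (n + 1) * pz[zi])
  }
  ## decoding may begin in leading silence or directly in a first note
  init <- rep(-Inf, S)
  init[c(1L, vapply(classes, function(z) sid(e0, z, "1"), 0L))] <-
    -log(n + 1)
  structure(list(classes = classes, states = states, emit = emit,
                 edges = cbind(from = from, to = to), edge_logp = log(p),
                 init_log = init),
            class = "substate_hmm")
}

#' @export
print.substate_hmm <- function(x, ...) {
  cat(sprintf("<substate_hmm> %d states (%d classes x 4 sub-states + start), %d transitions\n",
              nrow(x$states), length(x$classes), nrow(x$edges)))
  invisible(x)
}

## Dense transition matrix (linear probabilities); mostly for tests.
transition_matrix <- function(hmm) {
  S <- nrow(hmm$states)
  M <- matrix(0, S, S)
  M[hmm$edges] <- exp(hmm$edge_logp)
  rn <- paste0(hmm$states$ctx_x, hmm$states$ctx_y, "_", hmm$states$sub)
  dimnames(M) <- list(rn, rn)
  M
}

#' Convert classifier posteriors to scaled emission scores
#'
#' The network outputs are posterior probabilities `P(class | spectrogram)`.
#' For decoding they may be converted to (unnormalized) emission likelihoods
#' by Bayes' rule, dividing each class row by its prior `P(class)`. Whether
#' the conversion helps is data-dependent, so the pipeline chooses it by
#' cross-validation within the training data.
#'
#' @param scores Score matrix (classes x frames, or classes x intervals).
#' @param priors Strictly positive prior vector, one per class row.
#' @param enabled If `FALSE` the scores are returned unchanged.
#' @return A matrix shaped like `scores`.
#' @export
convert_posterior_to_emission <- function(scores, priors, enabled = TRUE) {
  if (!enabled) return(scores)
  if (length(priors) != nrow(scores))
    stop("degenerate-prior: need one prior per class row")
  if (any(priors <= 0)) stop("degenerate-prior: priors must be positive")
  scores / priors
}
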