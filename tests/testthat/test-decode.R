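test_that("interval decoding equals per-interval argmax under uniform syntax", {
  uni <- fit_syntax_model(list(), alpha = 1, classes = c("A", "B"))
  sc <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8))
  expect_equal(as.character(decode_interval_sequence(uni, sc)),
               c("A", "B", "B"))
  expect_length(decode_interval_sequence(uni, NULL), 0)
})

test_that("interval decoder matches exhaustive enumeration", {
  set.seed(50)
  for (k in 1:12) {
    n <- sample(2:3, 1); TT <- sample(2:6, 1)
    syn <- fit_syntax_model(simulate(fit_syntax_model(list(), alpha = 1,
                                                      classes = letters[1:n]),
                                     nsim = 6, seed = k, lengths = c(6L, 9L)),
                            alpha = 0.2)
    sc <- matrix(stats::runif(TT * n, 0.05, 1), TT, n)
    sc <- sc / rowSums(sc)
    got <- decode_interval_sequence(syn, sc)
    oracle <- brute_interval_decode(syn, sc)
    expect_equal(attr(got, "logp"), oracle$logp, tolerance = 1e-9)
    expect_equal(as.character(got), oracle$labels)
  }
})

test_that("syntax information can override the local argmax", {
  ## syntax that never produces B after (a, a); emissions mildly favour B
  syn <- fit_syntax_model(list(rep(c("a", "a"), 8)), alpha = 0.01,
                          classes = c("a", "b"))
  sc <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.45, 0.55))
  got <- decode_interval_sequence(syn, sc)
  expect_equal(as.character(got), c("a", "a", "a"))
  oracle <- brute_interval_decode(syn, sc)
  expect_equal(as.character(got), oracle$labels)
  ## with stronger emission evidence the local class wins
  sc2 <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.02, 0.98))
  expect_equal(as.character(decode_interval_sequence(syn, sc2))[3], "b")
})

test_that("frame decoder matches exhaustive enumeration on small instances", {
  set.seed(51)
  syn <- fit_syntax_model(list(c("a", "b", "a", "b")), alpha = 0.3)
  hmm <- build_substate_hmm(syn)
  for (k in 1:3) {
    TT <- 5
    em <- matrix(stats::runif(7 * TT, 0.05, 1), 7, TT)
    path <- decode_frame_sequence(hmm, em)
    oracle <- brute_frame_decode(hmm, em)
    expect_equal(attr(path, "logp"), oracle$logp, tolerance = 1e-9)
    expect_equal(unclass(path), oracle$path, ignore_attr = TRUE)
  }
})

test_that("frame decoder agrees with an independent max-product DP on larger runs", {
  set.seed(52)
  syn <- fit_syntax_model(simulate(fit_syntax_model(list(), alpha = 1,
                                                    classes = letters[1:3]),
                                   nsim = 8, seed = 3), alpha = 0.1)
  hmm <- build_substate_hmm(syn)
  em <- matrix(stats::runif(10 * 40, 0.02, 1), 10, 40)
  path <- decode_frame_sequence(hmm, em)
  M <- songscribe:::transition_matrix(hmm); lM <- log(M); lem <- log(em)
  d <- hmm$init_log + lem[hmm$emit, 1]
  for (t in 2:40) d <- apply(d + lM, 2, max) + lem[hmm$emit, t]
  expect_equal(attr(path, "logp"), max(d), tolerance = 1e-9)
  ## every consecutive pair of the path is a permitted transition
  key <- paste(hmm$edges[, 1], hmm$edges[, 2])
  expect_true(all(paste(path[-40], path[-1]) %in% key))
})

test_that("one-hot emissions reproduce their legal path", {
  syn <- fit_syntax_model(list(c("a", "b", "a")), alpha = 0.5)
  hmm <- build_substate_hmm(syn)
  sid <- function(x, y, s)
    which(hmm$states$ctx_x == x & hmm$states$ctx_y == y & hmm$states$sub == s)
  want <- c(1, sid(".e", "a", "1"), sid(".e", "a", "2"), sid(".e", "a", "3"),
            sid(".e", "a", "s"), sid("a", "b", "1"), sid("a", "b", "2"),
            sid("a", "b", "3"))
  em <- matrix(1e-6, 7, length(want))
  for (t in seq_along(want)) em[hmm$emit[want[t]], t] <- 1
  path <- decode_frame_sequence(hmm, em)
  expect_equal(unclass(path), want, ignore_attr = TRUE)
})

test_that("state paths convert to annotations by the onset/offset rules", {
  syn <- fit_syntax_model(list(c("A", "A", "A")), alpha = 1, classes = "A")
  ## a single-class sub-state machine is enough to express the rule examples
  hmm <- build_substate_hmm(syn)
  sid <- function(x, y, s)
    which(hmm$states$ctx_x == x & hmm$states$ctx_y == y & hmm$states$sub == s)
  fake_path <- function(states)
    structure(states, logp = 0, hmm = hmm, class = "state_path")
  a1 <- sid(".e", "A", "1"); a2 <- sid(".e", "A", "2")
  a3 <- sid(".e", "A", "3"); as_ <- sid(".e", "A", "s")
  b1 <- sid("A", "A", "1"); b2 <- sid("A", "A", "2"); b3 <- sid("A", "A", "3")
  ## silence, one note, silence -> A on [2, 7)
  ann <- path_to_annotation(fake_path(c(1, 1, a1, a1, a2, a3, a3, as_)),
                            validate = FALSE)
  expect_equal(ann$onset, 2); expect_equal(ann$offset, 7)
  expect_equal(ann$label, "A")
  ## immediate repetition: boundary exactly at the 3 -> 1 transition
  ann2 <- path_to_annotation(fake_path(c(a1, a2, a3, b1, b2, b3)),
                             validate = FALSE)
  expect_equal(ann2$onset, c(0, 3))
  expect_equal(ann2$offset, c(3, 6))
  ## all silence
  expect_equal(nrow(path_to_annotation(fake_path(c(1, 1, 1)),
                                       validate = FALSE)), 0)
  ## malformed paths are rejected when validation is on
  expect_error(path_to_annotation(fake_path(c(a2, a1))), "invalid-path")
})

test_that("left-to-right constraints forbid boundaries without a full sub-state pass", {
  ## strong sub-division-1 evidence in mid-note cannot split the note,
  ## because 2 -> 1 transitions do not exist
  syn <- fit_syntax_model(list(rep("A", 6)), alpha = 1, classes = c("A", "B"))
  hmm <- build_substate_hmm(syn)
  em <- matrix(1e-4, 7, 9)
  em[1, c(1, 2, 5)] <- 1    # A sub-1 evidence, again mid-note at frame 5
  em[2, 3:4] <- 1           # A sub-2
  em[2, 6] <- 1
  em[3, 7:8] <- 1           # A sub-3
  em[7, 9] <- 1             # silence
  ann <- path_to_annotation(decode_frame_sequence(hmm, em), validate = FALSE)
  expect_equal(nrow(ann), 1L)   # one note despite the burst at frame 5
  ## structural minimum duration: every decoded note spans >= 3 frames
  set.seed(53)
  for (k in 1:5) {
    emr <- matrix(stats::runif(7 * 30, 0.01, 1), 7, 30)
    annr <- path_to_annotation(decode_frame_sequence(hmm, emr),
                               validate = FALSE)
    if (nrow(annr)) expect_gte(min(annr$offset - annr$onset), 3)
  }
})
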