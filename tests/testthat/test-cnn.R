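test_that("architectures compose to 1x1 with the documented filter widths", {
  a1 <- build_architecture("BD_LC_GS", 8)
  expect_equal(a1$n_outputs, 8L)
  expect_equal(a1$input_width, 96L)
  tr <- shape_trace(a1)
  ## spatial sizes through the stack of the 112x96 window
  sub <- tr[tr$kind != "input", ][c(1, 3, 4, 6, 7, 9, 10), ]
  expect_equal(sub$h, c(108, 54, 50, 25, 22, 11, 1))
  expect_equal(sub$w, c(92, 46, 42, 21, 18, 9, 1))
  expect_equal(a1$layers[[10]]$w, 9L)   # fourth convolutional layer
  expect_equal(a1$layers[[10]]$h, 11L)
  expect_equal(a1$layers[[10]]$c_out, 240L)

  a2 <- build_architecture("LC_BDGS", 8)
  expect_equal(a2$n_outputs, 25L)       # 3n + 1

  a3 <- build_architecture("LCGS_BDGS", 8)
  expect_equal(a3$input_width, 288L)
  expect_equal(a3$n_outputs, 25L)
  expect_equal(a3$layers[[11]]$w, 25L)  # inserted layer
  tr3 <- shape_trace(a3)
  expect_equal(unlist(tr3[nrow(tr3), c("h", "w")]), c(h = 1L, w = 1L))
  ## the fourth layer emits 25 frames on the wide window
  expect_equal(tr3$w[tr3$layer == 10], 25)

  expect_error(build_architecture("NOPE", 8), "unknown-arrangement")
  expect_equal(receptive_field_ms(96), 111)
  expect_equal(receptive_field_ms(288), 303)
})

test_that("frame labels split notes into floor-divided thirds", {
  cls <- c("A", "B")
  ann <- song_annotation(10, 22, "A", 30)
  lab <- derive_frame_labels(ann, "LC_BDGS", cls)
  expect_equal(lab[11:14], rep(1L, 4))   # frames 10..13: sub-division 1
  expect_equal(lab[15:18], rep(2L, 4))
  expect_equal(lab[19:22], rep(3L, 4))
  expect_equal(lab[1:10], rep(7L, 10))   # silence class 3n+1
  ## 11-frame note: splits at floor(11/3)=3 and floor(22/3)=7
  lab2 <- derive_frame_labels(song_annotation(0, 11, "B", 11), "LC_BDGS", cls)
  expect_equal(lab2, c(rep(4L, 3), rep(5L, 4), rep(6L, 4)))
  ## BD arrangement: class labels inside notes, untrainable 0 outside
  lab3 <- derive_frame_labels(ann, "BD_LC_GS", cls)
  expect_equal(unique(lab3[11:22]), 1L)
  expect_equal(unique(lab3[-(11:22)]), 0L)
  ## all silence
  expect_equal(unique(derive_frame_labels(song_annotation(timeline = 20),
                                          "LC_BDGS", cls)), 7L)
})

test_that("He initialization has the stated scale and is seed-deterministic", {
  arch <- build_architecture("BD_LC_GS", 4)
  p1 <- initialize_parameters(arch, 7)
  p2 <- initialize_parameters(arch, 7)
  expect_identical(p1, p2)
  p3 <- initialize_parameters(arch, 8)
  expect_false(identical(p1, p3))
  ## first conv: fan-in 25, sigma = sqrt(2/25)
  expect_equal(stats::sd(p1[[1]]$W), sqrt(2 / 25), tolerance = 0.05 * sqrt(2/25))
  expect_true(all(vapply(p1, function(l)
    is.null(l) || all(l$b == 0), TRUE)))
  ## conv4: fan-in 16*11*9
  expect_equal(stats::sd(p1[[10]]$W), sqrt(2 / (16 * 11 * 9)), tolerance = 0.02)
})

test_that("analytic gradients match central finite differences", {
  layers <- songscribe:::annotate_c_in(list(
    list(kind = "conv", h = 3, w = 3, c_out = 2, activation = "relu"),
    list(kind = "maxpool"),
    list(kind = "conv", h = 3, w = 3, c_out = 3, activation = "softmax")))
  set.seed(42)
  params <- lapply(layers, function(l) {
    if (l$kind == "maxpool") return(NULL)
    fan <- l$c_in * l$h * l$w
    list(W = matrix(stats::rnorm(l$c_out * fan, sd = 0.5), nrow = l$c_out),
         b = stats::rnorm(l$c_out, sd = 0.1))
  })
  x <- matrix(stats::rnorm(64), 8, 8)
  g <- songscribe:::cpp_cnn_grad(layers, params, x, 2L,
                                 double_precision = TRUE)
  for (i in c(1, 3)) {
    for (wi in seq_along(params[[i]]$W)) {
      eps <- 1e-5
      pp <- params; pp[[i]]$W[wi] <- pp[[i]]$W[wi] + eps
      lp <- songscribe:::cpp_cnn_grad(layers, pp, x, 2L, TRUE)$loss
      pp[[i]]$W[wi] <- pp[[i]]$W[wi] - 2 * eps
      lm <- songscribe:::cpp_cnn_grad(layers, pp, x, 2L, TRUE)$loss
      fd <- (lp - lm) / (2 * eps)
      if (abs(fd) > 1e-5)
        expect_lt(abs(g$grads[[i]]$dW[wi] - fd) / abs(fd), 1e-4)
    }
    ## bias gradients too
    for (bi in seq_along(params[[i]]$b)) {
      eps <- 1e-5
      pp <- params; pp[[i]]$b[bi] <- pp[[i]]$b[bi] + eps
      lp <- songscribe:::cpp_cnn_grad(layers, pp, x, 2L, TRUE)$loss
      pp[[i]]$b[bi] <- pp[[i]]$b[bi] - 2 * eps
      lm <- songscribe:::cpp_cnn_grad(layers, pp, x, 2L, TRUE)$loss
      fd <- (lp - lm) / (2 * eps)
      if (abs(fd) > 1e-5)
        expect_lt(abs(g$grads[[i]]$db[bi] - fd) / abs(fd), 1e-4)
    }
  }
})

test_that("frame scores are dense, normalized and translation consistent", {
  arch <- build_architecture("BD_LC_GS", 3)
  params <- initialize_parameters(arch, 1)
  ens <- structure(list(arch = arch,
                        members = list(params,
                                       initialize_parameters(arch, 2),
                                       initialize_parameters(arch, 3))),
                   class = "classifier_ensemble")
  spec <- matrix(stats::rnorm(112 * 150), 112, 150)
  for (mode in c("fast", "dense")) {
    s <- predict_frame_scores(ens, spec, mode = mode)
    expect_equal(dim(s), c(3L, 150L))
    expect_true(all(abs(colSums(s) - 1) < 1e-6))
    expect_true(all(s >= 0 & s <= 1))
  }
  ## fast and dense agree exactly at the stride-8 phase-0 frames
  sf <- predict_frame_scores(ens, spec, mode = "fast")
  sd_ <- predict_frame_scores(ens, spec, mode = "dense")
  expect_equal(sf[, seq(1, 150, by = 8)], sd_[, seq(1, 150, by = 8)],
               tolerance = 1e-6)
  ## constant input gives constant interior columns (reflect padding can
  ## only affect frames within half a window of the edges)
  const <- matrix(1, 112, 150)
  sc <- predict_frame_scores(ens, const, mode = "dense")
  interior <- sc[, 49:102]
  expect_lt(max(abs(interior - interior[, 1])), 1e-6)
  ## too-short input
  expect_error(predict_frame_scores(ens, matrix(0, 112, 30)),
               "input-too-short")
})

test_that("a trained sub-division classifier clearly beats the majority class", {
  ds <- generate_dataset(generator_config(classes = default_note_classes(3),
                                          total_minutes = 0.6,
                                          noise_snr_db = 35, seed = 9))
  raw <- lapply(ds, function(s) compute_spectrogram(s$wave))
  st <- fit_normalization(raw)
  specs <- lapply(raw, apply_normalization, stats = st)
  cls <- sort(vapply(attr(ds, "config")$classes, `[[`, "", "label"))
  arch <- build_architecture("LC_BDGS", 3)
  labs <- mapply(function(s, sp)
    derive_frame_labels(annotation_to_frame_grid(s$annotation, ncol(sp)),
                        "LC_BDGS", cls, ncol(sp)),
    ds, specs, SIMPLIFY = FALSE)
  cfg <- train_config(lr_candidates = 0.02, seeds_per_rate = 1,
                      probe_iters = 2, halvings = 1, patience = 1,
                      eval_every = 6, batch_s = 2, max_iters = 36,
                      eval_budget_s = 2, seed = 5)
  ens <- train_ensemble(specs, labs, arch, cfg, normalization = st,
                        classes = cls)
  prep <- mapply(function(sp, lb) songscribe:::prep_train_seq(sp, lb, arch),
                 specs, labs, SIMPLIFY = FALSE)
  acc <- 1 - songscribe:::strided_error(arch, ens$members[[1]], prep)
  baseline <- max(table(unlist(labs))) / length(unlist(labs))
  expect_gte(acc, baseline + 0.30)
})

test_that("training separates disjoint-band classes and is deterministic", {
  ## two classes with non-overlapping spectra; BD arrangement (class labels
  ## only inside notes) on a tiny corpus
  ds <- memo("cnn_sep_ds", generate_dataset(generator_config(
    classes = list(note_class_spec("lo", 1400, 1, 0, c(60, 100)),
                   note_class_spec("hi", 5200, 1, 0, c(60, 100))),
    syntax = NULL, total_minutes = 0.35, noise_snr_db = 35, seed = 9)))
  raw <- lapply(ds, function(s) compute_spectrogram(s$wave))
  st <- fit_normalization(raw)
  specs <- lapply(raw, apply_normalization, stats = st)
  arch <- build_architecture("BD_LC_GS", 2)
  labs <- mapply(function(s, sp)
    derive_frame_labels(annotation_to_frame_grid(s$annotation, ncol(sp)),
                        "BD_LC_GS", c("hi", "lo"), ncol(sp)),
    ds, specs, SIMPLIFY = FALSE)
  cfg <- train_config(lr_candidates = 0.02, seeds_per_rate = 1,
                      probe_iters = 2, halvings = 1, patience = 1,
                      eval_every = 5, batch_s = 2, max_iters = 25,
                      eval_budget_s = 2, seed = 5)
  ens <- train_ensemble(specs, labs, arch, cfg, normalization = st,
                        classes = c("hi", "lo"))
  expect_length(ens$members, 3L)
  prepped <- mapply(function(sp, lb) songscribe:::prep_train_seq(sp, lb, arch),
                    specs, labs, SIMPLIFY = FALSE)
  err <- songscribe:::strided_error(arch, ens$members[[1]], prepped)
  expect_lt(err, 0.01)
  ## determinism: identical config and data give identical members
  ens2 <- train_ensemble(specs, labs, arch, cfg, normalization = st,
                         classes = c("hi", "lo"))
  expect_identical(ens$members, ens2$members)
  expect_error(train_ensemble(specs[1:4], labs[1:4], arch, cfg),
               "too-few-sequences")
})
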