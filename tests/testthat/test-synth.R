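test_that("dataset generation is deterministic and annotations are exact", {
  cfg <- generator_config(classes = default_note_classes(3),
                          total_minutes = 0.15, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(lapply(d1, `[[`, "wave"), lapply(d2, `[[`, "wave"))
  expect_identical(lapply(d1, `[[`, "annotation"),
                   lapply(d2, `[[`, "annotation"))
  d3 <- generate_dataset(generator_config(classes = default_note_classes(3),
                                          total_minutes = 0.15, seed = 43))
  expect_false(identical(d1[[1]]$wave, d3[[1]]$wave))
  for (s in d1) {
    ann <- s$annotation
    expect_true(all(ann$onset < ann$offset))
    expect_true(all(ann$onset[-1] >= ann$offset[-nrow(ann)]))
    expect_lte(max(ann$offset), annotation_timeline(ann))
    expect_equal(length(s$wave), annotation_timeline(ann) * 32)
  }
})

test_that("generated note statistics follow the class specifications", {
  classes <- default_note_classes(4)
  ds <- memo("synth_stats_ds", generate_dataset(generator_config(
    classes = classes, total_minutes = 0.4, seed = 7)))
  anns <- lapply(ds, `[[`, "annotation")
  durs <- unlist(lapply(anns, note_durations))
  labs <- unlist(lapply(anns, annotation_labels))
  for (cl in classes) {
    d <- durs[labs == cl$label]
    expect_gte(min(d), cl$dur_range[1])
    expect_lte(max(d), cl$dur_range[2])
  }
  ## note durations stay in the songbird-note range
  expect_true(all(durs >= 30 & durs <= 200))
  ## SNR: in-note RMS well above background RMS
  s <- ds[[1]]
  ann <- s$annotation
  note_idx <- unlist(mapply(function(a, b) (a * 32 + 1):(b * 32),
                            ann$onset, ann$offset))
  expect_gt(sqrt(mean(s$wave[note_idx]^2)) /
              sqrt(mean(s$wave[-note_idx]^2)), 10)
})

test_that("generated sequences reproduce the configured second-order syntax", {
  cfg <- generator_config(classes = default_note_classes(4),
                          total_minutes = 2.4, seed = 31)
  ds <- memo("synth_syntax_ds", generate_dataset(cfg))
  seqs <- lapply(ds, function(s) annotation_labels(s$annotation))
  expect_gte(sum(lengths(seqs)), 800)
  est <- fit_syntax_model(seqs, alpha = 0, classes = cfg$syntax$classes)
  seen <- apply(est$counts, c(1, 2), sum) >= 60
  err <- abs(est$trans - cfg$syntax$trans)
  expect_gt(sum(seen), 0)
  for (x in seq_len(4)) for (y in seq_len(4))
    if (seen[x, y]) expect_lt(max(err[x, y, ]), 0.08)
})

test_that("song extraction applies the segmentation rules", {
  mk <- function(labels, gaps = 50) {
    n <- length(labels)
    on <- cumsum(c(100, rep(80 + gaps, n - 1)))
    song_annotation(on, on + 80, labels, max(on) + 200)
  }
  ## 20-note run splits greedily into 15 + 5
  out <- extract_songs(mk(rep(c("a", "b"), 10)))
  expect_equal(lengths(lapply(out, annotation_labels)), c(15, 5))
  ## an unclassifiable note splits an 8-note run into 3 + 4, both kept
  out2 <- extract_songs(mk(c("a", "b", "a", ".unk", "b", "a", "b", "a")))
  expect_equal(lengths(lapply(out2, annotation_labels)), c(3, 4))
  expect_false(any(unlist(lapply(out2, annotation_labels)) == ".unk"))
  ## runs of <= 7 notes are not songs
  expect_length(extract_songs(mk(rep("a", 7))), 0)
  expect_length(extract_songs(mk(rep("a", 8))), 1)
  ## gaps of >= 300 ms split runs; a call splits runs
  long_gap <- mk(rep("a", 16), gaps = 310)
  expect_length(extract_songs(long_gap), 0)   # all runs are single notes
  with_call <- mk(c(rep("a", 8), ".call", rep("b", 8)))
  out3 <- extract_songs(with_call)
  expect_equal(lengths(lapply(out3, annotation_labels)), c(8, 8))
  expect_false(any(unlist(lapply(out3, annotation_labels)) == ".call"))
  ## rare classes (< 1% of notes) become unclassifiable and split songs
  many <- mk(c(rep("a", 60), "z", rep("a", 60)), gaps = 20)
  out4 <- extract_songs(many)
  expect_false(any(unlist(lapply(out4, annotation_labels)) == "z"))
  ## idempotence on outputs that satisfy the song criterion
  for (fr in out3) {
    again <- extract_songs(fr)
    expect_length(again, 1)
    expect_equal(annotation_labels(again[[1]]), annotation_labels(fr))
  }
})

test_that("fold splitting is balanced, exhaustive and seed-deterministic", {
  f <- split_folds(30, k = 3, seed = 2)
  expect_equal(sort(unique(f)), 1:3)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_identical(f, split_folds(30, k = 3, seed = 2))
  expect_false(identical(f, split_folds(30, k = 3, seed = 3)))
  expect_equal(split_folds(5, k = 1, seed = 1), rep(1L, 5))
  expect_error(split_folds(2, k = 3), "too-few-sequences")
})

test_that("training subsets reach the duration budget minimally", {
  durs <- rep(6000, 25)  # 6-s sequences
  idx <- select_training_subset(NULL, minutes = 0.5, seed = 4,
                                durations_ms = durs)
  expect_equal(length(idx), 5)  # 30 s / 6 s
  expect_identical(idx, select_training_subset(NULL, 0.5, 4,
                                               durations_ms = durs))
  ## full duration: everything
  expect_length(select_training_subset(NULL, 2.5, 1, durations_ms = durs), 25)
  expect_error(select_training_subset(NULL, 3, 1, durations_ms = durs),
               "insufficient-duration")
  ## duration in [budget, budget + longest)
  set.seed(11)
  durs2 <- sample(1000:8000, 40)
  idx2 <- select_training_subset(NULL, 0.4, 9, durations_ms = durs2)
  tot <- sum(durs2[idx2])
  expect_gte(tot, 24000)
  expect_lt(tot, 24000 + max(durs2))
})

test_that("WAV and label files round-trip through disk", {
  dir <- tempfile(); dir.create(dir)
  wav <- file.path(dir, "a.wav"); lab <- file.path(dir, "a.txt")
  set.seed(12)
  x <- stats::runif(3200, -0.8, 0.8)
  write_wav(x, wav, 32000)
  back <- read_wav(wav)
  expect_equal(attr(back, "sample_rate"), 32000)
  expect_lt(max(abs(as.numeric(back) - x)), 2^-15)  # 16-bit quantization
  ann <- song_annotation(c(10, 60), c(40, 95), c("a", "b"), 100)
  write_labels(ann, lab)
  back_ann <- read_labels(lab, timeline_s = 0.1)
  expect_equal(back_ann$onset, ann$onset)
  expect_equal(back_ann$offset, ann$offset)
  expect_equal(back_ann$label, ann$label)
})
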