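test_that("spectrogram has 112 band rows and the expected tone row", {
  p <- spectrogram_params()
  x <- sin(2 * pi * 4000 * (0:31999) / 32000)
  sp <- compute_spectrogram(x, p)
  expect_equal(nrow(sp), 112L)
  expect_equal(ncol(sp), (32000 - 512) %/% 32 + 1)
  expect_true(all(is.finite(sp)))
  ## 4 kHz sits 48 rows above the 1 kHz row (62.5 Hz bin spacing)
  expect_equal(unname(which.max(rowMeans(sp))) - 1L, 48L)
  ## independent oracle: direct DFT magnitude of one tapered frame
  tap <- dpss_taper(512, 4 / 512)
  frame <- x[1:512] * tap
  k <- 0:511
  dft_mag <- vapply(16:127, function(bin)
    Mod(sum(frame * exp(-2i * pi * bin * k / 512))), 0)
  expect_equal(unclass(sp[, 1]), log(pmax(dft_mag, p$log_floor)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("row count follows the band edges", {
  p <- spectrogram_params(band_low = 2000, band_high = 6000)
  sp <- compute_spectrogram(sin(2 * pi * 3000 * (0:16383) / 32000), p)
  expect_equal(nrow(sp), (6000 - 2000) / (32000 / 512))
})

test_that("degenerate inputs are handled per contract", {
  z <- compute_spectrogram(rep(0, 2048))
  expect_true(all(z == log(1e-10)))
  expect_error(compute_spectrogram(rep(0, 100)), "insufficient-input")
  expect_error(compute_spectrogram(c(rep(0, 600), NA)), "invalid-input")
})

test_that("DPSS taper is unit-energy, symmetric and spectrally concentrated", {
  v <- dpss_taper(512, 4 / 512)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  expect_equal(v, rev(v), tolerance = 1e-9)
  conc <- function(w) {
    ## fraction of spectral energy inside |f| <= W, on a fine frequency grid
    f <- seq(-0.5, 0.5, length.out = 4096)
    H <- abs(vapply(f, function(fr) sum(w * exp(-2i * pi * fr * (0:511))), 0+0i))^2
    sum(H[abs(f) <= 4 / 512]) / sum(H)
  }
  rect <- rep(1 / sqrt(512), 512)
  expect_gt(conc(v), conc(rect))
  expect_gt(conc(v), 0.99)
})

test_that("total spectrogram energy is monotone in waveform scaling", {
  x <- stats::rnorm(4096)
  e1 <- sum(exp(compute_spectrogram(x)))
  e2 <- sum(exp(compute_spectrogram(2 * x)))
  expect_gt(e2, e1)
})

test_that("normalization follows the population convention and per-fold contract", {
  p <- spectrogram_params()
  sp <- compute_spectrogram(stats::rnorm(4096), p)
  ## cells {1, 3}: population mean 2, sd 1
  fake <- sp; fake[] <- rep(c(1, 3), length.out = length(fake))
  st <- fit_normalization(list(fake))
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  ## fitting on one spectrogram then applying it standardizes exactly
  st2 <- fit_normalization(sp)
  nz <- apply_normalization(sp, st2)
  expect_equal(mean(nz), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((nz - mean(nz))^2)), 1, tolerance = 1e-10)
  ## identity stats
  id <- st2; id$mean <- 0; id$sd <- 1
  expect_equal(unclass(apply_normalization(sp, id)), unclass(sp),
               ignore_attr = TRUE)
  ## arithmetic: (5 - 2)/3 = 1
  one <- sp; one[] <- 5
  st3 <- st2; st3$mean <- 2; st3$sd <- 3
  expect_true(all(apply_normalization(one, st3) == 1))
  ## different training folds give different stats
  spB <- compute_spectrogram(0.3 * stats::rnorm(4096), p)
  expect_false(isTRUE(all.equal(fit_normalization(sp)$mean,
                                fit_normalization(spB)$mean)))
  ## degenerate: identical cells warn and floor the sd
  expect_warning(fit_normalization(list(one)), "degenerate-training-data")
})

test_that("per-row normalization standardizes each frequency row", {
  sp <- compute_spectrogram(stats::rnorm(8192))
  st <- fit_normalization(sp, per_row = TRUE)
  nz <- apply_normalization(sp, st)
  expect_equal(unname(rowMeans(nz)), rep(0, 112), tolerance = 1e-10)
})

test_that("spectral envelope sums band rows and shares the frame grid", {
  song <- toy_tone_song()
  sp <- compute_spectrogram(song$wave)
  env <- envelope_from_spectrogram(sp)
  expect_equal(length(env), ncol(sp))
  const <- sp; const[] <- 2.5
  expect_true(all(abs(envelope_from_spectrogram(const) - 112 * 2.5) < 1e-9))
  ## tone frames louder than silence frames
  tone_frames <- 110:160; silent_frames <- 1:80
  expect_gt(min(env[tone_frames]), max(env[silent_frames]))
  ## normalized input is refused
  nz <- apply_normalization(sp, fit_normalization(sp))
  expect_error(envelope_from_spectrogram(nz), "invalid-input")
})

test_that("rectification envelope matches its analytic level and frame grid", {
  p <- spectrogram_params()
  song <- toy_tone_song(amp = 0.5)
  env <- envelope_from_rectification(song$wave, 200, p)
  sp <- compute_spectrogram(song$wave, p)
  expect_equal(length(env), ncol(sp))
  ## all-zero input sits at the log floor
  expect_true(all(envelope_from_rectification(rep(0, 4096), 200, p)
                  == log(p$log_floor)))
  ## constant tone: settled level ~ log of mean |sin| * amplitude (DC gain 1)
  mid <- env[120:150]
  expect_equal(mean(mid), log(0.5 * 2 / pi), tolerance = 0.05)
  expect_lt(stats::sd(mid), 0.05)
  expect_error(envelope_from_rectification(song$wave, 20000, p),
               "invalid-parameter")
  ## both envelope flavours localize the same toy note
  thr <- threshold_set(mean(range(env)), 0, 10)
  iv_r <- detect_note_intervals(env, thr)
  env_s <- envelope_from_spectrogram(sp)
  iv_s <- detect_note_intervals(envelope_from_spectrogram(sp),
                                threshold_set(mean(range(env_s)), 0, 10))
  for (iv in list(iv_r, iv_s)) {
    expect_equal(nrow(iv), 1L)
    ## envelope frames are window-anchored: the note at 100-180 ms appears
    ## around frames 92-172 on the frame grid
    expect_lt(abs(iv[1, 1] - 92), 12)
    expect_lt(abs(iv[1, 2] - 172), 12)
  }
})

test_that("annotation/frame-grid conversions shift by the window half-width", {
  ann <- song_annotation(100, 180, "a", 300)
  fg <- annotation_to_frame_grid(ann, 285)
  expect_equal(fg$onset, 92)
  expect_equal(fg$offset, 172)
  back <- frame_grid_to_annotation(fg, 300)
  expect_equal(back$onset, ann$onset)
  expect_equal(back$offset, ann$offset)
})
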