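#' Spectrogram front-end parameters
#'
#' Defaults reproduce the front end used throughout the package: 32 kHz audio,
#' 512-sample short-time Fourier transform tapered with the 0th-order discrete
#' prolate spheroidal sequence (time-half-bandwidth `W * fft_size = 4`), hop of
#' 32 samples (one frame per millisecond), and the 1-8 kHz analysis band,
#' which yields 112 frequency rows at 62.5 Hz spacing.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param fft_size Transform length in samples.
#' @param hop Frame step in samples; must equal `sample_rate/1000` for 1-ms
#'   frames.
#' @param W DPSS half-bandwidth parameter in cycles/sample.
#' @param band_low,band_high Analysis band edges in Hz (half-open
#'   `[band_low, band_high)` on bin centres).
#' @param log_floor Amplitude floor applied before the logarithm.
#' @return A list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(sample_rate = 32000, fft_size = 512L,
                               hop = 32L, W = 4 / 512,
                               band_low = 1000, band_high = 8000,
                               log_floor = 1e-10) {
  fft_size <- as.integer(fft_size); hop <- as.integer(hop)
  stopifnot(fft_size > hop, band_low < band_high,
            band_high <= sample_rate / 2, log_floor > 0)
  if ((sample_rate / 1000) %% hop != 0)
    stop("invalid-parameter: hop must divide sample_rate/1000 (1 ms frames)")
  structure(list(sample_rate = sample_rate, fft_size = fft_size, hop = hop,
                 W = W, band_low = band_low, band_high = band_high,
                 log_floor = log_floor),
            class = "spectrogram_params")
}

## Indices (1-based) of FFT bins whose centre frequency lies in
## [band_low, band_high).
band_bins <- function(params) {
  freq <- (seq_len(params$fft_size) - 1L) * params$sample_rate / params$fft_size
  which(freq >= params$band_low & freq < params$band_high)
}

#' 0th-order discrete prolate spheroidal sequence
#'
#' The DPSS of order zero maximizes spectral concentration in
#' `[-W, W]` among all tapers of length `n`; it is computed as the leading
#' eigenvector of the classical symmetric tridiagonal matrix whose
#' eigenvectors are the DPSS, and returned with unit energy and positive sign.
#'
#' @param n Taper length in samples.
#' @param W Half-bandwidth in cycles/sample.
#' @return Numeric vector of length `n` with `sum(taper^2) == 1`.
#' @export
dpss_taper <- function(n, W = 4 / 512) {
  i <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off_v <- (i[-1L] * (n - i[-1L])) / 2
  tri <- matrix(0, n, n)
  tri[cbind(seq_len(n), seq_len(n))] <- diag_v
  tri[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off_v
  tri[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off_v
  v <- eigen(tri, symmetric = TRUE)$vectors[, 1L]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  v
}

taper_cache <- new.env(parent = emptyenv())

get_taper <- function(params) {
  key <- sprintf("%d_%.10f", params$fft_size, params$W)
  if (is.null(taper_cache[[key]]))
    taper_cache[[key]] <- dpss_taper(params$fft_size, params$W)
  taper_cache[[key]]
}

#' Compute a normalized-ready log-magnitude spectrogram
#'
#' Frames are anchored at their starting sample: frame `t` (0-based) covers
#' samples `[t*hop, t*hop + fft_size)`; any final partial frame is dropped.
#' Each frame is tapered with the 0th-order DPSS, Fourier transformed, and the
#' log magnitude of the bins whose centres fall in the analysis band is kept.
#'
#' @param waveform Numeric vector of audio samples.
#' @param params A [spectrogram_params()] object.
#' @return A `song_spectrogram`: matrix `frequency rows x frames` of raw log
#'   magnitudes, with the parameters, frame duration and normalization state
#'   stored as attributes.
#' @examples
#' x <- sin(2 * pi * 4000 * seq(0, 0.1, by = 1 / 32000))
#' sp <- compute_spectrogram(x)
#' dim(sp)[1]  # 112 frequency rows at defaults
#' @export
compute_spectrogram <- function(waveform, params = spectrogram_params()) {
  if (any(!is.finite(waveform))) stop("invalid-input: non-finite samples")
  n <- length(waveform)
  if (n < params$fft_size)
    stop("insufficient-input: waveform shorter than fft_size")
  n_frames <- (n - params$fft_size) %/% params$hop + 1L
  idx <- outer(seq_len(params$fft_size),
               (seq_len(n_frames) - 1L) * params$hop, "+")
  frames <- matrix(waveform[idx], nrow = params$fft_size) * get_taper(params)
  mag <- Mod(stats::mvfft(frames))[band_bins(params), , drop = FALSE]
  vals <- log(pmax(mag, params$log_floor))
  new_spectrogram(vals, params, normalized = FALSE)
}

new_spectrogram <- function(values, params, normalized) {
  structure(values, params = params, frame_duration = 1,
            normalized = normalized,
            class = c("song_spectrogram", "matrix", "array"))
}

#' @export
print.song_spectrogram <- function(x, ...) {
  cat(sprintf("<song_spectrogram> %d frequency rows x %d frames (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw"))
  invisible(x)
}

#' Fit and apply spectrogram normalization
#'
#' Log-magnitude spectrograms are mean-subtracted and divided by the standard
#' deviation before classification. The statistics are fitted on the training
#' fold only and then applied to every spectrogram, so each cross-validation
#' fold carries its own statistics. By default a single global mean/sd over
#' all cells is used (population convention); `per_row = TRUE` fits one
#' mean/sd per frequency row instead.
#'
#' @param spectrograms A `song_spectrogram` or list of them (training fold).
#' @param per_row Fit per-frequency-row statistics instead of global ones.
#' @return `fit_normalization` returns a `normalization_stats` object;
#'   `apply_normalization` returns a normalized `song_spectrogram`.
#' @export
fit_normalization <- function(spectrograms, per_row = FALSE) {
  if (is.matrix(spectrograms)) spectrograms <- list(spectrograms)
  if (!length(spectrograms)) stop("no-training-data: empty collection")
  nr <- nrow(spectrograms[[1L]])
  if (per_row) {
    n <- 0; s <- numeric(nr); s2 <- numeric(nr)
    for (sp in spectrograms) {
      n <- n + ncol(sp)
      s <- s + rowSums(sp)
      s2 <- s2 + rowSums(sp^2)
    }
    mean <- s / n
    var <- s2 / n - mean^2
  } else {
    n <- 0; s <- 0; s2 <- 0
    for (sp in spectrograms) {
      n <- n + length(sp)
      s <- s + sum(sp)
      s2 <- s2 + sum(sp^2)
    }
    mean <- s / n
    var <- s2 / n - mean^2
  }
  sd <- sqrt(pmax(var, 0))
  if (any(sd <= 1e-12)) {
    warning("degenerate-training-data: zero variance; sd floored at 1e-6")
    sd <- pmax(sd, 1e-6)
  }
  structure(list(mean = mean, sd = sd, per_row = per_row, n_rows = nr),
            class = "normalization_stats")
}

#' @rdname fit_normalization
#' @param spec A raw `song_spectrogram`.
#' @param stats A `normalization_stats` object.
#' @export
apply_normalization <- function(spec, stats) {
  if (nrow(spec) != stats$n_rows)
    stop("incompatible-stats: row count mismatch")
  out <- (spec - stats$mean) / stats$sd   # scalars or per-row vectors recycle
  new_spectrogram(out, attr(spec, "params"), normalized = TRUE)
}

#' Amplitude envelope from a spectrogram
#'
#' The envelope at frame `t` is the sum of the logarithmic amplitude spectrum
#' over the 1-8 kHz band rows — the default envelope used for boundary
#' detection by thresholding.
#'
#' @param spec A raw (un-normalized) `song_spectrogram`.
#' @return An `amplitude_envelope`: numeric vector, one value per frame.
#' @export
envelope_from_spectrogram <- function(spec) {
  if (isTRUE(attr(spec, "normalized")))
    stop("invalid-input: envelope requires a raw (un-normalized) spectrogram")
  structure(colSums(spec), frame_duration = 1,
            class = "amplitude_envelope")
}

#' Amplitude envelope by rectification and low-pass filtering
#'
#' The alternative envelope: full-wave rectification, 4th-order zero-phase
#' Butterworth low-pass (default cut-off 200 Hz), logarithm with floor, then
#' sampling at the spectrogram frame centres so both envelope flavours share
#' one frame grid. The spectral-sum envelope is the pipeline default; this one
#' is provided for comparison.
#'
#' @param waveform Numeric vector of audio samples.
#' @param cutoff Low-pass cut-off in Hz.
#' @param params A [spectrogram_params()] object.
#' @return An `amplitude_envelope` aligned with [compute_spectrogram()] frames.
#' @export
envelope_from_rectification <- function(waveform, cutoff = 200,
                                        params = spectrogram_params()) {
  if (cutoff <= 0 || cutoff >= params$sample_rate / 2)
    stop("invalid-parameter: cutoff must lie in (0, sample_rate/2)")
  n <- length(waveform)
  if (n < params$fft_size)
    stop("insufficient-input: waveform shorter than fft_size")
  bf <- signal::butter(4, cutoff / (params$sample_rate / 2), type = "low")
  sm <- signal::filtfilt(bf, abs(waveform))
  lg <- log(pmax(sm, params$log_floor))
  n_frames <- (n - params$fft_size) %/% params$hop + 1L
  centres <- (seq_len(n_frames) - 1L) * params$hop + params$fft_size %/% 2L
  structure(lg[centres + 1L], frame_duration = 1,
            class = "amplitude_envelope")
}
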