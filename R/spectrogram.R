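#' Spectrogram dataset configuration
#'
#' Controls segmentation of a recording into fixed-length windows and the
#' short-time spectral analysis of each window. The analysis window is a
#' tapered-cosine (Tukey) window with shape parameter 0.25, a choice suited
#' to transient signals such as clicks.
#'
#' @param segment_s Segment length in seconds.
#' @param hop_s Hop between segment starts in seconds (defaults to
#'   `segment_s`, i.e. non-overlapping tiling).
#' @param window_shape Tukey shape parameter in \[0, 1\] (0 = rectangular,
#'   1 = Hann).
#' @param fft_size FFT length in samples; must be a positive power of two.
#' @param fft_overlap Fractional overlap of successive analysis frames.
#' @param freq_range_hz Length-2 vector: frequency crop (low, high) in Hz,
#'   matching the detector band so images show the click-bearing band.
#' @param image_size Length-2 vector (height, width): spectrogram matrices
#'   are resampled to this fixed size.
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(segment_s = 0.5, hop_s = segment_s,
                               window_shape = 0.25, fft_size = 512,
                               fft_overlap = 0.75,
                               freq_range_hz = c(2000, 20000),
                               image_size = c(64, 64)) {
  stopifnot(hop_s > 0, hop_s <= segment_s,
            window_shape >= 0, window_shape <= 1,
            fft_size >= 2, bitwAnd(as.integer(fft_size), as.integer(fft_size) - 1L) == 0L,
            fft_overlap >= 0, fft_overlap < 1,
            length(freq_range_hz) == 2L, freq_range_hz[1] < freq_range_hz[2],
            length(image_size) == 2L, all(image_size >= 2))
  structure(
    list(segment_s = segment_s, hop_s = hop_s, window_shape = window_shape,
         fft_size = as.integer(fft_size), fft_overlap = fft_overlap,
         freq_range_hz = freq_range_hz, image_size = as.integer(image_size)),
    class = "spectrogram_config"
  )
}

#' Tapered-cosine (Tukey) window
#'
#' @param n Window length in samples.
#' @param shape Shape parameter in \[0, 1\]: the fraction of the window inside
#'   the cosine tapers.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, shape = 0.25) {
  stopifnot(n >= 1, shape >= 0, shape <= 1)
  if (n == 1L) return(1)
  if (shape == 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < shape / 2
  hi <- t > 1 - shape / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / shape - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / shape - 2 / shape + 1)))
  w
}

#' Cut a signal into fixed-length segments
#'
#' Segments are half-open intervals `[start, start + segment_s)` whose starts
#' sit at multiples of `hop_s`; a trailing partial segment is discarded.
#'
#' @param signal An [audio_signal()].
#' @param config A [spectrogram_config()].
#' @return A list of segments, each a list with `start_s`, `end_s`, and
#'   `samples`; the sample rate is attached as the `rate` attribute.
#' @export
segment_signal <- function(signal, config = spectrogram_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  seg_n <- round(config$segment_s * signal$rate)
  hop_n <- round(config$hop_s * signal$rate)
  n <- length(signal$samples)
  if (n < seg_n) {
    segs <- list()
    attr(segs, "rate") <- signal$rate
    return(segs)
  }
  starts <- seq(0L, n - seg_n, by = hop_n)
  starts <- starts[starts + seg_n <= n]
  segs <- lapply(starts, function(s) {
    list(
      start_s = s / signal$rate,
      end_s = s / signal$rate + config$segment_s,
      samples = signal$samples[(s + 1L):(s + seg_n)]
    )
  })
  attr(segs, "rate") <- signal$rate
  segs
}

# Short-time Fourier magnitude of one segment: frames x tukey window, FFT,
# rows = frequency bins 0..fs/2. Returns list(mag, freqs).
whale_stft <- function(samples, rate, config) {
  nfft <- config$fft_size
  if (length(samples) < nfft) {
    stop("segment shorter than fft_size (", length(samples), " < ", nfft, ")")
  }
  hop <- max(1L, round(nfft * (1 - config$fft_overlap)))
  starts <- seq(1L, length(samples) - nfft + 1L, by = hop)
  w <- tukey_window(nfft, config$window_shape)
  frames <- vapply(starts, function(s) samples[s:(s + nfft - 1L)] * w,
                   numeric(nfft))
  spec <- stats::mvfft(frames)
  keep <- seq_len(nfft %/% 2L + 1L)
  mag <- abs(spec[keep, , drop = FALSE])
  list(mag = mag, freqs = (keep - 1L) * rate / nfft,
       times = (starts - 1L + nfft / 2) / rate)
}

# Bilinear resampling of a matrix to a fixed (rows, cols) size.
resample_matrix <- function(m, out_rows, out_cols) {
  in_rows <- nrow(m); in_cols <- ncol(m)
  ri <- if (in_rows == 1L) rep(1, out_rows) else
    seq(1, in_rows, length.out = out_rows)
  ci <- if (in_cols == 1L) rep(1, out_cols) else
    seq(1, in_cols, length.out = out_cols)
  r0 <- pmin(floor(ri), in_rows - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), in_cols - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0; fc <- ci - c0
  if (in_rows == 1L) { r0 <- rep(1L, out_rows); fr <- rep(0, out_rows) }
  if (in_cols == 1L) { c0 <- rep(1L, out_cols); fc <- rep(0, out_cols) }
  top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, pmin(c0 + 1L, in_cols), drop = FALSE] * outer(1 - fr, fc)
  bot <- m[pmin(r0 + 1L, in_rows), c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[pmin(r0 + 1L, in_rows), pmin(c0 + 1L, in_cols), drop = FALSE] *
    outer(fr, fc)
  top + bot
}

#' Compute a log-magnitude spectrogram matrix for one segment
#'
#' Short-time analysis with a Tukey window, magnitude in dB relative to the
#' segment maximum with an -80 dB floor, cropped to the configured frequency
#' band, and bilinearly resampled to `image_size`. An all-zero (silent)
#' segment is returned as a constant matrix at the floor value. Deterministic
#' for fixed input.
#'
#' @param samples Numeric vector: one segment of audio.
#' @param rate Sampling rate in Hz.
#' @param config A [spectrogram_config()].
#' @return A numeric matrix of dimension `config$image_size`
#'   (frequency x time, low frequencies in row 1).
#' @export
compute_spectrogram <- function(samples, rate, config = spectrogram_config()) {
  st <- whale_stft(samples, rate, config)
  keep <- st$freqs >= config$freq_range_hz[1] &
    st$freqs <= config$freq_range_hz[2]
  if (!any(keep)) stop("frequency crop leaves no bins; check freq_range_hz")
  mag <- st$mag[keep, , drop = FALSE]
  peak <- max(mag)
  floor_db <- -80
  db <- if (peak > 0) {
    pmax(20 * log10(pmax(mag / peak, 1e-12)), floor_db)
  } else {
    matrix(floor_db, nrow(mag), ncol(mag))
  }
  resample_matrix(db, config$image_size[1], config$image_size[2])
}

#' Auto-label segments as click / no-click from a click train
#'
#' Implements the labeling oracle of the CNN corpus: a segment is labeled
#' `"click"` exactly when at least one detected click time t satisfies
#' `start_s <= t < end_s` (half-open, so a click on a boundary belongs to the
#' later segment).
#'
#' @param segments Output of [segment_signal()].
#' @param clicks A [click_train()] computed from the same signal.
#' @param config A [spectrogram_config()]; used to compute each segment's
#'   spectrogram matrix.
#' @return A list of labelled spectrograms, each a list with `matrix`,
#'   `label` (`"click"` or `"no_click"`), `start_s`, `end_s`.
#' @export
auto_label <- function(segments, clicks, config = spectrogram_config()) {
  stopifnot(inherits(clicks, "click_train"))
  rate <- attr(segments, "rate")
  lapply(segments, function(seg) {
    has_click <- any(clicks$times >= seg$start_s & clicks$times < seg$end_s)
    list(
      matrix = compute_spectrogram(seg$samples, rate, config),
      label = if (has_click) "click" else "no_click",
      start_s = seg$start_s,
      end_s = seg$end_s
    )
  })
}

#' Assemble a balanced image dataset from labelled spectrograms
#'
#' Samples `n_per_class` spectrograms per class without replacement and
#' shuffles them, reproducibly for a fixed seed. Each image is standardized
#' to zero mean and unit variance before entering the CNN.
#'
#' @param labeled List of labelled spectrograms from [auto_label()].
#' @param n_per_class Number of images to draw from each class.
#' @param seed Integer seed controlling sampling and shuffling.
#' @return A list with `x` (array n x height x width x 1), `labels` (factor
#'   with levels `click`, `no_click`), and `manifest` (data frame with label
#'   and segment bounds).
#' @export
build_image_dataset <- function(labeled, n_per_class, seed = 1L) {
  labs <- vapply(labeled, `[[`, character(1), "label")
  counts <- table(factor(labs, levels = c("click", "no_click")))
  if (any(counts < n_per_class)) {
    stop(sprintf(
      "insufficient examples: need %d per class, have click=%d no_click=%d",
      n_per_class, counts[["click"]], counts[["no_click"]]))
  }
  set.seed(seed)
  pick <- c(
    sample(which(labs == "click"), n_per_class),
    sample(which(labs == "no_click"), n_per_class)
  )
  pick <- sample(pick)
  h <- nrow(labeled[[pick[1]]]$matrix)
  w <- ncol(labeled[[pick[1]]]$matrix)
  x <- array(0, c(length(pick), h, w, 1L))
  for (i in seq_along(pick)) {
    m <- labeled[[pick[i]]]$matrix
    s <- stats::sd(m)
    x[i, , , 1L] <- if (s > 0) (m - mean(m)) / s else m * 0
  }
  list(
    x = x,
    labels = factor(labs[pick], levels = c("click", "no_click")),
    manifest = data.frame(
      label = labs[pick],
      start_s = vapply(labeled[pick], `[[`, numeric(1), "start_s"),
      end_s = vapply(labeled[pick], `[[`, numeric(1), "end_s")
    )
  )
}
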