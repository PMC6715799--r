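#' Construct an audio signal
#'
#' A lightweight container for a uniformly sampled mono waveform, the carrier
#' of the acoustic track of the pipeline.
#'
#' @param samples Numeric vector of dimensionless amplitudes. Must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param origin Optional character identifier of the source (e.g. file path).
#' @return An object of class `audio_signal` with fields `samples`, `rate`,
#'   and `origin`.
#' @export
audio_signal <- function(samples, rate, origin = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)")
  }
  structure(
    list(samples = samples, rate = rate, origin = origin),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s)%s>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (is.null(x$origin)) "" else paste0(", ", x$origin)))
  invisible(x)
}

#' Detector parameters
#'
#' Parameters of the time-domain click detector: a fifth-order Butterworth
#' bandpass (2--20 kHz by default) applied zero-phase, an amplitude threshold
#' expressed as a fraction of the normalized peak, and a minimum separation
#' between retained clicks that suppresses echoes, reflections and
#' within-click pulse structure.
#'
#' @param low_hz Low-frequency cutoff in Hz.
#' @param high_hz High-frequency cutoff in Hz.
#' @param order Butterworth filter order.
#' @param threshold Amplitude threshold as a fraction of the normalized peak
#'   (0 < threshold <= 1).
#' @param min_separation_s Minimum separation between retained clicks in
#'   seconds.
#' @param abs_floor Optional absolute amplitude floor, in pre-normalization
#'   units of the filtered signal. When set, peaks whose absolute filtered
#'   amplitude falls below this floor are rejected even if they exceed
#'   `threshold` after peak normalization. Off (`NULL`) by default; useful on
#'   synthetic audio where pure noise would otherwise be rescaled to peak 1.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(low_hz = 2000, high_hz = 20000, order = 5,
                            threshold = 0.15, min_separation_s = 0.2,
                            abs_floor = NULL) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1,
            threshold > 0, threshold <= 1, min_separation_s > 0)
  structure(
    list(low_hz = low_hz, high_hz = high_hz, order = order,
         threshold = threshold, min_separation_s = min_separation_s,
         abs_floor = abs_floor),
    class = "detector_params"
  )
}

#' Construct a click train
#'
#' @param times Strictly increasing click times in seconds.
#' @param amplitudes Absolute peak heights matched to `times`.
#' @param params The [detector_params()] used to produce the train.
#' @return An object of class `click_train`.
#' @export
click_train <- function(times, amplitudes, params) {
  stopifnot(length(times) == length(amplitudes))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  structure(
    list(times = as.numeric(times), amplitudes = as.numeric(amplitudes),
         params = params),
    class = "click_train"
  )
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train: %d clicks%s>\n", length(x$times),
              if (length(x$times))
                sprintf(", %.3f-%.3f s", min(x$times), max(x$times)) else ""))
  invisible(x)
}

## WAV I/O -------------------------------------------------------------------

#' Read a PCM/float WAV file as a mono audio signal
#'
#' Parses the RIFF/WAVE container directly: 16- and 24-bit integer PCM and
#' 32-bit IEEE float encodings are supported. Multi-channel files are averaged
#' to mono; integer samples are scaled to \[-1, 1).
#'
#' @param path Path to the WAV file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read audio file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("garbled WAV file (missing fmt/data chunk): ", path)
  }
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                   signed = TRUE, endian = "little") / 2^15,
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw), nrow = 3L)[, seq_len(n), drop = FALSE]
      v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    },
    "32" = {
      if (fmt$audio_format == 3L) {
        readBin(data_raw, "double", length(data_raw) / 4L, 4L,
                endian = "little")
      } else {
        readBin(data_raw, "integer", length(data_raw) / 4L, 4L,
                endian = "little") / 2^31
      }
    },
    stop("unsupported WAV bit depth: ", fmt$bits)
  )
  if (length(x) == 0L) stop("zero-length audio in: ", path)
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate, origin = path)
}

#' Write an audio signal as 16-bit PCM WAV
#'
#' @param signal An [audio_signal()]. Samples outside \[-1, 1\] are clipped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmin(pmax(signal$samples, -1), 1)
  pcm <- as.integer(round(x * (2^15 - 1)))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")         # PCM, mono
  writeBin(as.integer(signal$rate), con, 4L, endian = "little")
  writeBin(as.integer(signal$rate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")        # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

#' Read audio from file
#'
#' Convenience front end used by the detector CLI; currently supports WAV.
#'
#' @param path Path to a PCM/float WAV file.
#' @return An [audio_signal()].
#' @export
read_audio <- function(path) read_wav(path)

## Preprocessing -------------------------------------------------------------

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the detector's Butterworth bandpass forward and backward
#' (zero-phase), so click peak times are not shifted by filter group delay.
#' If the high cutoff is at or above the Nyquist frequency it is clamped to
#' 0.45 x rate with a warning, since archive recordings vary in sample rate.
#'
#' @param signal An [audio_signal()].
#' @param params A [detector_params()].
#' @return The filtered [audio_signal()], same length and rate.
#' @export
bandpass_filter <- function(signal, params = detector_params()) {
  stopifnot(inherits(signal, "audio_signal"))
  high <- params$high_hz
  nyq <- signal$rate / 2
  if (high >= nyq) {
    high <- 0.45 * signal$rate
    if (high <= params$low_hz) {
      stop("sample rate ", signal$rate,
           " Hz too low for the requested band; lower `high_hz`")
    }
    warning(sprintf(
      "high_hz %g >= Nyquist (%g Hz); clamped to %g Hz",
      params$high_hz, nyq, high))
  }
  if (length(signal$samples) == 0L) return(signal)
  bf <- signal::butter(params$order, c(params$low_hz, high) / nyq,
                       type = "pass")
  y <- signal::filtfilt(bf, signal$samples)
  audio_signal(y, signal$rate, origin = signal$origin)
}

#' Mean-subtract and peak-normalize a signal
#'
#' Subtracts the mean and rescales so the maximum absolute amplitude is 1.
#' A constant (zero-variance) input — legitimate silence — returns all zeros.
#'
#' @param signal An [audio_signal()].
#' @return The normalized [audio_signal()].
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  if (length(x) == 0L) return(signal)
  # already normalized (peak exactly 1, mean within tolerance): fixed point,
  # so repeated application is exactly idempotent
  if (max(abs(x)) == 1 && abs(mean(x)) <= 1e-9) return(signal)
  x <- x - mean(x)
  peak <- max(abs(x))
  x <- if (peak > 0) x / peak else x * 0
  audio_signal(x, signal$rate, origin = signal$origin)
}

## Detection -----------------------------------------------------------------

#' Detect echolocation clicks by suprathreshold peak picking
#'
#' Scans the absolute value of the (already filtered and normalized) signal
#' for local maxima above `params$threshold`, then greedily retains peaks in
#' descending amplitude order, discarding any peak closer than
#' `params$min_separation_s` to an already retained one. Exact amplitude ties
#' are broken in favor of the earlier peak. Click time is the peak sample
#' index divided by the rate, with the first sample at time 0.
#'
#' @param signal An [audio_signal()], assumed bandpassed and normalized (see
#'   [run_detector()] for the composed pipeline).
#' @param params A [detector_params()].
#' @return A [click_train()].
#' @export
detect_clicks <- function(signal, params = detector_params()) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- abs(signal$samples)
  n <- length(x)
  if (n < 3L) return(click_train(numeric(0), numeric(0), params))
  core <- x[2:(n - 1L)]
  is_peak <- core > x[1:(n - 2L)] & core >= x[3:n] & core > params$threshold
  idx <- which(is_peak) + 1L
  if (length(idx) == 0L) return(click_train(numeric(0), numeric(0), params))
  amp <- x[idx]
  # Greedy amplitude-priority suppression; ties resolved by earlier time.
  ord <- order(-amp, idx)
  min_gap <- params$min_separation_s * signal$rate
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(idx[i] - kept) >= min_gap)) {
      kept <- c(kept, idx[i])
    }
  }
  kept <- sort(kept)
  click_train((kept - 1L) / signal$rate, x[kept], params)
}

#' Run the full click detector
#'
#' Chains [bandpass_filter()], [normalize_signal()], and [detect_clicks()].
#' When `params$abs_floor` is set, the effective threshold is raised so that
#' retained peaks also exceed the absolute (pre-normalization) floor on the
#' filtered signal.
#'
#' @param signal A raw [audio_signal()].
#' @param params A [detector_params()].
#' @return A [click_train()].
#' @export
run_detector <- function(signal, params = detector_params()) {
  filt <- bandpass_filter(signal, params)
  centred <- filt$samples - mean(filt$samples)
  peak <- if (length(centred)) max(abs(centred)) else 0
  norm <- normalize_signal(filt)
  eff <- params
  if (!is.null(params$abs_floor)) {
    if (peak <= 0 || params$abs_floor / peak >= 1) {
      return(click_train(numeric(0), numeric(0), params))
    }
    eff$threshold <- max(params$threshold, params$abs_floor / peak)
  }
  out <- detect_clicks(norm, eff)
  out$params <- params
  out
}

#' Histogram of inter-click intervals
#'
#' Used to choose the canonical minimum inter-click interval of the
#' suppression rule by inspection.
#'
#' @param train A [click_train()].
#' @param bin_width_s Bin width in seconds (> 0).
#' @return A list with `edges` (bin boundaries) and `counts`; the counts sum
#'   to `max(0, n_clicks - 1)`.
#' @export
ici_histogram <- function(train, bin_width_s) {
  stopifnot(inherits(train, "click_train"), bin_width_s > 0)
  gaps <- diff(train$times)
  if (length(gaps) == 0L) {
    return(list(edges = c(0, bin_width_s), counts = 0L))
  }
  n_bins <- max(1L, ceiling(max(gaps) / bin_width_s + 1e-12))
  edges <- seq(0, n_bins * bin_width_s, by = bin_width_s)
  # nudge guards against gaps computed a half-ulp below an exact bin edge
  counts <- tabulate(pmin(findInterval(gaps + bin_width_s * 1e-9, edges),
                          n_bins), n_bins)
  list(edges = edges, counts = counts)
}
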