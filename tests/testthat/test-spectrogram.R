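test_that("segmentation tiles the recording and discards trailing partials", {
  rate <- 48000
  cfg <- spectrogram_config()
  segs <- segment_signal(audio_signal(rep(0, 5 * rate), rate), cfg)
  expect_length(segs, 10)
  expect_equal(sapply(segs, `[[`, "start_s"), seq(0, 4.5, by = 0.5))
  expect_true(all(sapply(segs, function(s) s$end_s - s$start_s) == 0.5))

  expect_length(segment_signal(audio_signal(rep(0, 0.4 * rate), rate), cfg), 0)

  cfg2 <- spectrogram_config(segment_s = 0.5, hop_s = 0.25)
  segs2 <- segment_signal(audio_signal(rep(0, rate), rate), cfg2)
  expect_equal(sapply(segs2, `[[`, "start_s"), c(0, 0.25, 0.5))
})

test_that("a pure tone concentrates spectrogram energy at its frequency", {
  rate <- 96000
  cfg <- spectrogram_config(image_size = c(64, 64))
  t <- seq(0, 0.5 - 1 / rate, by = 1 / rate)
  m <- compute_spectrogram(sin(2 * pi * 10000 * t), rate, cfg)
  expect_equal(dim(m), c(64, 64))
  # reconstruct the row -> frequency mapping of the cropped, resampled image
  freqs <- (seq_len(cfg$fft_size %/% 2 + 1) - 1) * rate / cfg$fft_size
  kept <- freqs[freqs >= cfg$freq_range_hz[1] & freqs <= cfg$freq_range_hz[2]]
  row_freq <- seq(min(kept), max(kept), length.out = 64)
  peak_freq <- row_freq[which.max(rowMeans(m))]
  bin_hz <- rate / cfg$fft_size
  row_hz <- diff(row_freq[1:2])
  expect_lt(abs(peak_freq - 10000), bin_hz + row_hz)
})

test_that("silent segments sit at the log floor and framing obeys Parseval", {
  cfg <- spectrogram_config(image_size = c(16, 16))
  m <- compute_spectrogram(rep(0, 24000), 48000, cfg)
  expect_true(all(m == -80))

  set.seed(4)
  samples <- stats::rnorm(512)
  st <- whalecoda:::whale_stft(samples, 48000, spectrogram_config())
  w <- tukey_window(512, 0.25)
  time_energy <- sum((samples[1:512] * w)^2)
  mag <- st$mag[, 1]
  freq_energy <- (mag[1]^2 + 2 * sum(mag[2:256]^2) + mag[257]^2) / 512
  expect_equal(freq_energy, time_energy, tolerance = 0.01)

  expect_error(compute_spectrogram(rep(0, 100), 48000, cfg), "fft_size")
})

test_that("segments are labelled click exactly when the detector saw a click inside", {
  rate <- 48000
  cfg <- spectrogram_config(image_size = c(16, 16))
  sig <- audio_signal(stats::rnorm(rate, sd = 0.01), rate)
  segs <- segment_signal(sig, cfg)
  params <- detector_params()

  tr <- click_train(0.25, 1, params)
  labs <- sapply(auto_label(segs, tr, cfg), `[[`, "label")
  expect_equal(labs, c("click", "no_click"))

  none <- click_train(numeric(0), numeric(0), params)
  expect_true(all(sapply(auto_label(segs, none, cfg), `[[`, "label") ==
                    "no_click"))

  boundary <- click_train(0.5, 1, params)
  labs_b <- sapply(auto_label(segs, boundary, cfg), `[[`, "label")
  expect_equal(labs_b, c("no_click", "click"))

  # label consistency: recomputing labels from the train reproduces them
  tr2 <- click_train(c(0.1, 0.4, 0.8), rep(1, 3), params)
  lab2 <- auto_label(segs, tr2, cfg)
  for (ls in lab2) {
    expect_equal(ls$label,
                 if (any(tr2$times >= ls$start_s & tr2$times < ls$end_s))
                   "click" else "no_click")
  }
})

test_that("image dataset assembly balances classes deterministically", {
  mk <- function(label, i) list(matrix = matrix(i + 0:3, 2, 2), label = label,
                                start_s = i, end_s = i + 0.5)
  pool <- c(lapply(1:8, function(i) mk("click", i)),
            lapply(1:6, function(i) mk("no_click", 100 + i)))
  ds <- build_image_dataset(pool, 5, seed = 3)
  expect_equal(as.vector(table(ds$labels)), c(5, 5))
  expect_equal(dim(ds$x), c(10, 2, 2, 1))
  ds2 <- build_image_dataset(pool, 5, seed = 3)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$x, ds2$x)
  expect_error(build_image_dataset(pool, 7, seed = 1), "insufficient")
  # per-image standardization
  expect_equal(mean(ds$x[1, , , 1]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ds$x[1, , , 1]), 1, tolerance = 1e-12)
})
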