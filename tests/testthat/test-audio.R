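test_that("WAV files round-trip and multi-channel audio is averaged to mono", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(rep(0, 48000), 48000), path)
  sig <- read_audio(path)
  expect_equal(length(sig$samples), 48000)
  expect_equal(sig$rate, 48000)
  expect_true(all(sig$samples == 0))

  t <- seq(0, 0.1, by = 1 / 48000)
  tone <- 0.5 * sin(2 * pi * 440 * t)
  write_wav(audio_signal(tone, 48000), path)
  expect_equal(read_wav(path)$samples, tone, tolerance = 1e-3)

  x <- 0.4 * sin(2 * pi * 100 * seq(0, 0.05, by = 1 / 44100))
  write_stereo_wav(path, x, -x, 44100)
  mono <- read_wav(path)
  expect_lt(max(abs(mono$samples)), 1e-4)

  expect_error(read_audio("no/such/file.wav"), "no/such/file.wav")
})

test_that("normalization subtracts the mean, scales the peak to 1, and is idempotent", {
  expect_equal(normalize_signal(audio_signal(c(1, 3), 10))$samples, c(-1, 1))
  expect_equal(normalize_signal(audio_signal(c(5, 5, 5), 10))$samples,
               c(0, 0, 0))
  out <- normalize_signal(audio_signal(c(0, 0.5, -0.25), 10))$samples
  x <- 5 / 12
  expect_equal(out, c(-(1 / 12) / x, (5 / 12) / x, -(1 / 3) / x))
  expect_equal(max(abs(out)), 1)

  set.seed(1)
  for (i in 1:5) {
    sig <- audio_signal(stats::rnorm(1000), 48000)
    once <- normalize_signal(sig)
    expect_identical(normalize_signal(once)$samples, once$samples)
    expect_lt(abs(mean(once$samples)), 1e-9)
  }
})

test_that("the bandpass filter passes the click band and rejects low-frequency noise", {
  rate <- 96000
  t <- seq(0, 1, by = 1 / rate)
  rms <- function(x) sqrt(mean(x^2))
  tone10k <- audio_signal(sin(2 * pi * 10000 * t), rate)
  tone100 <- audio_signal(sin(2 * pi * 100 * t), rate)
  expect_gte(rms(bandpass_filter(tone10k)$samples), 0.9 * rms(tone10k$samples))
  expect_lte(rms(bandpass_filter(tone100)$samples), 0.01 * rms(tone100$samples))

  zero <- bandpass_filter(audio_signal(rep(0, 1000), rate))
  expect_true(all(zero$samples == 0))
  expect_equal(length(zero$samples), 1000)

  set.seed(2)
  sig <- audio_signal(stats::rnorm(4000), rate)
  a <- 3.7
  expect_equal(bandpass_filter(audio_signal(a * sig$samples, rate))$samples,
               a * bandpass_filter(sig)$samples, tolerance = 1e-8)

  expect_warning(
    clamped <- bandpass_filter(audio_signal(stats::rnorm(2000), 16000)),
    "clamped")
  expect_equal(length(clamped$samples), 2000)
})

test_that("click detection finds planted impulses and suppresses close neighbours", {
  rate <- 48000
  x <- rep(0, 2 * rate)
  for (ts in c(0.5, 1.0, 1.6)) x[round(ts * rate) + 1] <- 1
  tr <- detect_clicks(audio_signal(x, rate))
  expect_equal(tr$times, c(0.5, 1.0, 1.6), tolerance = 1 / rate)

  expect_length(detect_clicks(audio_signal(rep(0, 1000), rate))$times, 0)

  x2 <- rep(0, 2 * rate)
  x2[round(1.0 * rate) + 1] <- 1
  x2[round(1.1 * rate) + 1] <- 0.8
  tr2 <- detect_clicks(audio_signal(x2, rate))
  expect_equal(tr2$times, 1.0)
  expect_equal(tr2$amplitudes, 1.0)
})

test_that("the detector matches the brute-force oracle and is monotone in threshold", {
  params <- detector_params()
  for (seed in 1:20) {
    sig <- random_click_signal(seed, n = 20000)
    got <- detect_clicks(sig, params)
    want <- brute_force_clicks(sig$samples, sig$rate, params$threshold,
                               params$min_separation_s)
    expect_identical(got$times, want$times)
    expect_identical(got$amplitudes, want$amplitudes)
  }
  sig <- random_click_signal(99)
  counts <- vapply(c(0.05, 0.15, 0.3, 0.6, 0.9), function(th) {
    length(detect_clicks(sig, detector_params(threshold = th))$times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("click trains enforce their invariants", {
  params <- detector_params()
  sig <- random_click_signal(5)
  tr <- detect_clicks(sig, params)
  if (length(tr$times) > 1) {
    expect_true(all(diff(tr$times) >= params$min_separation_s - 1e-12))
  }
  expect_true(all(tr$amplitudes > params$threshold))
  expect_error(click_train(c(1, 1), c(0.5, 0.5), params), "increasing")
})

test_that("inter-click-interval histograms count successive gaps", {
  params <- detector_params()
  h <- ici_histogram(click_train(c(0, 0.5, 1.0), rep(1, 3), params), 0.1)
  expect_equal(sum(h$counts), 2)
  bin <- findInterval(0.5, h$edges)
  expect_equal(h$counts[bin], 2)

  h1 <- ici_histogram(click_train(0.3, 1, params), 0.1)
  expect_true(all(h1$counts == 0))

  h2 <- ici_histogram(click_train(c(0, 0.2, 0.6), rep(1, 3), params), 0.1)
  expect_equal(h2$counts[findInterval(0.2 + 1e-9, h2$edges)], 1)
  expect_equal(h2$counts[findInterval(0.4 + 1e-9, h2$edges)], 1)
  expect_equal(sum(h2$counts), 2)
})
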