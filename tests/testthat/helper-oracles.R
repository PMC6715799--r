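# Independent oracles and fixture builders shared across the suite.

# Brute-force click detector: scan every sample of |x| for suprathreshold
# local maxima (strictly above the left neighbour, at least the right one),
# sort candidates by descending amplitude (earlier time wins ties), and
# greedily accept peaks at least min_separation from every accepted one.
# Kept deliberately naive and separate from the package implementation.
brute_force_clicks <- function(samples, rate, threshold, min_separation_s) {
  x <- abs(samples)
  n <- length(x)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (x[i] > x[i - 1L] && x[i] >= x[i + 1L] && x[i] > threshold) {
      cand <- c(cand, i)
    }
  }
  ord <- cand[order(-x[cand], cand)]
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in acc) {
      if (abs(i - j) < min_separation_s * rate) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, i)
  }
  acc <- sort(acc)
  list(times = (acc - 1L) / rate, amplitudes = x[acc])
}

# Random test signal: band-limited noise plus a few strong impulses, already
# on a normalized-looking scale.
random_click_signal <- function(seed, n = 20000, rate = 48000) {
  set.seed(seed)
  x <- stats::rnorm(n, sd = 0.05)
  k <- sample(0:6, 1)
  if (k > 0) {
    pos <- sample(seq(10L, n - 10L), k)
    x[pos] <- x[pos] + stats::runif(k, 0.3, 1)
  }
  audio_signal(x / max(abs(x)), rate)
}

# Codas obeying the learnable rule: final ICI = mean of the preceding ones.
mean_rule_dataset <- function(n, seed, len_range = 3:8) {
  set.seed(seed)
  coda_dataset(lapply(seq_len(n), function(i) {
    k <- sample(len_range, 1)
    v <- stats::runif(k, 0.1, 0.6)
    coda(c(v, mean(v)))
  }), provenance = "mean-rule")
}

# Toy separable image task: class "click" has energy in the top half,
# class "no_click" in the bottom half.
toy_image_dataset <- function(n_per_class, size = 16, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(0, c(n, size, size, 1))
  lab <- rep(c("click", "no_click"), each = n_per_class)
  half <- seq_len(size %/% 2)
  for (i in seq_len(n)) {
    m <- matrix(stats::rnorm(size * size, sd = 0.3), size, size)
    if (lab[i] == "click") m[half, ] <- m[half, ] + 1.5
    else m[size %/% 2 + half, ] <- m[size %/% 2 + half, ] + 1.5
    x[i, , , 1] <- m
  }
  ord <- sample(n)
  list(x = x[ord, , , , drop = FALSE],
       labels = factor(lab[ord], levels = c("click", "no_click")))
}

# Desk-scale pretrain -> transfer -> evaluate run on a synthetic population.
# Returns train/test accuracy. Head hyperparameters follow the package
# defaults except where a task needs a longer schedule (clan).
synthetic_pipeline_run <- function(jitter_cv, seed, cell = "LSTM",
                                   axis = "type", n_classes = 5,
                                   n_per_class = 100, head_epochs = 200) {
  spec <- simple_synth_spec(n_types = 5, jitter_cv = jitter_cv,
                            n_per_class = n_per_class, class_axis = axis,
                            seed = seed)
  cds <- generate_codas(spec)
  sp <- split_train_test(cds, 0.1, seed = seed + 1, stratify_by = axis)
  base <- pretrain_base(sp$train,
                        base_config(cell = cell, n_layers = 2,
                                    hidden_units = 32, epochs = 10,
                                    max_len = 11, seed = seed))
  clf <- build_transfer_model(
    base,
    head_config(n_classes = n_classes, head_hidden_units = 32,
                dense_widths = 32, epochs = head_epochs, seed = seed + 2))
  fit <- train_classifier(clf, sp$train, axis)
  c(train = fit$report$final_accuracy,
    test = evaluate_classifier(fit$model, sp$test, axis))
}

# Minimal stereo 16-bit PCM WAV writer used only to exercise read_wav's
# channel averaging.
write_stereo_wav <- function(path, left, right, rate) {
  stopifnot(length(left) == length(right))
  inter <- as.vector(rbind(left, right))
  pcm <- as.integer(round(pmin(pmax(inter, -1), 1) * (2^15 - 1)))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 2L), con, 2L, endian = "little")
  writeBin(as.integer(rate), con, 4L, endian = "little")
  writeBin(as.integer(rate * 4L), con, 4L, endian = "little")
  writeBin(c(4L, 16L), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
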