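test_that("sequence preparation pads, masks, and excludes the proxy target", {
  ds <- coda_dataset(list(coda(c(0.2, 0.3, 0.4)), coda(c(0.5, 0.6))))
  prep <- prepare_sequences(ds, "proxy", max_len = 6)
  expect_equal(dim(prep$x), c(2, 5))
  expect_equal(prep$x[1, ], c(0.2, 0.3, 0, 0, 0))
  expect_equal(prep$mask[1, ], c(1, 1, 0, 0, 0))
  expect_equal(prep$targets, c(0.4, 0.6))
  expect_true(all(prep$x[prep$mask == 0] == 0))

  expect_error(prepare_sequences(coda_dataset(list(coda(0.2))), "proxy"),
               ">= 2 ICIs")
  expect_error(prepare_sequences(ds, "proxy", max_len = 2), "max_len")

  lab <- coda_dataset(list(coda(c(0.2, 0.3), type = "A"),
                           coda(c(0.4, 0.5), type = "B"),
                           coda(c(0.6, 0.7), type = "A")))
  cls <- prepare_sequences(lab, "classify", label_kind = "type", max_len = 4)
  expect_equal(dim(cls$x), c(3, 4))
  expect_equal(cls$targets, c(0L, 1L, 0L))
})

test_that("recurrent backward passes match numerical gradients", {
  num_grad <- function(fun, param, eps = 1e-5) {
    g <- param * 0
    for (i in seq_along(param)) {
      p1 <- param; p1[i] <- p1[i] + eps
      p2 <- param; p2[i] <- p2[i] - eps
      g[i] <- (fun(p1) - fun(p2)) / (2 * eps)
    }
    g
  }
  set.seed(42)
  B <- 3; T_ <- 5; d <- 2; H <- 4
  xs <- lapply(1:T_, function(t) matrix(stats::rnorm(B * d), B, d))
  mask <- matrix(1, B, T_); mask[1, 4:5] <- 0; mask[2, 5] <- 0
  w_out <- matrix(stats::rnorm(H), H, 1)
  for (cell in c("LSTM", "GRU")) {
    layer <- whalecoda:::rnn_layer_new(cell, d, H)
    loss_fn <- function(ly) {
      fw <- whalecoda:::rnn_forward(ly, xs, mask)
      sum((fw$h_last %*% w_out)^2) / 2
    }
    fw <- whalecoda:::rnn_forward(layer, xs, mask)
    d_h <- (fw$h_last %*% w_out) %*% t(w_out)
    bk <- whalecoda:::rnn_backward(layer, fw$cache, d_h_last = d_h)
    for (nm in c("Wx", "Wh", "b")) {
      ng <- num_grad(function(p) {
        ly <- layer; ly$params[[nm]] <- p; loss_fn(ly)
      }, layer$params[[nm]])
      expect_equal(bk$grads[[nm]], ng, tolerance = 1e-6,
                   label = paste(cell, nm, "gradient"))
    }
  }
})

test_that("parameter counts follow the closed-form gate conventions", {
  ds <- mean_rule_dataset(20, seed = 1)
  lstm <- pretrain_base(ds, base_config("LSTM", n_layers = 1, hidden_units = 2,
                                        epochs = 0, max_len = 11))
  pc_l <- count_parameters(lstm)
  expect_equal(pc_l$by_layer$parameters[1], 4 * (2 * (2 + 1) + 2))  # 32
  expect_equal(pc_l$total, 32 + (2 * 1 + 1))

  gru <- pretrain_base(ds, base_config("GRU", n_layers = 1, hidden_units = 2,
                                       epochs = 0, max_len = 11))
  pc_g <- count_parameters(gru)
  expect_equal(pc_g$by_layer$parameters[1], 3 * (2 * (2 + 1) + 2))  # 24
  expect_lt(pc_g$total, pc_l$total)
  expect_equal(pc_g$total, pc_g$trainable + pc_g$frozen)

  # frozen partition of a transfer model equals the base stack's count
  base <- pretrain_base(ds, base_config("LSTM", n_layers = 2, hidden_units = 8,
                                        epochs = 0, max_len = 11))
  clf <- build_transfer_model(base, head_config(n_classes = 2,
                                                head_hidden_units = 4,
                                                dense_widths = 4, epochs = 0))
  pc_c <- count_parameters(clf)
  stack_count <- 4 * (8 * (8 + 1) + 8) + 4 * (8 * (8 + 8) + 8)
  expect_equal(pc_c$frozen, stack_count)
  expect_equal(pc_c$total, pc_c$trainable + pc_c$frozen)
})

test_that("relative error has its analytic values", {
  expect_equal(relative_error_pct(c(0.2, 0.5), c(0.2, 0.5)), 0)
  expect_equal(relative_error_pct(2 * c(0.2, 0.5), c(0.2, 0.5)), 100)
  expect_equal(relative_error_pct(0.30, 0.25), 20)
  expect_error(relative_error_pct(1, 0), "zero")
})

test_that("proxy pretraining learns the mean rule and is seeded", {
  ds <- mean_rule_dataset(2000, seed = 8)
  cfg0 <- base_config("LSTM", n_layers = 2, hidden_units = 32, epochs = 0,
                      max_len = 11, seed = 1)
  base0 <- pretrain_base(ds, cfg0)
  err0 <- proxy_relative_error(base0, ds)
  expect_gt(err0, 50)

  cfg <- base_config("LSTM", n_layers = 2, hidden_units = 32, epochs = 15,
                     max_len = 11, seed = 1)
  base <- pretrain_base(ds, cfg)
  expect_lte(proxy_relative_error(base, ds), 5)

  # epochs = 0 reproduces the seeded initialization exactly
  base0b <- pretrain_base(ds, cfg0)
  expect_identical(base0$layers, base0b$layers)
  expect_identical(base0$out_layer, base0b$out_layer)
})

test_that("pretraining reduces the proxy error for every seed in a 5-seed suite", {
  for (seed in 1:5) {
    ds <- mean_rule_dataset(400, seed = 100 + seed)
    pre <- proxy_relative_error(
      pretrain_base(ds, base_config("LSTM", n_layers = 1, hidden_units = 16,
                                    epochs = 0, max_len = 11, seed = seed)), ds)
    post <- proxy_relative_error(
      pretrain_base(ds, base_config("LSTM", n_layers = 1, hidden_units = 16,
                                    epochs = 5, max_len = 11, seed = seed)), ds)
    expect_lt(post, pre)
  }
})

test_that("transfer models freeze the base, train the head, and stay reproducible", {
  spec <- simple_synth_spec(n_types = 3, jitter_cv = 0.05, n_per_class = 40,
                            seed = 5)
  cds <- generate_codas(spec)
  base <- pretrain_base(cds, base_config("LSTM", n_layers = 2,
                                         hidden_units = 16, epochs = 5,
                                         max_len = 11, seed = 5))
  head <- head_config(n_classes = 3, head_hidden_units = 16, dense_widths = 16,
                      epochs = 10, seed = 6)
  clf <- build_transfer_model(base, head)

  expect_true(all(!sapply(clf$frozen_layers, `[[`, "trainable")))
  frozen_before <- lapply(clf$frozen_layers, `[[`, "params")
  fit <- train_classifier(clf, cds, "type")
  expect_identical(lapply(fit$model$frozen_layers, `[[`, "params"),
                   frozen_before)
  expect_identical(frozen_before, lapply(base$layers, `[[`, "params"))

  # softmax rows normalized
  probs <- predict(fit$model, cds)
  expect_equal(rowSums(probs), rep(1, length(cds)), tolerance = 1e-6)
  expect_equal(ncol(probs), 3)

  # same seeds, same trajectory
  fit2 <- train_classifier(build_transfer_model(base, head), cds, "type")
  expect_identical(fit$report$loss, fit2$report$loss)

  # guards
  expect_error(head_config(n_classes = 1), "n_classes")
  dead <- build_transfer_model(base, head)
  dead$head_rnn$trainable <- FALSE
  for (i in seq_along(dead$dense_layers)) dead$dense_layers[[i]]$trainable <- FALSE
  expect_error(train_classifier(dead, cds, "type"), "no trainable")
  wrong <- build_transfer_model(base, head_config(n_classes = 5,
                                                  head_hidden_units = 8,
                                                  epochs = 1))
  expect_error(train_classifier(wrong, cds, "type"), "vocabulary")
})

test_that("hidden features have the head width and separate trained classes", {
  spec <- simple_synth_spec(n_types = 3, jitter_cv = 0, n_per_class = 30,
                            seed = 9)
  cds <- generate_codas(spec)
  base <- pretrain_base(cds, base_config("LSTM", n_layers = 1,
                                         hidden_units = 16, epochs = 5,
                                         max_len = 11, seed = 2))
  fit <- train_classifier(
    build_transfer_model(base, head_config(n_classes = 3,
                                           head_hidden_units = 24,
                                           dense_widths = 16, epochs = 40,
                                           seed = 3)),
    cds, "type")
  feats <- extract_hidden_features(fit$model, cds)
  expect_equal(dim(feats), c(length(cds), 24))

  # identical codas give identical features
  two <- coda_dataset(list(cds$codas[[1]], cds$codas[[1]]))
  f2 <- extract_hidden_features(fit$model, two)
  expect_identical(f2[1, ], f2[2, ])

  labs <- sapply(cds$codas, `[[`, "type")
  d <- as.matrix(stats::dist(feats))
  same <- outer(labs, labs, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
})

test_that("classifier evaluation validates inputs", {
  spec <- simple_synth_spec(n_types = 3, jitter_cv = 0.05, n_per_class = 20,
                            seed = 13)
  cds <- generate_codas(spec)
  base <- pretrain_base(cds, base_config("LSTM", n_layers = 1,
                                         hidden_units = 8, epochs = 2,
                                         max_len = 11, seed = 1))
  fit <- train_classifier(
    build_transfer_model(base, head_config(n_classes = 3,
                                           head_hidden_units = 8,
                                           dense_widths = 8, epochs = 5,
                                           seed = 1)),
    cds, "type")
  expect_error(evaluate_classifier(fit$model, coda_dataset(list()), "type"),
               "empty")
  alien <- coda_dataset(list(coda(c(0.2, 0.3), type = "Zq")))
  expect_error(evaluate_classifier(fit$model, alien, "type"), "vocabulary")
  acc <- evaluate_classifier(fit$model, cds, "type")
  expect_gte(acc, 0)
  expect_lte(acc, 1)
})
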