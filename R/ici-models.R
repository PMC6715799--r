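#' Configuration of the recurrent base network
#'
#' The base network is a stack of recurrent layers (LSTM by default) with a
#' scalar regression output, pretrained on the self-supervised proxy task:
#' for an n-click coda, predict the final inter-click interval from the
#' first (n - 1) intervals. Defaults follow the reference regime: two LSTM
#' layers of 256 hidden units, Adam with learning rate 1e-3, 20 epochs,
#' minimizing root-mean-square error.
#'
#' @param cell `"LSTM"` or `"GRU"`.
#' @param n_layers Number of recurrent layers.
#' @param hidden_units Hidden state width per layer.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param max_len Maximum ICI count per coda accepted by the network
#'   (sequences are post-padded to this length; default 11, i.e. codas of up
#'   to 12 clicks).
#' @param seed Integer seed for initialization and shuffling.
#' @param standardize If `TRUE`, inputs are standardized with the
#'   pretraining set's mean and standard deviation; off by default so the
#'   models consume ICIs in raw seconds.
#' @return An object of class `base_config`.
#' @export
base_config <- function(cell = c("LSTM", "GRU"), n_layers = 2,
                        hidden_units = 256, learning_rate = 1e-3,
                        epochs = 20, batch_size = 64, max_len = 11,
                        seed = 1L, standardize = FALSE) {
  cell <- match.arg(cell)
  stopifnot(n_layers >= 1, hidden_units >= 1, max_len >= 2, epochs >= 0,
            batch_size >= 1, learning_rate > 0)
  structure(
    list(cell = cell, n_layers = as.integer(n_layers),
         hidden_units = as.integer(hidden_units),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), max_len = as.integer(max_len),
         seed = as.integer(seed), standardize = standardize),
    class = "base_config"
  )
}

#' Configuration of the trainable classification head
#'
#' The head added during transfer learning: one recurrent layer reading the
#' frozen base's output sequence, a stack of ReLU fully connected layers,
#' and an `n_classes`-way softmax trained under categorical cross entropy.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param head_hidden_units Hidden width of the head recurrent layer (its
#'   final-step output is the feature vector used for embedding; 256 under
#'   defaults).
#' @param dense_widths Integer vector of ReLU layer widths between the head
#'   recurrent layer and the softmax.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return An object of class `head_config`.
#' @export
head_config <- function(n_classes, head_hidden_units = 256,
                        dense_widths = 128, learning_rate = 5e-3,
                        epochs = 200, batch_size = 32, seed = 1L) {
  stopifnot(n_classes >= 2, head_hidden_units >= 1, epochs >= 0,
            batch_size >= 1, learning_rate > 0)
  structure(
    list(n_classes = as.integer(n_classes),
         head_hidden_units = as.integer(head_hidden_units),
         dense_widths = as.integer(dense_widths),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "head_config"
  )
}

#' Prepare padded sequence batches from a coda dataset
#'
#' Post-pads ICI vectors with zeros to a fixed length and builds the 0/1
#' validity mask consumed by the recurrent layers. For the proxy task the
#' inputs are the first (n - 1) ICIs and the target is the nth ICI, which is
#' never included in the inputs; for classification the inputs are all n
#' ICIs and the target is the encoded label.
#'
#' @param ds A [coda_dataset()].
#' @param task `"proxy"` or `"classify"`.
#' @param label_kind Label kind for classification targets.
#' @param max_len Maximum ICI count (proxy inputs are padded to
#'   `max_len - 1`).
#' @return A list with `x` (n x T matrix), `mask` (n x T), `lengths`,
#'   `targets`, and for classification `mapping` (see [encode_labels()]).
#' @export
prepare_sequences <- function(ds, task = c("proxy", "classify"),
                              label_kind = NULL, max_len = 11) {
  task <- match.arg(task)
  stopifnot(inherits(ds, "coda_dataset"))
  if (length(ds$codas) == 0L) stop("empty dataset")
  lens <- vapply(ds$codas, function(cd) length(cd$icis), integer(1))
  if (any(lens > max_len)) {
    stop(sum(lens > max_len), " coda(s) exceed max_len = ", max_len,
         "; filter the dataset first")
  }
  if (task == "proxy") {
    if (any(lens < 2L)) {
      stop("proxy task needs >= 2 ICIs per coda; ", sum(lens < 2L),
           " coda(s) have fewer")
    }
    T_ <- max_len - 1L
    in_len <- lens - 1L
    targets <- vapply(ds$codas, function(cd) cd$icis[length(cd$icis)],
                      numeric(1))
  } else {
    if (is.null(label_kind)) stop("classification needs `label_kind`")
    T_ <- as.integer(max_len)
    in_len <- lens
    enc <- encode_labels(ds, label_kind)
    targets <- enc$labels
  }
  n <- length(ds$codas)
  x <- matrix(0, n, T_)
  mask <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    k <- in_len[i]
    x[i, seq_len(k)] <- ds$codas[[i]]$icis[seq_len(k)]
    mask[i, seq_len(k)] <- 1
  }
  out <- list(x = x, mask = mask, lengths = in_len, targets = targets,
              task = task)
  if (task == "classify") out$mapping <- enc$mapping
  out
}

## Stack backward helper -----------------------------------------------------

rnn_stack_backward <- function(layers, outs, d_h_last) {
  L <- length(layers)
  grads <- vector("list", L)
  d_hs <- NULL
  for (l in rev(seq_len(L))) {
    bk <- rnn_backward(layers[[l]], outs[[l]]$cache,
                       d_hs = d_hs,
                       d_h_last = if (l == L) d_h_last else NULL)
    grads[[l]] <- bk$grads
    d_hs <- bk$d_xs
  }
  grads
}

## Base model ----------------------------------------------------------------

#' Pretrain the recurrent base on the final-interval proxy task
#'
#' Builds the recurrent stack plus a scalar linear output and trains it with
#' Adam to minimize the root-mean-square error of the final-ICI forecast.
#' Reproducible for a fixed `config$seed`; `epochs = 0` returns the seeded
#' initialization untouched.
#'
#' @param ds A [coda_dataset()] whose codas all have between 2 and
#'   `config$max_len` ICIs.
#' @param config A [base_config()].
#' @return A model handle of class `whale_rnn_base` with a `history` of
#'   per-epoch RMSE.
#' @export
pretrain_base <- function(ds, config = base_config()) {
  stopifnot(inherits(config, "base_config"))
  prep <- prepare_sequences(ds, "proxy", max_len = config$max_len)
  set.seed(config$seed)
  layers <- vector("list", config$n_layers)
  d_in <- 1L
  for (l in seq_len(config$n_layers)) {
    layers[[l]] <- rnn_layer_new(config$cell, d_in, config$hidden_units)
    d_in <- config$hidden_units
  }
  out_layer <- nn_dense_new(config$hidden_units, 1L, activation = "linear")
  scale <- if (isTRUE(config$standardize)) {
    v <- prep$x[prep$mask == 1]
    list(center = mean(v), sd = stats::sd(v))
  } else {
    list(center = 0, sd = 1)
  }
  model <- structure(
    list(kind = "rnn_base", config = config, layers = layers,
         out_layer = out_layer, scale = scale, history = NULL),
    class = "whale_rnn_base"
  )
  n <- nrow(prep$x)
  states <- c(lapply(model$layers, function(l) adam_state_new(l$params)),
              list(adam_state_new(model$out_layer$params)))
  step <- 0L
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- nn_minibatches(n, config$batch_size)
    ep_sse <- 0
    for (bi in batches) {
      xb <- (prep$x[bi, , drop = FALSE] - scale$center) / scale$sd
      xs <- seq_to_steps(xb)
      mb <- prep$mask[bi, , drop = FALSE]
      outs <- rnn_stack_forward(model$layers, xs, mb)
      top <- outs[[length(outs)]]$h_last
      fw_out <- nn_dense_forward(model$out_layer, top)
      pred <- fw_out$out[, 1]
      err <- pred - prep$targets[bi]
      rmse <- sqrt(mean(err^2))
      ep_sse <- ep_sse + sum(err^2)
      d_pred <- if (rmse > 0) err / (length(bi) * rmse) else err * 0
      bk_out <- nn_dense_backward(model$out_layer, fw_out$cache,
                                  matrix(d_pred, ncol = 1))
      g_stack <- rnn_stack_backward(model$layers, outs, bk_out$d_in)
      step <- step + 1L
      for (l in seq_along(model$layers)) {
        upd <- adam_step(model$layers[[l]]$params, g_stack[[l]], states[[l]],
                         config$learning_rate, step)
        model$layers[[l]]$params <- upd$params
        states[[l]] <- upd$state
      }
      upd <- adam_step(model$out_layer$params, bk_out$grads,
                       states[[length(states)]], config$learning_rate, step)
      model$out_layer$params <- upd$params
      states[[length(states)]] <- upd$state
    }
    hist[ep] <- sqrt(ep_sse / n)
  }
  model$history <- list(rmse = hist)
  model
}

#' @export
print.whale_rnn_base <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<whale_rnn_base: %d x %s(%d), %d parameters%s>\n",
              x$config$n_layers, x$config$cell, x$config$hidden_units,
              pc$total, if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Predict the final inter-click interval for each coda
#'
#' @param object A `whale_rnn_base`.
#' @param ds A [coda_dataset()] valid for the proxy task.
#' @param ... Unused.
#' @return Numeric vector of predicted final ICIs in seconds.
#' @export
predict.whale_rnn_base <- function(object, ds, ...) {
  prep <- prepare_sequences(ds, "proxy", max_len = object$config$max_len)
  xb <- (prep$x - object$scale$center) / object$scale$sd
  outs <- rnn_stack_forward(object$layers, seq_to_steps(xb), prep$mask)
  nn_dense_forward(object$out_layer, outs[[length(outs)]]$h_last)$out[, 1]
}

#' Mean relative error of predictions, in percent
#'
#' @param predicted Numeric predictions.
#' @param actual Ground-truth values; must be nonzero.
#' @return `mean(|predicted - actual| / actual) * 100`.
#' @export
relative_error_pct <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  if (any(actual == 0)) stop("relative error undefined for zero targets")
  mean(abs(predicted - actual) / actual) * 100
}

#' Proxy-task relative error of a base model on a dataset
#'
#' The mean over codas of |predicted - true| / true for the final ICI,
#' expressed in percent (global mean, not per-batch).
#'
#' @param model A `whale_rnn_base`.
#' @param ds A [coda_dataset()] valid for the proxy task.
#' @return Percentage error (0 = perfect).
#' @export
proxy_relative_error <- function(model, ds) {
  prep <- prepare_sequences(ds, "proxy", max_len = model$config$max_len)
  relative_error_pct(predict(model, ds), prep$targets)
}

## Transfer model ------------------------------------------------------------

#' Build a transfer-learning classifier from a pretrained base
#'
#' Copies the base's recurrent stack and freezes its weights, discards the
#' proxy regression output, and appends a randomly initialized trainable
#' head: one recurrent layer reading the frozen stack's output sequence,
#' ReLU fully connected layers, and an `n_classes`-way softmax.
#'
#' @param base A pretrained `whale_rnn_base`.
#' @param head A [head_config()].
#' @return A model handle of class `whale_rnn_classifier`.
#' @export
build_transfer_model <- function(base, head) {
  stopifnot(inherits(base, "whale_rnn_base"), inherits(head, "head_config"))
  if (head$n_classes < 2L) stop("need at least 2 classes")
  frozen <- lapply(base$layers, function(l) {
    l$trainable <- FALSE
    l
  })
  set.seed(head$seed)
  head_rnn <- rnn_layer_new(base$config$cell, base$config$hidden_units,
                            head$head_hidden_units)
  dense_layers <- list()
  d_in <- head$head_hidden_units
  for (w in head$dense_widths) {
    dense_layers[[length(dense_layers) + 1L]] <-
      nn_dense_new(d_in, w, activation = "relu")
    d_in <- w
  }
  dense_layers[[length(dense_layers) + 1L]] <-
    nn_dense_new(d_in, head$n_classes, activation = "linear")
  structure(
    list(kind = "rnn_classifier", base_config = base$config,
         head_config = head, scale = base$scale, frozen_layers = frozen,
         head_rnn = head_rnn, dense_layers = dense_layers,
         vocab = NULL, history = NULL),
    class = "whale_rnn_classifier"
  )
}

#' @export
print.whale_rnn_classifier <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(
    "<whale_rnn_classifier: %s, %d classes, %d trainable + %d frozen parameters>\n",
    x$base_config$cell, x$head_config$n_classes, pc$trainable, pc$frozen))
  invisible(x)
}

# Frozen-stack forward: returns the top frozen layer's output sequence.
classifier_frozen_sequence <- function(model, prep) {
  xb <- (prep$x - model$scale$center) / model$scale$sd
  outs <- rnn_stack_forward(model$frozen_layers, seq_to_steps(xb), prep$mask)
  outs[[length(outs)]]$hs
}

# Head forward from the frozen sequence; returns probs and caches.
classifier_head_forward <- function(model, frozen_hs, mask) {
  fw_rnn <- rnn_forward(model$head_rnn, frozen_hs, mask)
  cur <- fw_rnn$h_last
  dense_caches <- vector("list", length(model$dense_layers))
  for (i in seq_along(model$dense_layers)) {
    res <- nn_dense_forward(model$dense_layers[[i]], cur)
    dense_caches[[i]] <- res$cache
    cur <- res$out
  }
  list(probs = nn_softmax(cur), rnn = fw_rnn, dense_caches = dense_caches)
}

#' Train the classification head of a transfer model
#'
#' Minimizes categorical cross entropy with Adam, updating only the
#' trainable head; the frozen base parameters are never touched (their
#' output sequences are precomputed once). Deterministic for a fixed
#' `head_config` seed.
#'
#' @param model A [build_transfer_model()] handle.
#' @param ds A labelled [coda_dataset()].
#' @param label_kind `"type"`, `"clan"`, or `"whale"`.
#' @return A list with `model` (trained, with the label vocabulary attached)
#'   and `report` (per-epoch training `loss` and `accuracy`).
#' @export
train_classifier <- function(model, ds, label_kind) {
  stopifnot(inherits(model, "whale_rnn_classifier"))
  head <- model$head_config
  trainable <- c(isTRUE(model$head_rnn$trainable),
                 vapply(model$dense_layers, function(l)
                   isTRUE(l$trainable), logical(1)))
  if (!any(trainable)) stop("model has no trainable parameters")
  prep <- prepare_sequences(ds, "classify", label_kind = label_kind,
                            max_len = model$base_config$max_len)
  vocab <- names(prep$mapping)
  if (length(vocab) != head$n_classes) {
    stop("label vocabulary has ", length(vocab), " classes but the head has ",
         head$n_classes)
  }
  frozen_before <- lapply(model$frozen_layers, `[[`, "params")
  frozen_hs <- classifier_frozen_sequence(model, prep)
  y_idx <- prep$targets + 1L
  n <- nrow(prep$x)
  set.seed(head$seed + 1L)
  states <- c(list(adam_state_new(model$head_rnn$params)),
              lapply(model$dense_layers, function(l) adam_state_new(l$params)))
  step <- 0L
  hist_loss <- hist_acc <- numeric(head$epochs)
  for (ep in seq_len(head$epochs)) {
    batches <- nn_minibatches(n, head$batch_size)
    ep_loss <- ep_correct <- 0
    for (bi in batches) {
      hs_b <- lapply(frozen_hs, function(h) h[bi, , drop = FALSE])
      mb <- prep$mask[bi, , drop = FALSE]
      yb <- nn_one_hot(y_idx[bi], head$n_classes)
      fw <- classifier_head_forward(model, hs_b, mb)
      ep_loss <- ep_loss + nn_cross_entropy(fw$probs, yb) * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(fw$probs, ties.method = "first") == y_idx[bi])
      d_cur <- (fw$probs - yb) / length(bi)
      dense_grads <- vector("list", length(model$dense_layers))
      for (i in rev(seq_along(model$dense_layers))) {
        bk <- nn_dense_backward(model$dense_layers[[i]],
                                fw$dense_caches[[i]], d_cur)
        dense_grads[[i]] <- bk$grads
        d_cur <- bk$d_in
      }
      bk_rnn <- rnn_backward(model$head_rnn, fw$rnn$cache, d_h_last = d_cur)
      step <- step + 1L
      if (isTRUE(model$head_rnn$trainable)) {
        upd <- adam_step(model$head_rnn$params, bk_rnn$grads, states[[1]],
                         head$learning_rate, step)
        model$head_rnn$params <- upd$params
        states[[1]] <- upd$state
      }
      for (i in seq_along(model$dense_layers)) {
        if (!isTRUE(model$dense_layers[[i]]$trainable)) next
        upd <- adam_step(model$dense_layers[[i]]$params, dense_grads[[i]],
                         states[[i + 1L]], head$learning_rate, step)
        model$dense_layers[[i]]$params <- upd$params
        states[[i + 1L]] <- upd$state
      }
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
  }
  stopifnot(identical(frozen_before,
                      lapply(model$frozen_layers, `[[`, "params")))
  model$vocab <- vocab
  report <- list(loss = hist_loss, accuracy = hist_acc,
                 final_accuracy = if (head$epochs > 0)
                   hist_acc[head$epochs] else NA_real_)
  model$history <- report
  list(model = model, report = report)
}

#' Predict class probabilities for codas
#'
#' @param object A trained `whale_rnn_classifier`.
#' @param ds A [coda_dataset()].
#' @param ... Unused.
#' @return An n x n_classes matrix of softmax probabilities; columns follow
#'   the model's label vocabulary.
#' @export
predict.whale_rnn_classifier <- function(object, ds, ...) {
  prep <- pad_icis(ds, object$base_config$max_len)
  frozen_hs <- classifier_frozen_sequence(object, prep)
  fw <- classifier_head_forward(object, frozen_hs, prep$mask)
  colnames(fw$probs) <- object$vocab
  fw$probs
}

# Pad full ICI vectors without requiring labels.
pad_icis <- function(ds, max_len) {
  stopifnot(inherits(ds, "coda_dataset"))
  if (length(ds$codas) == 0L) stop("empty dataset")
  lens <- vapply(ds$codas, function(cd) length(cd$icis), integer(1))
  if (any(lens > max_len)) {
    stop(sum(lens > max_len), " coda(s) exceed max_len = ", max_len,
         "; filter the dataset first")
  }
  x <- matrix(0, length(ds$codas), max_len)
  mask <- matrix(0, length(ds$codas), max_len)
  for (i in seq_along(ds$codas)) {
    x[i, seq_len(lens[i])] <- ds$codas[[i]]$icis
    mask[i, seq_len(lens[i])] <- 1
  }
  list(x = x, mask = mask, lengths = lens)
}

#' Evaluate classification accuracy on a labelled dataset
#'
#' Argmax accuracy; probability ties resolve to the lowest class index.
#' Works for both the full-dataset protocol (pass the training set) and the
#' held-out protocol (pass a disjoint test set).
#'
#' @param model A trained `whale_rnn_classifier`.
#' @param ds A labelled [coda_dataset()].
#' @param label_kind `"type"`, `"clan"`, or `"whale"`.
#' @return Fraction of codas labelled correctly.
#' @export
evaluate_classifier <- function(model, ds, label_kind) {
  stopifnot(inherits(model, "whale_rnn_classifier"))
  if (length(ds$codas) == 0L) stop("empty dataset")
  if (is.null(model$vocab)) stop("classifier has not been trained")
  labs <- coda_labels(ds, label_kind)
  if (any(!labs %in% model$vocab)) {
    stop("dataset contains labels outside the model vocabulary: ",
         paste(utils::head(setdiff(labs, model$vocab), 5), collapse = ", "))
  }
  probs <- predict(model, ds)
  pred <- model$vocab[max.col(probs, ties.method = "first")]
  mean(pred == labs)
}

#' Extract hidden features from a transfer classifier
#'
#' Returns the final-valid-timestep output of the head recurrent layer for
#' every coda (`head_hidden_units` wide, 256 under defaults); deterministic.
#'
#' @param model A `whale_rnn_classifier`.
#' @param ds A [coda_dataset()].
#' @return An n x `head_hidden_units` matrix.
#' @export
extract_hidden_features <- function(model, ds) {
  stopifnot(inherits(model, "whale_rnn_classifier"))
  prep <- pad_icis(ds, model$base_config$max_len)
  frozen_hs <- classifier_frozen_sequence(model, prep)
  rnn_forward(model$head_rnn, frozen_hs, prep$mask)$h_last
}

## Parameter accounting ------------------------------------------------------

#' Count model parameters
#'
#' Exact integer counts by layer traversal, split into trainable and frozen.
#' The closed-form layer counts follow the one-bias-per-gate-set convention:
#' an LSTM layer with input d and hidden H has `4 * (H * (H + d) + H)`
#' parameters, a GRU layer `3 * (H * (H + d) + H)`, and a dense layer with
#' input d and k units `d * k + k`.
#'
#' @param model A `whale_cnn`, `whale_rnn_base`, or `whale_rnn_classifier`.
#' @return A list of class `param_count` with `trainable`, `frozen`,
#'   `total`, and a `by_layer` breakdown.
#' @export
count_parameters <- function(model) {
  collect <- function(layers, tag) {
    lapply(seq_along(layers), function(i) {
      ly <- layers[[i]]
      list(layer = paste0(tag, "_", i, "_", ly$type %||% "layer"),
           count = nn_layer_param_count(ly),
           trainable = !isFALSE(ly$trainable))
    })
  }
  entries <- if (inherits(model, "whale_cnn")) {
    collect(Filter(function(l) length(l$params) > 0, model$layers), "cnn")
  } else if (inherits(model, "whale_rnn_base")) {
    c(collect(model$layers, "rnn"), collect(list(model$out_layer), "out"))
  } else if (inherits(model, "whale_rnn_classifier")) {
    c(collect(model$frozen_layers, "frozen"),
      collect(list(model$head_rnn), "head_rnn"),
      collect(model$dense_layers, "head_dense"))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  trainable <- as.integer(sum(vapply(entries, function(e)
    if (e$trainable) e$count else 0L, numeric(1))))
  frozen <- as.integer(sum(vapply(entries, function(e)
    if (e$trainable) 0L else e$count, numeric(1))))
  by_layer <- data.frame(
    layer = vapply(entries, `[[`, character(1), "layer"),
    parameters = vapply(entries, `[[`, numeric(1), "count"),
    trainable = vapply(entries, `[[`, logical(1), "trainable")
  )
  structure(
    list(trainable = trainable, frozen = frozen, total = trainable + frozen,
         by_layer = by_layer),
    class = "param_count"
  )
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf("parameters: %d total (%d trainable, %d frozen)\n",
              x$total, x$trainable, x$frozen))
  invisible(x)
}
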