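#' CNN configuration for the click / no-click classifier
#'
#' The architecture follows the detector design: `n_blocks` repetitions of a
#' convolution (odd square kernel, 'same' padding) followed by 2x2 max
#' pooling, then a fully connected feature layer, dropout, and a two-way
#' softmax trained under categorical cross entropy. Sigmoid is the hidden
#' activation selected by hyperparameter search; the softmax output is forced
#' by the loss.
#'
#' @param n_blocks Number of conv + max-pool blocks.
#' @param filter_size Convolution kernel side (odd).
#' @param filters_per_block Integer vector of filter counts, recycled to
#'   `n_blocks`.
#' @param dense_units Width of the penultimate fully connected feature layer
#'   (the hidden features used for embedding).
#' @param dropout_rate Dropout fraction applied after the feature layer.
#' @param activation Hidden activation (`"sigmoid"` or `"relu"`).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs Number of training epochs.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_blocks = 3, filter_size = 5,
                       filters_per_block = c(16, 32, 64), dense_units = 80,
                       dropout_rate = 0.5, activation = "sigmoid",
                       batch_size = 64, learning_rate = 1e-3, epochs = 50,
                       seed = 1L) {
  stopifnot(n_blocks >= 1, filter_size >= 1, filter_size %% 2 == 1,
            dropout_rate >= 0, dropout_rate < 1, epochs >= 0,
            batch_size >= 1, learning_rate > 0)
  filters_per_block <- rep_len(as.integer(filters_per_block), n_blocks)
  structure(
    list(n_blocks = as.integer(n_blocks), filter_size = as.integer(filter_size),
         filters_per_block = filters_per_block,
         dense_units = as.integer(dense_units), dropout_rate = dropout_rate,
         activation = activation, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

#' Build the click CNN
#'
#' @param config A [cnn_config()].
#' @param input_shape Length-2 vector (height, width) of the input images.
#' @return A model handle of class `whale_cnn` with deterministic seeded
#'   initialization; all parameters trainable.
#' @export
build_cnn <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 2L)
  h <- as.integer(input_shape[1]); w <- as.integer(input_shape[2])
  set.seed(config$seed)
  layers <- list()
  in_ch <- 1L
  for (b in seq_len(config$n_blocks)) {
    if (h < 2L || w < 2L) {
      stop("input ", input_shape[1], "x", input_shape[2], " too small for ",
           config$n_blocks, " pooling stages")
    }
    layers[[length(layers) + 1L]] <-
      nn_conv_new(in_ch, config$filters_per_block[b], config$filter_size,
                  activation = config$activation)
    layers[[length(layers) + 1L]] <- list(type = "pool", params = list())
    in_ch <- config$filters_per_block[b]
    h <- h %/% 2L; w <- w %/% 2L
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten", params = list())
  flat <- h * w * in_ch
  layers[[length(layers) + 1L]] <-
    nn_dense_new(flat, config$dense_units, activation = config$activation)
  layers[[length(layers) + 1L]] <-
    list(type = "dropout", rate = config$dropout_rate, params = list())
  layers[[length(layers) + 1L]] <-
    nn_dense_new(config$dense_units, 2L, activation = "linear")
  structure(
    list(kind = "cnn", config = config, input_shape = c(input_shape[1], input_shape[2]),
         layers = layers, history = NULL),
    class = "whale_cnn"
  )
}

#' @export
print.whale_cnn <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<whale_cnn: %d blocks, %dx%d input, %d parameters%s>\n",
              x$config$n_blocks, x$input_shape[1], x$input_shape[2], pc$total,
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# Forward pass; returns logits and per-layer caches. `training` enables
# dropout (which consumes RNG).
cnn_forward <- function(model, x, training = FALSE, upto = NULL) {
  caches <- vector("list", length(model$layers))
  cur <- x
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    res <- switch(ly$type,
      conv = nn_conv_forward(ly, cur),
      pool = nn_pool_forward(cur),
      flatten = {
        d <- dim(cur)
        list(out = matrix(cur, nrow = d[1]), cache = d)
      },
      dense = nn_dense_forward(ly, cur),
      dropout = nn_dropout_forward(cur, ly$rate, training)
    )
    caches[[i]] <- res$cache
    cur <- res$out
    if (!is.null(upto) && i == upto) return(list(out = cur, caches = caches))
  }
  list(out = cur, caches = caches)
}

cnn_backward <- function(model, caches, d_out) {
  grads <- vector("list", length(model$layers))
  cur <- d_out
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      bk <- nn_conv_backward(ly, caches[[i]], cur)
      grads[[i]] <- bk$grads
      cur <- bk$d_in
    } else if (ly$type == "pool") {
      cur <- nn_pool_backward(caches[[i]], cur)
    } else if (ly$type == "flatten") {
      cur <- array(cur, caches[[i]])
    } else if (ly$type == "dense") {
      bk <- nn_dense_backward(ly, caches[[i]], cur)
      grads[[i]] <- bk$grads
      cur <- bk$d_in
    } else if (ly$type == "dropout") {
      cur <- nn_dropout_backward(caches[[i]], cur)
    }
  }
  grads
}

cnn_check_dataset <- function(dataset) {
  if (is.null(dataset$x) || length(dim(dataset$x)) != 4L ||
      dim(dataset$x)[1] == 0L) {
    stop("dataset must contain a non-empty 4-d image array `x`")
  }
  if (length(dataset$labels) != dim(dataset$x)[1]) {
    stop("dataset labels must match the number of images")
  }
}

#' Train the click CNN
#'
#' Minimizes categorical cross entropy with Adam. Training is fully
#' deterministic for a fixed `config$seed` on one machine: initialization,
#' shuffling and dropout all draw from the seeded RNG.
#'
#' @param model A [build_cnn()] handle.
#' @param dataset List with `x` (n x h x w x 1 array) and `labels` (factor
#'   with two levels).
#' @param config Optional [cnn_config()] override; defaults to the model's.
#' @return A list with `model` (trained) and `report` (per-epoch `loss` and
#'   `accuracy` on the training data, plus `final_accuracy`).
#' @export
train_cnn <- function(model, dataset, config = model$config) {
  stopifnot(inherits(model, "whale_cnn"))
  cnn_check_dataset(dataset)
  y_idx <- as.integer(dataset$labels)
  n <- dim(dataset$x)[1]
  set.seed(config$seed + 1L)
  states <- lapply(model$layers, function(ly)
    if (length(ly$params)) adam_state_new(ly$params) else NULL)
  step <- 0L
  hist_loss <- hist_acc <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- nn_minibatches(n, config$batch_size)
    ep_loss <- ep_correct <- 0
    for (bi in batches) {
      xb <- dataset$x[bi, , , , drop = FALSE]
      yb <- nn_one_hot(y_idx[bi], 2L)
      fw <- cnn_forward(model, xb, training = TRUE)
      p <- nn_softmax(fw$out)
      ep_loss <- ep_loss + nn_cross_entropy(p, yb) * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(p, ties.method = "first") == y_idx[bi])
      grads <- cnn_backward(model, fw$caches, (p - yb) / length(bi))
      step <- step + 1L
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]]) || !isTRUE(model$layers[[i]]$trainable)) next
        upd <- adam_step(model$layers[[i]]$params, grads[[i]], states[[i]],
                         config$learning_rate, step)
        model$layers[[i]]$params <- upd$params
        states[[i]] <- upd$state
      }
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
  }
  report <- list(loss = hist_loss, accuracy = hist_acc,
                 final_accuracy = if (config$epochs > 0)
                   hist_acc[config$epochs] else NA_real_)
  model$history <- report
  list(model = model, report = report)
}

#' Predict class probabilities with the click CNN
#'
#' Dropout is disabled at inference, so repeated calls give identical output.
#'
#' @param object A `whale_cnn` model.
#' @param x Image array (n x h x w x 1).
#' @param ... Unused.
#' @return An n x 2 matrix of softmax probabilities (columns follow the
#'   training label levels: click, no_click).
#' @export
predict.whale_cnn <- function(object, x, ...) {
  nn_softmax(cnn_forward(object, x, training = FALSE)$out)
}

#' Evaluate classification accuracy of the click CNN
#'
#' @param model A trained `whale_cnn`.
#' @param dataset List with `x` and `labels`, as in [train_cnn()].
#' @return Fraction of argmax predictions equal to the labels.
#' @export
evaluate_cnn <- function(model, dataset) {
  cnn_check_dataset(dataset)
  p <- predict(model, dataset$x)
  mean(max.col(p, ties.method = "first") == as.integer(dataset$labels))
}

#' Extract hidden features from the click CNN
#'
#' Returns the activations of the penultimate fully connected layer
#' (`dense_units` wide, 80 under defaults), with dropout disabled — the
#' high-dimensional hidden features used for PCA / t-SNE inspection.
#'
#' @param model A `whale_cnn`.
#' @param x Image array (n x h x w x 1).
#' @return An n x `dense_units` matrix.
#' @export
extract_cnn_features <- function(model, x) {
  feat_idx <- max(which(vapply(model$layers, function(l)
    l$type == "dense", logical(1)))) - 2L  # dense feature layer precedes dropout+output
  cnn_forward(model, x, training = FALSE, upto = feat_idx)$out
}

#' Exhaustive grid search over CNN hyperparameters
#'
#' Trains one model per combination of the supplied candidate values (all
#' other settings taken from `base_config`) and selects the configuration
#' with the highest held-out accuracy; ties go to the first combination in
#' lexicographic grid order.
#'
#' @param grid Named list mapping `cnn_config` field names to candidate
#'   value vectors.
#' @param dataset Training dataset (list with `x`, `labels`).
#' @param eval_dataset Held-out dataset used for model selection.
#' @param base_config Defaults for fields not in the grid.
#' @return A list with `best_config`, `best_accuracy`, and `results` (one
#'   row per combination with its held-out accuracy).
#' @export
cnn_grid_search <- function(grid, dataset, eval_dataset,
                            base_config = cnn_config()) {
  stopifnot(length(grid) >= 1, !is.null(names(grid)))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  accs <- numeric(nrow(combos))
  input_shape <- dim(dataset$x)[2:3]
  for (i in seq_len(nrow(combos))) {
    cfg <- unclass(base_config)
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    cfg <- do.call(cnn_config, cfg)
    fit <- train_cnn(build_cnn(cfg, input_shape), dataset, cfg)
    accs[i] <- evaluate_cnn(fit$model, eval_dataset)
  }
  best <- which.max(accs)  # first maximum = lexicographic tie-break
  cfg <- unclass(base_config)
  for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][best]
  best_cfg <- do.call(cnn_config, cfg)
  list(
    best_config = best_cfg,
    best_accuracy = accs[best],
    results = cbind(combos, accuracy = accs)
  )
}
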