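# Internal 2-D convolution / pooling primitives for the click CNN.
# Images are arrays of shape (batch, height, width, channels). Convolutions
# use odd square kernels with 'same' zero padding; pooling is 2x2 stride 2
# with any odd trailing row/column dropped.

# Unfold k x k patches into a (B*H*W) x (k*k*C) matrix. Column blocks are
# ordered by kernel offset (row-major over the kernel), channels within a
# block; nn_col2im must mirror this ordering exactly.
nn_im2col <- function(x, k) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(B, H + 2 * p, W + 2 * p, C))
  xp[, p + seq_len(H), p + seq_len(W), ] <- x
  cols <- vector("list", k * k)
  i <- 1L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      s <- xp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE]
      cols[[i]] <- matrix(s, nrow = B * H * W)
      i <- i + 1L
    }
  }
  do.call(cbind, cols)
}

nn_col2im <- function(dcols, dimx, k) {
  B <- dimx[1]; H <- dimx[2]; W <- dimx[3]; C <- dimx[4]
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(B, H + 2 * p, W + 2 * p, C))
  i <- 1L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      blk <- array(dcols[, ((i - 1L) * C + 1L):(i * C)], c(B, H, W, C))
      dxp[, di + seq_len(H), dj + seq_len(W), ] <-
        dxp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE] + blk
      i <- i + 1L
    }
  }
  dxp[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

nn_conv_new <- function(in_channels, filters, k, activation = "sigmoid",
                        trainable = TRUE) {
  fan_in <- k * k * in_channels
  list(
    type = "conv",
    k = k,
    activation = activation,
    trainable = trainable,
    params = list(
      W = nn_glorot(fan_in, filters),
      b = rep(0, filters)
    )
  )
}

nn_conv_forward <- function(layer, x) {
  d <- dim(x)
  cols <- nn_im2col(x, layer$k)
  z <- cols %*% layer$params$W
  z <- sweep(z, 2L, layer$params$b, "+")
  out <- array(nn_act(z, layer$activation),
               c(d[1], d[2], d[3], ncol(layer$params$W)))
  list(out = out, cache = list(cols = cols, dimx = d, out = out))
}

nn_conv_backward <- function(layer, cache, d_out) {
  d <- cache$dimx
  f <- ncol(layer$params$W)
  dz <- matrix(d_out, nrow = d[1] * d[2] * d[3]) *
    nn_act_grad(matrix(cache$out, nrow = d[1] * d[2] * d[3]), layer$activation)
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dcols <- dz %*% t(layer$params$W)
  list(
    grads = list(W = dW, b = db),
    d_in = nn_col2im(dcols, d, layer$k)
  )
}

## Max pooling ---------------------------------------------------------------

nn_pool_forward <- function(x) {
  d <- dim(x)
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  if (H2 < 1L || W2 < 1L) {
    stop("input too small to max-pool: ", d[2], "x", d[3])
  }
  ri <- seq_len(2L * H2); ci <- seq_len(2L * W2)
  slices <- list(
    x[, ri[ri %% 2 == 1], ci[ci %% 2 == 1], , drop = FALSE],
    x[, ri[ri %% 2 == 0], ci[ci %% 2 == 1], , drop = FALSE],
    x[, ri[ri %% 2 == 1], ci[ci %% 2 == 0], , drop = FALSE],
    x[, ri[ri %% 2 == 0], ci[ci %% 2 == 0], , drop = FALSE]
  )
  best <- slices[[1]]
  which_max <- array(1L, dim(best))
  for (j in 2:4) {
    upd <- slices[[j]] > best
    which_max[upd] <- j
    best[upd] <- slices[[j]][upd]
  }
  list(out = best, cache = list(which_max = which_max, dimx = d))
}

nn_pool_backward <- function(cache, d_out) {
  d <- cache$dimx
  dx <- array(0, d)
  H2 <- dim(d_out)[2]; W2 <- dim(d_out)[3]
  ri <- seq_len(2L * H2); ci <- seq_len(2L * W2)
  rows <- list(ri[ri %% 2 == 1], ri[ri %% 2 == 0], ri[ri %% 2 == 1], ri[ri %% 2 == 0])
  colsl <- list(ci[ci %% 2 == 1], ci[ci %% 2 == 1], ci[ci %% 2 == 0], ci[ci %% 2 == 0])
  for (j in 1:4) {
    contrib <- d_out * (cache$which_max == j)
    dx[, rows[[j]], colsl[[j]], ] <-
      dx[, rows[[j]], colsl[[j]], , drop = FALSE] + contrib
  }
  dx
}

## Dropout -------------------------------------------------------------------

nn_dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

nn_dropout_backward <- function(cache, d_out) {
  if (is.null(cache)) d_out else d_out * cache
}
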