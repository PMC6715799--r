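# Internal recurrent layers (LSTM / GRU) with masking for post-padded
# variable-length sequences. Sequences are passed as lists of T matrices of
# shape (batch x input_dim); the mask is a (batch x T) 0/1 matrix. Masked
# steps carry the previous hidden (and cell) state forward, so after all T
# steps the state equals the state at each sequence's last valid step.
#
# Gate blocks are concatenated column-wise: LSTM order (i, f, g, o), GRU
# order (z, r, n). One bias vector per gate set, so a layer with input d and
# hidden H has 4*(H*(H+d)+H) parameters (LSTM) or 3*(H*(H+d)+H) (GRU).

rnn_layer_new <- function(cell = c("LSTM", "GRU"), input_dim, hidden,
                          trainable = TRUE) {
  cell <- match.arg(cell)
  gates <- if (cell == "LSTM") 4L else 3L
  list(
    type = "rnn",
    cell = cell,
    hidden = hidden,
    trainable = trainable,
    params = list(
      Wx = nn_glorot(input_dim, gates * hidden),
      Wh = nn_glorot(hidden, gates * hidden),
      b = rep(0, gates * hidden)
    )
  )
}

rnn_forward <- function(layer, xs, mask) {
  if (layer$cell == "LSTM") lstm_forward(layer, xs, mask)
  else gru_forward(layer, xs, mask)
}

rnn_backward <- function(layer, cache, d_hs = NULL, d_h_last = NULL) {
  if (layer$cell == "LSTM") lstm_backward(layer, cache, d_hs, d_h_last)
  else gru_backward(layer, cache, d_hs, d_h_last)
}

gate_cols <- function(h, j) ((j - 1L) * h + 1L):(j * h)

## LSTM ----------------------------------------------------------------------

lstm_forward <- function(layer, xs, mask) {
  H <- layer$hidden
  B <- nrow(xs[[1]])
  T_ <- length(xs)
  h <- matrix(0, B, H)
  cst <- matrix(0, B, H)
  hs <- gates <- cs_pre <- cs_prev <- hs_prev <- vector("list", T_)
  for (t in seq_len(T_)) {
    m <- mask[, t]
    a <- xs[[t]] %*% layer$params$Wx + h %*% layer$params$Wh
    a <- sweep(a, 2L, layer$params$b, "+")
    i <- nn_sigmoid(a[, gate_cols(H, 1), drop = FALSE])
    f <- nn_sigmoid(a[, gate_cols(H, 2), drop = FALSE])
    g <- tanh(a[, gate_cols(H, 3), drop = FALSE])
    o <- nn_sigmoid(a[, gate_cols(H, 4), drop = FALSE])
    c_tilde <- f * cst + i * g
    h_tilde <- o * tanh(c_tilde)
    hs_prev[[t]] <- h
    cs_prev[[t]] <- cst
    h <- m * h_tilde + (1 - m) * h
    cst <- m * c_tilde + (1 - m) * cst
    hs[[t]] <- h
    gates[[t]] <- list(i = i, f = f, g = g, o = o)
    cs_pre[[t]] <- c_tilde
  }
  list(
    hs = hs, h_last = h,
    cache = list(xs = xs, mask = mask, gates = gates, cs_pre = cs_pre,
                 cs_prev = cs_prev, hs_prev = hs_prev, B = B, T_ = T_)
  )
}

lstm_backward <- function(layer, cache, d_hs = NULL, d_h_last = NULL) {
  H <- layer$hidden
  B <- cache$B; T_ <- cache$T_
  dWx <- layer$params$Wx * 0
  dWh <- layer$params$Wh * 0
  db <- layer$params$b * 0
  dh_next <- if (is.null(d_h_last)) matrix(0, B, H) else d_h_last
  dc_next <- matrix(0, B, H)
  dxs <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    m <- cache$mask[, t]
    if (!is.null(d_hs)) dh_next <- dh_next + d_hs[[t]]
    gt <- cache$gates[[t]]
    tanh_c <- tanh(cache$cs_pre[[t]])
    dh_t <- m * dh_next          # through the updated state
    dh_carry <- (1 - m) * dh_next
    dc_t <- m * dc_next
    dc_carry <- (1 - m) * dc_next
    do <- dh_t * tanh_c
    dc <- dc_t + dh_t * gt$o * (1 - tanh_c^2)
    di <- dc * gt$g
    df <- dc * cache$cs_prev[[t]]
    dg <- dc * gt$i
    da <- cbind(
      di * gt$i * (1 - gt$i),
      df * gt$f * (1 - gt$f),
      dg * (1 - gt$g^2),
      do * gt$o * (1 - gt$o)
    )
    dWx <- dWx + crossprod(cache$xs[[t]], da)
    dWh <- dWh + crossprod(cache$hs_prev[[t]], da)
    db <- db + colSums(da)
    dxs[[t]] <- da %*% t(layer$params$Wx)
    dh_next <- da %*% t(layer$params$Wh) + dh_carry
    dc_next <- dc * gt$f + dc_carry
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), d_xs = dxs)
}

## GRU -----------------------------------------------------------------------

gru_forward <- function(layer, xs, mask) {
  H <- layer$hidden
  B <- nrow(xs[[1]])
  T_ <- length(xs)
  h <- matrix(0, B, H)
  hs <- gates <- hs_prev <- vector("list", T_)
  for (t in seq_len(T_)) {
    m <- mask[, t]
    ax <- xs[[t]] %*% layer$params$Wx
    ah <- h %*% layer$params$Wh
    z <- nn_sigmoid(sweep(ax[, gate_cols(H, 1), drop = FALSE] +
                          ah[, gate_cols(H, 1), drop = FALSE],
                          2L, layer$params$b[gate_cols(H, 1)], "+"))
    r <- nn_sigmoid(sweep(ax[, gate_cols(H, 2), drop = FALSE] +
                          ah[, gate_cols(H, 2), drop = FALSE],
                          2L, layer$params$b[gate_cols(H, 2)], "+"))
    q <- ah[, gate_cols(H, 3), drop = FALSE]
    n <- tanh(sweep(ax[, gate_cols(H, 3), drop = FALSE] + r * q,
                    2L, layer$params$b[gate_cols(H, 3)], "+"))
    h_tilde <- (1 - z) * n + z * h
    hs_prev[[t]] <- h
    h <- m * h_tilde + (1 - m) * h
    hs[[t]] <- h
    gates[[t]] <- list(z = z, r = r, n = n, q = q)
  }
  list(
    hs = hs, h_last = h,
    cache = list(xs = xs, mask = mask, gates = gates, hs_prev = hs_prev,
                 B = B, T_ = T_)
  )
}

gru_backward <- function(layer, cache, d_hs = NULL, d_h_last = NULL) {
  H <- layer$hidden
  B <- cache$B; T_ <- cache$T_
  dWx <- layer$params$Wx * 0
  dWh <- layer$params$Wh * 0
  db <- layer$params$b * 0
  dh_next <- if (is.null(d_h_last)) matrix(0, B, H) else d_h_last
  dxs <- vector("list", T_)
  Wxz <- layer$params$Wx[, gate_cols(H, 1), drop = FALSE]
  Wxr <- layer$params$Wx[, gate_cols(H, 2), drop = FALSE]
  Wxn <- layer$params$Wx[, gate_cols(H, 3), drop = FALSE]
  Whz <- layer$params$Wh[, gate_cols(H, 1), drop = FALSE]
  Whr <- layer$params$Wh[, gate_cols(H, 2), drop = FALSE]
  Whn <- layer$params$Wh[, gate_cols(H, 3), drop = FALSE]
  for (t in rev(seq_len(T_))) {
    m <- cache$mask[, t]
    if (!is.null(d_hs)) dh_next <- dh_next + d_hs[[t]]
    gt <- cache$gates[[t]]
    h_prev <- cache$hs_prev[[t]]
    dh_t <- m * dh_next
    dh_carry <- (1 - m) * dh_next
    dn <- dh_t * (1 - gt$z)
    dz <- dh_t * (h_prev - gt$n)
    dan <- dn * (1 - gt$n^2)
    dq <- dan * gt$r
    dr <- dan * gt$q
    daz <- dz * gt$z * (1 - gt$z)
    dar <- dr * gt$r * (1 - gt$r)
    dWx[, gate_cols(H, 1)] <- dWx[, gate_cols(H, 1), drop = FALSE] +
      crossprod(cache$xs[[t]], daz)
    dWx[, gate_cols(H, 2)] <- dWx[, gate_cols(H, 2), drop = FALSE] +
      crossprod(cache$xs[[t]], dar)
    dWx[, gate_cols(H, 3)] <- dWx[, gate_cols(H, 3), drop = FALSE] +
      crossprod(cache$xs[[t]], dan)
    dWh[, gate_cols(H, 1)] <- dWh[, gate_cols(H, 1), drop = FALSE] +
      crossprod(h_prev, daz)
    dWh[, gate_cols(H, 2)] <- dWh[, gate_cols(H, 2), drop = FALSE] +
      crossprod(h_prev, dar)
    dWh[, gate_cols(H, 3)] <- dWh[, gate_cols(H, 3), drop = FALSE] +
      crossprod(h_prev, dq)
    db[gate_cols(H, 1)] <- db[gate_cols(H, 1)] + colSums(daz)
    db[gate_cols(H, 2)] <- db[gate_cols(H, 2)] + colSums(dar)
    db[gate_cols(H, 3)] <- db[gate_cols(H, 3)] + colSums(dan)
    dxs[[t]] <- daz %*% t(Wxz) + dar %*% t(Wxr) + dan %*% t(Wxn)
    dh_next <- dh_t * gt$z + daz %*% t(Whz) + dar %*% t(Whr) +
      dq %*% t(Whn) + dh_carry
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), d_xs = dxs)
}

## Stack helpers -------------------------------------------------------------

# Forward a list of rnn layers; xs is the input sequence (list of B x d).
# Returns per-layer forward results.
rnn_stack_forward <- function(layers, xs, mask) {
  outs <- vector("list", length(layers))
  cur <- xs
  for (l in seq_along(layers)) {
    outs[[l]] <- rnn_forward(layers[[l]], cur, mask)
    cur <- outs[[l]]$hs
  }
  outs
}

# Convert a padded (batch x T) value matrix into a list of T column matrices.
seq_to_steps <- function(x) {
  lapply(seq_len(ncol(x)), function(t) x[, t, drop = FALSE])
}
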