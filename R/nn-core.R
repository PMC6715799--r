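# Internal neural-network engine: initialization, activations, dense layers,
# and the Adam optimizer. One training example per row throughout. All
# randomness goes through R's RNG so callers control determinism with
# set.seed().

nn_glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_act <- function(x, name) {
  switch(name,
    sigmoid = nn_sigmoid(x),
    relu    = pmax(x, 0),
    tanh    = tanh(x),
    linear  = x,
    stop("unknown activation: ", name)
  )
}

# Derivative expressed in terms of the activation *output* y = act(x).
nn_act_grad <- function(y, name) {
  switch(name,
    sigmoid = y * (1 - y),
    relu    = (y > 0) + 0,
    tanh    = 1 - y^2,
    linear  = 1,
    stop("unknown activation: ", name)
  )
}

nn_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Mean categorical cross entropy for one-hot targets y (same shape as p).
nn_cross_entropy <- function(p, y) {
  -mean(rowSums(y * log(pmax(p, 1e-12))))
}

nn_one_hot <- function(idx, k) {
  y <- matrix(0, length(idx), k)
  y[cbind(seq_along(idx), idx)] <- 1
  y
}

## Dense layer ---------------------------------------------------------------

nn_dense_new <- function(input_dim, units, activation = "sigmoid",
                         trainable = TRUE) {
  list(
    type = "dense",
    activation = activation,
    trainable = trainable,
    params = list(
      W = nn_glorot(input_dim, units),
      b = rep(0, units)
    )
  )
}

nn_dense_forward <- function(layer, x) {
  z <- x %*% layer$params$W
  z <- sweep(z, 2L, layer$params$b, "+")
  out <- nn_act(z, layer$activation)
  list(out = out, cache = list(x = x, out = out))
}

# d_out is the gradient w.r.t. the layer output (post-activation).
nn_dense_backward <- function(layer, cache, d_out) {
  dz <- d_out * nn_act_grad(cache$out, layer$activation)
  list(
    grads = list(W = crossprod(cache$x, dz), b = colSums(dz)),
    d_in = dz %*% t(layer$params$W)
  )
}

## Adam ----------------------------------------------------------------------

adam_state_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# Returns list(params, state); `t` is the 1-based global step counter.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    m_hat <- st$m / (1 - beta1^t)
    v_hat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# Deterministic minibatch index generator: a seeded shuffle split into
# batches; the last batch may be smaller.
nn_minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Count parameters of one engine layer.
nn_layer_param_count <- function(layer) {
  sum(vapply(layer$params, length, integer(1)))
}
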