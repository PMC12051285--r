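# Minimal dense-network machinery: Glorot initialization, multilayer
# perceptrons with ReLU and inverted dropout, analytic backprop, and Adam.
# Written against plain base-R matrices; every parameter set is a (nested)
# named list of matrices/vectors so the optimizer can walk it generically.

glorot <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

# MLP parameters: list of layers, each list(W, b). Hidden activations are
# rectified; the final layer is linear (caller applies sigmoid/identity).
mlp_init <- function(dims) {
  stopifnot(length(dims) >= 2L)
  lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = glorot(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
  })
}

# x: n x d_in matrix. Inverted dropout on hidden activations when training.
mlp_forward <- function(layers, x, drop_p = 0, training = FALSE) {
  acts <- list(x)
  masks <- vector("list", length(layers))
  a <- x
  for (i in seq_along(layers)) {
    z <- a %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(a), length(layers[[i]]$b), byrow = TRUE)
    if (i < length(layers)) {
      a <- relu(z)
      if (training && drop_p > 0) {
        m <- matrix(stats::rbinom(length(a), 1, 1 - drop_p) / (1 - drop_p),
                    nrow(a), ncol(a))
        a <- a * m
        masks[[i]] <- m
      }
    } else {
      a <- z
    }
    acts[[i + 1L]] <- a
  }
  list(out = a, acts = acts, masks = masks)
}

# dout: gradient at the (linear) output. Returns parameter grads + dx.
mlp_backward <- function(layers, cache, dout) {
  grads <- vector("list", length(layers))
  da <- dout
  for (i in rev(seq_along(layers))) {
    a_in <- cache$acts[[i]]
    if (i < length(layers)) {
      # undo dropout then the rectifier (post-activation cached)
      if (!is.null(cache$masks[[i]])) da <- da * cache$masks[[i]]
      da <- da * (cache$acts[[i + 1L]] > 0)
    }
    grads[[i]] <- list(W = t(a_in) %*% da, b = colSums(da))
    da <- da %*% t(layers[[i]]$W)
  }
  list(grads = grads, dx = da)
}

# ---------------------------------------------------------------------------
# Adam over arbitrary nested lists of numeric arrays

walk_zero <- function(p) {
  if (is.list(p)) lapply(p, walk_zero) else p * 0
}

walk_binary <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(walk_binary, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

adam_init <- function(params) {
  list(m = walk_zero(params), v = walk_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- walk_binary(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk_binary(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- walk_binary(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- walk_binary(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

walk_add <- function(a, b) walk_binary(a, b, `+`)
walk_scale <- function(a, s) {
  if (is.list(a)) lapply(a, walk_scale, s = s) else a * s
}

sigmoid <- function(x) 1 / (1 + exp(-x))
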