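# Low-level neural-network primitives shared by the encoder, the SLL head,
# the probing classifiers and the pre-training loop. Everything operates on
# plain double matrices; forward passes return the caches their backward
# counterparts need.

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Layer normalisation over the feature (column) dimension of an n x H matrix.
layernorm_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, `*`)
  y <- sweep(y, 2L, b, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

# Backward through a row-wise softmax: given probabilities p and upstream dP.
softmax_rows_backward <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

# ---- Adam optimiser over arbitrarily nested lists of numeric arrays -------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else array(0, dim = dim(x) %||% length(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"),
                    t = t))
}

# Elementwise sum of two congruent nested parameter lists.
params_add <- function(a, b) {
  if (is.list(a)) Map(params_add, a, b) else a + b
}

# A nested list of zeros shaped like `params`.
params_zero <- function(params) {
  if (is.list(params)) lapply(params, params_zero)
  else array(0, dim = dim(params) %||% length(params))
}

# Softmax cross-entropy head: logits is n x C, target is integer class 1..C.
# Returns mean loss and gradient w.r.t. logits.
softmax_xent <- function(logits, target) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), target)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
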