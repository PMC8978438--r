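# Scalar-mix edge probing. A probing classifier P_tau^l sees a learned
# softmax-weighted mixture of layers 0..l at every position,
# h_{i,l} = gamma_l * sum_k alpha_l^k h_i^k, concatenated across positions
# and fed to a two-layer perceptron. The encoder activations are frozen:
# only the mixing parameters and the perceptron train. The knowledge delta
# Delta_tau^l = Score(P_tau^l) - Score(P_tau^{l-1}) measures the
# information contributed by layer l alone; the deltas telescope to
# Score(P_tau^L) - Score(P_tau^0).

#' Scalar mix of layers 0..l
#'
#' @param acts a `layer_activations` object (hidden array
#'   `(n, L+1, N, H)`).
#' @param params list with `gamma` (scalar gain) and `raw` (unnormalized
#'   mixing scores, length `l + 1`; softmax-normalized at use time).
#' @param l top layer of the mix (0..L).
#' @return numeric array `(n, N, H)` of mixed per-position vectors.
#' @export
scalar_mix <- function(acts, params, l) {
  d <- dim(acts$hidden)
  assert_that(l >= 0L && l <= d[2] - 1L, "l exceeds the layer count")
  assert_that(length(params$raw) == l + 1L,
              "parameter count must equal l + 1")
  alpha <- softmax_vec(params$raw)
  out <- array(0, dim = d[c(1, 3, 4)])
  for (k in 0:l) {
    out <- out + alpha[k + 1L] * array(acts$hidden[, k + 1L, , ],
                                       dim = d[c(1, 3, 4)])
  }
  params$gamma * out
}

#' Probe hyperparameters
#'
#' Defaults follow the full-scale recipe: a two-layer perceptron with 1024
#' hidden units, learning rate 2e-5, 4 training epochs. Desk-scale runs
#' shrink the hidden layer and raise the learning rate via the `tiny`
#' preset. `heldout` is the fraction of instances reserved for scoring
#' (0.5 keeps per-layer scores stable enough that knowledge deltas are not
#' dominated by evaluation noise at desk-scale n).
#'
#' @param hidden perceptron hidden units.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch mini-batch size.
#' @param heldout held-out fraction in (0, 1).
#' @export
probe_config <- function(hidden = 1024L, lr = 2e-5, epochs = 4L,
                         batch = 32L, heldout = 0.5) {
  assert_that(heldout > 0 && heldout < 1, "heldout must be in (0, 1)")
  structure(list(hidden = as.integer(hidden), lr = lr,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 heldout = heldout),
            class = "probe_config")
}

# Flatten per-layer activations to n x (N*H) matrices, one per layer.
flatten_layers <- function(acts) {
  d <- dim(acts$hidden)
  lapply(seq_len(d[2]), function(k) {
    matrix(acts$hidden[, k, , ], d[1], d[3] * d[4])
  })
}

probe_forward <- function(Xk, idx, pp) {
  alpha <- softmax_vec(as.vector(pp$raw))
  M <- 0
  for (k in seq_along(Xk)) M <- M + alpha[k] * Xk[[k]][idx, , drop = FALSE]
  M <- as.vector(pp$gamma) * M
  Z1 <- tanh(sweep(M %*% pp$W1, 2L, pp$b1, `+`))
  logits <- sweep(Z1 %*% pp$W2, 2L, pp$b2, `+`)
  list(M = M, Z1 = Z1, logits = logits, alpha = alpha)
}

#' Train a probing classifier on frozen activations
#'
#' Trains the scalar-mix parameters and the two-layer perceptron jointly
#' with Adam on a stratified training split, then reports the score
#' (binary F1 for single-positive schemes, micro F1 over non-negative
#' classes otherwise) on the held-out split. The activations themselves
#' are data: no gradient reaches them, which realises the frozen-encoder
#' contract.
#'
#' @param acts a `layer_activations` object.
#' @param labels character labels, members of `scheme$labels`.
#' @param l top layer of the scalar mix (0..L).
#' @param scheme a [label_scheme()].
#' @param hyper a [probe_config()].
#' @param seed RNG seed (split and initialisation).
#' @return list of class `probe_result`: `score`, `alpha` (learned
#'   normalized mixing weights), `gamma`, `params`, `l`, `heldout_idx`.
#' @export
train_probe <- function(acts, labels, l, scheme, hyper = probe_config(),
                        seed = 1L) {
  d <- dim(acts$hidden)
  assert_that(l >= 0L && l <= d[2] - 1L, "l exceeds the layer count")
  n <- d[1]
  din <- d[3] * d[4]
  C <- length(scheme$labels)
  target <- match(labels, scheme$labels)
  assert_that(!anyNA(target), "labels outside the scheme")
  Xk <- flatten_layers(acts)[seq_len(l + 1L)]
  local_seed(seed, {
    heldout_idx <- sort(sample.int(n, round(hyper$heldout * n)))
    train_idx <- setdiff(seq_len(n), heldout_idx)
    pp <- list(raw = rep(0, l + 1L), gamma = 1,
               W1 = init_mat(din, hyper$hidden), b1 = rep(0, hyper$hidden),
               W2 = init_mat(hyper$hidden, C), b2 = rep(0, C))
    opt <- adam_init(pp)
    for (epoch in seq_len(hyper$epochs)) {
      perm <- train_idx[sample.int(length(train_idx))]
      for (s in seq(1L, length(perm), by = hyper$batch)) {
        idx <- perm[s:min(s + hyper$batch - 1L, length(perm))]
        fw <- probe_forward(Xk, idx, pp)
        ce <- softmax_xent(fw$logits, target[idx])
        g <- params_zero(pp)
        g$W2 <- t(fw$Z1) %*% ce$dlogits
        g$b2 <- colSums(ce$dlogits)
        dZ1 <- ce$dlogits %*% t(pp$W2)
        dpre <- dZ1 * (1 - fw$Z1 * fw$Z1)
        g$W1 <- t(fw$M) %*% dpre
        g$b1 <- colSums(dpre)
        dM <- dpre %*% t(pp$W1)
        g$gamma <- sum(dM * fw$M) / as.vector(pp$gamma)
        dalpha <- vapply(seq_along(Xk), function(k) {
          as.vector(pp$gamma) * sum(dM * Xk[[k]][idx, , drop = FALSE])
        }, numeric(1))
        g$raw <- fw$alpha * (dalpha - sum(fw$alpha * dalpha))
        stepped <- adam_step(pp, g, opt, hyper$lr)
        pp <- stepped$params
        opt <- stepped$state
      }
    }
    fw <- probe_forward(Xk, heldout_idx, pp)
    pred <- scheme$labels[max.col(fw$logits, ties.method = "first")]
    sc <- score_predictions(labels[heldout_idx], pred, scheme)
    structure(list(score = sc$f1, metrics = sc,
                   alpha = softmax_vec(as.vector(pp$raw)),
                   gamma = as.vector(pp$gamma), params = pp, l = l,
                   heldout_idx = heldout_idx),
              class = "probe_result")
  })
}

#' Per-layer knowledge deltas
#'
#' `Delta^l = Score(P^l) - Score(P^{l-1})` for l = 1..L; the deltas
#' telescope, so their sum equals `Score(P^L) - Score(P^0)` exactly.
#'
#' @param scores numeric vector of per-layer probe scores, indexed l =
#'   0..L (length >= 2).
#' @return numeric vector of deltas, length `length(scores) - 1`.
#' @export
knowledge_deltas <- function(scores) {
  assert_that(length(scores) >= 2L, "need at least two per-layer scores")
  diff(scores)
}

#' Run the full probe series
#'
#' Trains one probe per top layer l = 0..L (independently, under a shared
#' seed so every probe sees the same train/held-out split) and assembles
#' scores, knowledge deltas and the learned mixing weights.
#'
#' @inheritParams train_probe
#' @return object of class `probe_series`: `table` (data frame l, score,
#'   delta), `alphas` (list of learned mixing weights per l), `probes`.
#' @export
probe_series <- function(acts, labels, scheme, hyper = probe_config(),
                         seed = 1L) {
  L <- dim(acts$hidden)[2] - 1L
  probes <- lapply(0:L, function(l) {
    train_probe(acts, labels, l, scheme, hyper, seed)
  })
  scores <- vapply(probes, `[[`, numeric(1), "score")
  deltas <- knowledge_deltas(scores)
  structure(list(table = data.frame(l = 0:L, score = scores,
                                    delta = c(NA, deltas)),
                 alphas = lapply(probes, `[[`, "alpha"),
                 probes = probes),
            class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat("<probe_series>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @rdname probe_series
#' @param x a `probe_series`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.probe_series <- function(x, ...) {
  d <- x$table[-1L, ]
  graphics::barplot(d$delta, names.arg = d$l,
                    xlab = "layer l", ylab = "knowledge delta", ...)
  invisible(x)
}

#' @rdname probe_series
#' @param series a `probe_series`.
#' @param path destination CSV (l, score, delta).
#' @export
write_probe_series <- function(series, path) {
  utils::write.csv(series$table, path, row.names = FALSE)
  invisible(path)
}
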