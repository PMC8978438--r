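# A tiny deterministic transformer encoder. Standard pre-LN-free BERT-style
# blocks: token + position (+ segment) embeddings with layer norm, then L
# blocks of multi-head self-attention and a GELU feed-forward, each with a
# residual connection and layer norm. Forward passes cache every
# intermediate needed for the hand-written analytic backward pass, which is
# validated against central-difference numerical gradients in the test
# suite. Batch activations are stored as (B*T) x H matrices with rows
# ordered example-major (row (b-1)*T + t holds token t of example b).

#' Encoder configuration
#'
#' @param L number of transformer layers (>= 1).
#' @param H hidden size, divisible by `heads`.
#' @param heads attention head count.
#' @param vocab vocabulary size.
#' @param max_len maximum sequence length.
#' @param seed initialisation seed.
#' @param ffn feed-forward inner size (default `4 * H`).
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(L, H, heads = 4L, vocab, max_len = 32L,
                           seed = 1L, ffn = 4L * H) {
  assert_that(L >= 1L, "L must be at least 1")
  assert_that(H %% heads == 0L, "H must be divisible by heads")
  assert_that(vocab >= length(SPECIAL_TOKENS), "vocabulary too small")
  structure(list(L = as.integer(L), H = as.integer(H),
                 heads = as.integer(heads), vocab = as.integer(vocab),
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 ffn = as.integer(ffn)),
            class = "encoder_config")
}

init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Build the tiny reference encoder
#'
#' Parameters are drawn deterministically from `config$seed` (embeddings
#' first, then layers in order, so the embedding output is independent of
#' the deeper layers' parameters). The result supports [encode()] and is
#' the desk-scale stand-in for a full pretrained biomedical checkpoint in
#' tests and examples.
#'
#' @param config an [encoder_config()].
#' @return an object of class `tiny_encoder` (list of `config`, `params`).
#' @export
build_tiny_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  H <- config$H
  params <- local_seed(config$seed, {
    emb <- list(tok = init_mat(config$vocab, H),
                pos = init_mat(config$max_len, H),
                seg = init_mat(2L, H),
                ln_g = rep(1, H), ln_b = rep(0, H))
    layers <- lapply(seq_len(config$L), function(l) {
      list(Wq = init_mat(H, H), bq = rep(0, H),
           Wk = init_mat(H, H), bk = rep(0, H),
           Wv = init_mat(H, H), bv = rep(0, H),
           Wo = init_mat(H, H), bo = rep(0, H),
           ln1_g = rep(1, H), ln1_b = rep(0, H),
           W1 = init_mat(H, config$ffn), b1 = rep(0, config$ffn),
           W2 = init_mat(config$ffn, H), b2 = rep(0, H),
           ln2_g = rep(1, H), ln2_b = rep(0, H))
    })
    list(emb = emb, layers = layers)
  })
  structure(list(config = config, params = params), class = "tiny_encoder")
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat(sprintf("<tiny_encoder> L=%d H=%d heads=%d vocab=%d max_len=%d\n",
              x$config$L, x$config$H, x$config$heads, x$config$vocab,
              x$config$max_len))
  invisible(x)
}

# Full forward pass with caches. ids/mask/segments are B x T matrices.
encoder_forward <- function(enc, ids, mask, segments = NULL) {
  cfg <- enc$config
  p <- enc$params
  B <- nrow(ids)
  T <- ncol(ids)
  assert_that(T <= cfg$max_len, "sequence longer than encoder max length")
  assert_that(max(ids) <= cfg$vocab, "token id exceeds vocabulary size")
  H <- cfg$H
  nh <- cfg$heads
  dk <- H %/% nh
  idvec <- as.vector(t(ids))                    # example-major flattening
  posvec <- rep(seq_len(T), times = B)
  segvec <- if (is.null(segments)) rep.int(1L, B * T) else as.vector(t(segments))
  x <- p$emb$tok[idvec, , drop = FALSE] +
    p$emb$pos[posvec, , drop = FALSE] +
    p$emb$seg[segvec, , drop = FALSE]
  ln0 <- layernorm_forward(x, p$emb$ln_g, p$emb$ln_b)
  acts <- vector("list", cfg$L + 1L)
  acts[[1]] <- ln0$y
  layer_caches <- vector("list", cfg$L)
  h <- ln0$y
  scale <- 1 / sqrt(dk)
  for (l in seq_len(cfg$L)) {
    lp <- p$layers[[l]]
    Q <- sweep(h %*% lp$Wq, 2L, lp$bq, `+`)
    K <- sweep(h %*% lp$Wk, 2L, lp$bk, `+`)
    V <- sweep(h %*% lp$Wv, 2L, lp$bv, `+`)
    A <- matrix(0, B * T, H)
    P_cache <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T + 1L):(b * T)
      keymask <- mask[b, ]
      Pb <- vector("list", nh)
      for (j in seq_len(nh)) {
        cj <- ((j - 1L) * dk + 1L):(j * dk)
        S <- (Q[rb, cj, drop = FALSE] %*% t(K[rb, cj, drop = FALSE])) * scale
        S[, !keymask] <- -1e30
        P <- softmax_rows(S)
        A[rb, cj] <- P %*% V[rb, cj, drop = FALSE]
        Pb[[j]] <- P
      }
      P_cache[[b]] <- Pb
    }
    attn_out <- sweep(A %*% lp$Wo, 2L, lp$bo, `+`)
    res1 <- h + attn_out
    ln1 <- layernorm_forward(res1, lp$ln1_g, lp$ln1_b)
    h1 <- ln1$y
    Z <- sweep(h1 %*% lp$W1, 2L, lp$b1, `+`)
    G <- gelu(Z)
    ffn_out <- sweep(G %*% lp$W2, 2L, lp$b2, `+`)
    res2 <- h1 + ffn_out
    ln2 <- layernorm_forward(res2, lp$ln2_g, lp$ln2_b)
    layer_caches[[l]] <- list(h_in = h, Q = Q, K = K, V = V, A = A,
                              P = P_cache, ln1 = ln1, h1 = h1, Z = Z, G = G,
                              ln2 = ln2)
    h <- ln2$y
    acts[[l + 1L]] <- h
  }
  list(acts = acts, caches = layer_caches, ln0 = ln0,
       idvec = idvec, posvec = posvec, segvec = segvec,
       B = B, T = T)
}

# Backward pass. `dtop` is the gradient of the loss w.r.t. the layer-L
# output, shaped (B*T) x H (zero rows where nothing flows). Returns
# gradients for every encoder parameter.
encoder_backward <- function(enc, fwd, dtop) {
  cfg <- enc$config
  p <- enc$params
  H <- cfg$H
  nh <- cfg$heads
  dk <- H %/% nh
  B <- fwd$B
  T <- fwd$T
  scale <- 1 / sqrt(dk)
  grads <- params_zero(p)
  dh <- dtop
  for (l in rev(seq_len(cfg$L))) {
    lp <- p$layers[[l]]
    cc <- fwd$caches[[l]]
    lb2 <- layernorm_backward(dh, cc$ln2, lp$ln2_g)
    grads$layers[[l]]$ln2_g <- lb2$dg
    grads$layers[[l]]$ln2_b <- lb2$db
    dres2 <- lb2$dx
    dffn <- dres2
    grads$layers[[l]]$W2 <- t(cc$G) %*% dffn
    grads$layers[[l]]$b2 <- colSums(dffn)
    dG <- dffn %*% t(lp$W2)
    dZ <- dG * gelu_grad(cc$Z)
    grads$layers[[l]]$W1 <- t(cc$h1) %*% dZ
    grads$layers[[l]]$b1 <- colSums(dZ)
    dh1 <- dres2 + dZ %*% t(lp$W1)
    lb1 <- layernorm_backward(dh1, cc$ln1, lp$ln1_g)
    grads$layers[[l]]$ln1_g <- lb1$dg
    grads$layers[[l]]$ln1_b <- lb1$db
    dres1 <- lb1$dx
    dattn <- dres1
    grads$layers[[l]]$Wo <- t(cc$A) %*% dattn
    grads$layers[[l]]$bo <- colSums(dattn)
    dA <- dattn %*% t(lp$Wo)
    dQ <- matrix(0, B * T, H)
    dK <- matrix(0, B * T, H)
    dV <- matrix(0, B * T, H)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T + 1L):(b * T)
      for (j in seq_len(nh)) {
        cj <- ((j - 1L) * dk + 1L):(j * dk)
        P <- cc$P[[b]][[j]]
        dAbj <- dA[rb, cj, drop = FALSE]
        dP <- dAbj %*% t(cc$V[rb, cj, drop = FALSE])
        dV[rb, cj] <- t(P) %*% dAbj
        dS <- softmax_rows_backward(dP, P) * scale
        dQ[rb, cj] <- dS %*% cc$K[rb, cj, drop = FALSE]
        dK[rb, cj] <- t(dS) %*% cc$Q[rb, cj, drop = FALSE]
      }
    }
    grads$layers[[l]]$Wq <- t(cc$h_in) %*% dQ
    grads$layers[[l]]$bq <- colSums(dQ)
    grads$layers[[l]]$Wk <- t(cc$h_in) %*% dK
    grads$layers[[l]]$bk <- colSums(dK)
    grads$layers[[l]]$Wv <- t(cc$h_in) %*% dV
    grads$layers[[l]]$bv <- colSums(dV)
    dh <- dres1 + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  }
  lb0 <- layernorm_backward(dh, fwd$ln0, p$emb$ln_g)
  grads$emb$ln_g <- lb0$dg
  grads$emb$ln_b <- lb0$db
  dx <- lb0$dx
  grads$emb$tok <- scatter_rowsum(dx, fwd$idvec, cfg$vocab)
  grads$emb$pos <- scatter_rowsum(dx, fwd$posvec, cfg$max_len)
  grads$emb$seg <- scatter_rowsum(dx, fwd$segvec, 2L)
  grads
}

scatter_rowsum <- function(dx, index, n) {
  out <- matrix(0, n, ncol(dx))
  rs <- rowsum(dx, group = index)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Encode a batch of token sequences
#'
#' Runs the encoder and returns every per-layer hidden state: layer 0 is
#' the embedding output, layer `L` the final transformer block. Position 1
#' holds the classification token, the last real position the separator.
#'
#' @param encoder a [build_tiny_encoder()] result (or any object honouring
#'   the same contract, such as a loaded checkpoint adapter).
#' @param ids integer matrix (batch x seq_len) of token ids, or the result
#'   of [tokenize_batch()].
#' @param mask logical matrix flagging real (non-padding) tokens; taken
#'   from `ids` when a `tokenize_batch()` result is given.
#' @param segments optional integer matrix of segment ids (1 or 2).
#' @return object of class `layer_activations`: `hidden` is a
#'   `(batch, L+1, seq_len, H)` array, `mask` the padding mask.
#' @export
encode <- function(encoder, ids, mask = NULL, segments = NULL) {
  UseMethod("encode")
}

#' @export
encode.tiny_encoder <- function(encoder, ids, mask = NULL, segments = NULL) {
  if (is.list(ids) && !is.null(ids$ids)) {
    mask <- ids$mask
    ids <- ids$ids
  }
  assert_that(is.matrix(ids), "ids must be an integer matrix")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ids), ncol(ids))
  fwd <- encoder_forward(encoder, ids, mask, segments)
  acts_to_array(fwd$acts, mask, encoder$config$H)
}

acts_to_array <- function(acts, mask, H) {
  B <- nrow(mask)
  T <- ncol(mask)
  nl <- length(acts)
  hidden <- array(0, dim = c(B, nl, T, H))
  for (l in seq_len(nl)) {
    # rows of acts[[l]] are example-major: (b-1)*T + t
    hidden[, l, , ] <- aperm(array(t(acts[[l]]), dim = c(H, T, B)), c(3, 2, 1))
  }
  structure(list(hidden = hidden, mask = mask), class = "layer_activations")
}

#' Extract one layer from a `layer_activations` object
#'
#' @param acts a `layer_activations`.
#' @param l layer index, 0 (embedding output) to L.
#' @return numeric array `(batch, seq_len, H)`.
#' @export
act_layer <- function(acts, l) {
  d <- dim(acts$hidden)
  assert_that(l >= 0L && l < d[2], "layer index out of range")
  array(acts$hidden[, l + 1L, , ], dim = d[c(1, 3, 4)])
}

#' Classification-token vectors from the last layer
#' @param acts a `layer_activations`.
#' @return numeric matrix (batch x H) of position-1, layer-L vectors.
#' @export
cls_vectors <- function(acts) {
  nl <- dim(acts$hidden)[2]
  m <- acts$hidden[, nl, 1L, , drop = FALSE]
  matrix(m, dim(acts$hidden)[1], dim(acts$hidden)[4])
}
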