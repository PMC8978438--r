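# SLL fine-tuning: summarize the last layer's token outputs and
# concatenate the summary with the classification-token output before the
# softmax classifier. The summarized set {h_1 .. h_N} holds the real
# sentence tokens only: the classification token (concatenated separately),
# the separator and padding are excluded, while entity placeholder tokens
# are included. Three summarizers are available: additive attention
# (alpha = softmax(h^L K), O = sum alpha_i h_i^L), an LSTM whose final-step
# output is the summary, and a biLSTM concatenating the forward final-step
# and backward first-position outputs. `none` with use_cls reproduces the
# original [CLS]-only fine-tuning head exactly.

#' SLL head configuration
#'
#' @param summarizer one of `"attention"`, `"lstm"`, `"bilstm"`, `"none"`
#'   (the original classification-token-only baseline, which requires
#'   `use_cls = TRUE`).
#' @param use_cls concatenate the classification-token output (`TRUE`, the
#'   standard mechanism) or classify from the summary alone (`FALSE`, the
#'   ablation variant).
#' @param rnn_hidden LSTM/biLSTM hidden size; `NULL` means the encoder's
#'   hidden size (the desk-scale default; full-scale presets use 768).
#' @param max_len,epochs,lr,batch fine-tuning hyperparameters. Defaults are
#'   the full-scale recipe (sequence length 128, 10 epochs, learning rate
#'   2e-5, batch 32); tiny-encoder runs override them via the `tiny`
#'   preset.
#' @return object of class `sll_config`.
#' @export
sll_config <- function(summarizer = c("attention", "lstm", "bilstm", "none"),
                       use_cls = TRUE, rnn_hidden = NULL,
                       max_len = 128L, epochs = 10L, lr = 2e-5,
                       batch = 32L) {
  summarizer <- match.arg(summarizer)
  assert_that(summarizer != "none" || isTRUE(use_cls),
              "summarizer 'none' requires use_cls = TRUE")
  structure(list(summarizer = summarizer, use_cls = isTRUE(use_cls),
                 rnn_hidden = rnn_hidden, max_len = as.integer(max_len),
                 epochs = as.integer(epochs), lr = lr,
                 batch = as.integer(batch)),
            class = "sll_config")
}

#' Additive-attention summary of last-layer outputs
#'
#' Computes `alpha = softmax(h K)` over the included positions and
#' `O = sum alpha_i h_i`. Weights are non-negative and sum to one.
#'
#' @param h_last numeric matrix (seq_len x H) of last-layer activations
#'   for one instance.
#' @param include logical vector marking the summarized positions (real
#'   sentence tokens: no classification token, separator or padding); at
#'   least one position must be included.
#' @param K numeric weight vector of length H.
#' @return list with `O` (length H) and `alpha` (length seq_len; zero at
#'   excluded positions).
#' @export
attention_summarize <- function(h_last, include, K) {
  assert_that(any(include), "zero included positions")
  hs <- h_last[include, , drop = FALSE]
  a <- softmax_vec(as.vector(hs %*% K))
  alpha <- numeric(nrow(h_last))
  alpha[include] <- a
  list(O = as.vector(crossprod(hs, a)), alpha = alpha)
}

# ---- LSTM machinery -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(H_in, H_hid) {
  list(W = init_mat(H_in, 4L * H_hid), U = init_mat(H_hid, 4L * H_hid),
       b = rep(0, 4L * H_hid))
}

# Forward over a sequence matrix X (n x H_in); returns the final-step
# output and the caches for backpropagation through time.
lstm_seq_forward <- function(X, p) {
  Hh <- nrow(p$U)
  n <- nrow(X)
  h <- matrix(0, 1L, Hh)
  cst <- matrix(0, 1L, Hh)
  steps <- vector("list", n)
  ii <- seq_len(Hh)
  for (t in seq_len(n)) {
    x <- X[t, , drop = FALSE]
    z <- x %*% p$W + h %*% p$U
    z <- z + rep(p$b, each = 1L)
    i <- sigmoid(z[, ii])
    f <- sigmoid(z[, ii + Hh])
    g <- tanh(z[, ii + 2L * Hh])
    o <- sigmoid(z[, ii + 3L * Hh])
    c_new <- f * cst + i * g
    h_new <- o * tanh(c_new)
    steps[[t]] <- list(x = x, h_prev = h, c_prev = cst, i = i, f = f,
                       g = g, o = o, c = c_new)
    h <- matrix(h_new, 1L)
    cst <- matrix(c_new, 1L)
  }
  list(h_last = as.vector(h), steps = steps, n = n)
}

lstm_seq_backward <- function(fwd, p, dh_last) {
  Hh <- nrow(p$U)
  n <- fwd$n
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, Hh, 4L * Hh)
  db <- rep(0, 4L * Hh)
  dX <- matrix(0, n, nrow(p$W))
  dh <- matrix(dh_last, 1L)
  dc <- matrix(0, 1L, Hh)
  for (t in rev(seq_len(n))) {
    st <- fwd$steps[[t]]
    tc <- tanh(st$c)
    do_ <- dh * tc
    dc <- dc + dh * st$o * (1 - tc * tc)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_prev <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g * st$g),
                do_ * st$o * (1 - st$o))
    dW <- dW + crossprod(st$x, dz)
    dU <- dU + crossprod(st$h_prev, dz)
    db <- db + as.vector(dz)
    dX[t, ] <- dz %*% t(p$W)
    dh <- dz %*% t(p$U)
    dc <- dc_prev
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

#' Recurrent summary of last-layer outputs
#'
#' Runs an LSTM over the included positions in sentence order. In `lstm`
#' mode the summary is the final-step forward output; in `bilstm` mode the
#' forward final-step output is concatenated with the backward direction's
#' output at the first position (its own final step), giving a summary of
#' twice the hidden size.
#'
#' @inheritParams attention_summarize
#' @param mode `"lstm"` or `"bilstm"`.
#' @param params for `lstm`: list with `W` (H x 4H'), `U` (H' x 4H'), `b`
#'   (4H'); for `bilstm`: list with `fwd` and `bwd`, each such a list.
#' @return list with `O` (length H' or 2H').
#' @export
rnn_summarize <- function(h_last, include, mode = c("lstm", "bilstm"),
                          params) {
  mode <- match.arg(mode)
  assert_that(any(include), "zero included positions")
  X <- h_last[include, , drop = FALSE]
  if (mode == "lstm") {
    list(O = lstm_seq_forward(X, params)$h_last)
  } else {
    fw <- lstm_seq_forward(X, params$fwd)
    bw <- lstm_seq_forward(X[rev(seq_len(nrow(X))), , drop = FALSE],
                           params$bwd)
    list(O = c(fw$h_last, bw$h_last))
  }
}

#' Assemble the combined output vector
#'
#' @param h_cls classification-token output (length H), required when
#'   `use_cls`.
#' @param O summary vector from a summarizer (`NULL` for the `none`
#'   head).
#' @param use_cls if `TRUE`, `h = h_cls` concatenated with `O`; otherwise
#'   `h = O`.
#' @return the combined vector `h`.
#' @export
assemble_output <- function(h_cls, O, use_cls = TRUE) {
  if (use_cls) {
    assert_that(!is.null(h_cls), "use_cls requires the [CLS] output")
    c(h_cls, O)
  } else {
    assert_that(!is.null(O), "no summary to use without [CLS]")
    O
  }
}

#' Softmax classification of a combined output
#'
#' @param h combined output vector.
#' @param W_f weight matrix, `C x length(h)`.
#' @param b_f bias vector of length C.
#' @return list with `probs` (softmax probabilities, summing to 1) and
#'   `predicted` (argmax class index, ties broken by the lowest index).
#' @export
classify <- function(h, W_f, b_f) {
  assert_that(ncol(W_f) == length(h),
              "dimension mismatch between h and classifier parameters")
  logits <- as.vector(W_f %*% h + b_f)
  assert_that(all(is.finite(logits)), "non-finite logits")
  probs <- softmax_vec(logits)
  list(probs = probs, predicted = which.max(probs))
}

# ---- fine-tuning ----------------------------------------------------------

summary_dim <- function(config, H) {
  Hh <- config$rnn_hidden %||% H
  switch(config$summarizer, attention = H, lstm = Hh, bilstm = 2L * Hh,
         none = 0L)
}

init_sll_head <- function(config, H, C, seed) {
  Hh <- config$rnn_hidden %||% H
  d <- summary_dim(config, H) + if (config$use_cls) H else 0L
  local_seed(seed + 2L, {
    summ <- switch(config$summarizer,
      attention = list(K = stats::rnorm(H, sd = 0.02)),
      lstm = init_lstm_params(H, Hh),
      bilstm = list(fwd = init_lstm_params(H, Hh),
                    bwd = init_lstm_params(H, Hh)),
      none = list())
    list(summ = summ, Wc = init_mat(d, C), bc = rep(0, C))
  })
}

# Included-position mask for one tokenized input: real tokens minus the
# leading [CLS] and any separator.
include_mask <- function(ids, mask, tokenizer) {
  inc <- mask & ids != tokenizer$sep
  inc[1L] <- FALSE
  inc
}

# Prepare a corpus for the model: tokenize, drop instances whose second
# entity tag falls past the truncation point (a one-tag sentence violates
# the task definition).
prepare_instances <- function(corpus, tokenizer, scheme, max_len) {
  toks <- lapply(corpus$sentence, tokenize, tokenizer = tokenizer,
                 max_len = max_len)
  tag_counts <- vapply(toks, function(tk) {
    sum(tk$tokens %in% tokenizer$tags)
  }, integer(1))
  keep <- tag_counts == 2L
  if (any(!keep)) {
    warning(sprintf("skipping %d instance(s) whose entity tags were truncated",
                    sum(!keep)), call. = FALSE)
  }
  list(corpus = corpus[keep, , drop = FALSE], toks = toks[keep])
}

# Forward + backward of the SLL head for one batch. Returns loss, probs and
# the gradients, including dtop flowing back into the encoder.
sll_head_batch <- function(top, ids, mask, tokenizer, head, config, H, T,
                           target = NULL) {
  B <- nrow(ids)
  C <- ncol(head$Wc)
  use_cls <- config$use_cls
  mode <- config$summarizer
  h_rows <- matrix(0, B, nrow(head$Wc))
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * T + 1L):(b * T)
    hb <- top[rb, , drop = FALSE]
    inc <- include_mask(ids[b, ], mask[b, ], tokenizer)
    cache <- list(inc = inc, hb = hb)
    O <- NULL
    if (mode == "attention") {
      hs <- hb[inc, , drop = FALSE]
      a <- softmax_vec(as.vector(hs %*% head$summ$K))
      O <- as.vector(crossprod(hs, a))
      cache$alpha <- a
      cache$hs <- hs
    } else if (mode == "lstm") {
      cache$fwd <- lstm_seq_forward(hb[inc, , drop = FALSE], head$summ)
      O <- cache$fwd$h_last
    } else if (mode == "bilstm") {
      X <- hb[inc, , drop = FALSE]
      cache$fwd <- lstm_seq_forward(X, head$summ$fwd)
      cache$bwd <- lstm_seq_forward(X[rev(seq_len(nrow(X))), , drop = FALSE],
                                    head$summ$bwd)
      O <- c(cache$fwd$h_last, cache$bwd$h_last)
    }
    h_rows[b, ] <- if (use_cls) c(hb[1L, ], O) else O
    caches[[b]] <- cache
  }
  logits <- sweep(h_rows %*% head$Wc, 2L, head$bc, `+`)
  probs <- softmax_rows(logits)
  if (is.null(target)) {
    return(list(probs = probs, caches = caches))
  }
  ce <- softmax_xent(logits, target)
  ghead <- params_zero(head)
  ghead$Wc <- t(h_rows) %*% ce$dlogits
  ghead$bc <- colSums(ce$dlogits)
  dh_rows <- ce$dlogits %*% t(head$Wc)
  dtop <- matrix(0, B * T, H)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * T + 1L):(b * T)
    cache <- caches[[b]]
    inc <- cache$inc
    if (use_cls) {
      dcls <- dh_rows[b, seq_len(H)]
      dO <- dh_rows[b, -seq_len(H)]
      dtop[rb[1L], ] <- dtop[rb[1L], ] + dcls
    } else {
      dO <- dh_rows[b, ]
    }
    if (mode == "attention") {
      a <- cache$alpha
      hs <- cache$hs
      gvec <- as.vector(hs %*% dO)
      ds <- a * (gvec - sum(a * gvec))
      dhs <- outer(a, dO) + outer(ds, head$summ$K)
      ghead$summ$K <- ghead$summ$K + as.vector(crossprod(hs, ds))
      dtop[rb[inc], ] <- dtop[rb[inc], ] + dhs
    } else if (mode == "lstm") {
      bk <- lstm_seq_backward(cache$fwd, head$summ, dO)
      ghead$summ$W <- ghead$summ$W + bk$dW
      ghead$summ$U <- ghead$summ$U + bk$dU
      ghead$summ$b <- ghead$summ$b + bk$db
      dtop[rb[inc], ] <- dtop[rb[inc], ] + bk$dX
    } else if (mode == "bilstm") {
      Hh <- length(cache$fwd$h_last)
      bkf <- lstm_seq_backward(cache$fwd, head$summ$fwd, dO[seq_len(Hh)])
      bkb <- lstm_seq_backward(cache$bwd, head$summ$bwd, dO[-seq_len(Hh)])
      ghead$summ$fwd$W <- ghead$summ$fwd$W + bkf$dW
      ghead$summ$fwd$U <- ghead$summ$fwd$U + bkf$dU
      ghead$summ$fwd$b <- ghead$summ$fwd$b + bkf$db
      ghead$summ$bwd$W <- ghead$summ$bwd$W + bkb$dW
      ghead$summ$bwd$U <- ghead$summ$bwd$U + bkb$dU
      ghead$summ$bwd$b <- ghead$summ$bwd$b + bkb$db
      n_inc <- sum(inc)
      dXf <- bkf$dX
      dXb <- bkb$dX[rev(seq_len(n_inc)), , drop = FALSE]
      dtop[rb[inc], ] <- dtop[rb[inc], ] + dXf + dXb
    }
  }
  list(loss = ce$loss, probs = probs, ghead = ghead, dtop = dtop)
}

#' Fine-tune an encoder with an SLL head
#'
#' Joint cross-entropy training of the encoder and the SLL head. Each
#' epoch shuffles the training set, takes Adam steps over mini-batches,
#' and scores the development set (binary F1 for single-positive schemes,
#' micro F1 over the non-negative classes otherwise). Deterministic given
#' `seed` in single-threaded mode.
#'
#' @param encoder a [build_tiny_encoder()] result.
#' @param tokenizer the matching [toy_tokenizer()].
#' @param train,dev tagged relation corpora (data frames).
#' @param scheme the [label_scheme()] shared by both splits.
#' @param config an [sll_config()].
#' @param seed RNG seed.
#' @return object of class `sll_model`: trained `encoder`, `head`,
#'   `config`, `scheme`, `tokenizer` and the per-epoch `metrics` data
#'   frame (epoch, train_loss, precision, recall, f1).
#' @export
fine_tune <- function(encoder, tokenizer, train, dev, scheme,
                      config = sll_config(), seed = 1L) {
  assert_that(nrow(train) > 0L, "empty training set")
  validate_corpus(train, scheme)
  validate_corpus(dev, scheme)
  H <- encoder$config$H
  T <- min(config$max_len, encoder$config$max_len)
  C <- length(scheme$labels)
  prep <- prepare_instances(train, tokenizer, scheme, T)
  head <- init_sll_head(config, H, C, seed)
  model <- structure(list(encoder = encoder, head = head, config = config,
                          scheme = scheme, tokenizer = tokenizer,
                          max_len = T,
                          metrics = data.frame(epoch = integer(0),
                                               train_loss = numeric(0),
                                               precision = numeric(0),
                                               recall = numeric(0),
                                               f1 = numeric(0))),
                     class = "sll_model")
  if (config$epochs == 0L) return(model)
  target_all <- match(prep$corpus$label, scheme$labels)
  ids_all <- do.call(rbind, lapply(prep$toks, `[[`, "ids"))
  mask_all <- do.call(rbind, lapply(prep$toks, `[[`, "mask"))
  n <- nrow(prep$corpus)
  params <- list(enc = encoder$params, head = head)
  opt <- adam_init(params)
  metrics <- local_seed(seed, {
    rows <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch)
      losses <- numeric(length(starts))
      for (s in seq_along(starts)) {
        idx <- perm[starts[s]:min(starts[s] + config$batch - 1L, n)]
        ids <- ids_all[idx, , drop = FALSE]
        mask <- mask_all[idx, , drop = FALSE]
        enc_obj <- encoder
        enc_obj$params <- params$enc
        fwd <- encoder_forward(enc_obj, ids, mask)
        top <- fwd$acts[[encoder$config$L + 1L]]
        hb <- sll_head_batch(top, ids, mask, tokenizer, params$head, config,
                             H, T, target = target_all[idx])
        genc <- encoder_backward(enc_obj, fwd, hb$dtop)
        stepped <- adam_step(params, list(enc = genc, head = hb$ghead),
                             opt, config$lr)
        params <- stepped$params
        opt <- stepped$state
        losses[s] <- hb$loss
      }
      model$encoder$params <- params$enc
      model$head <- params$head
      dev_pred <- predict(model, dev)
      sc <- score_predictions(dev$label, dev_pred$predicted, scheme)
      rows[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                  precision = sc$precision,
                                  recall = sc$recall, f1 = sc$f1)
    }
    do.call(rbind, rows)
  })
  model$encoder$params <- params$enc
  model$head <- params$head
  model$metrics <- metrics
  model
}

#' Predict relation labels with a fine-tuned SLL model
#'
#' @param object an `sll_model`.
#' @param newdata a tagged relation corpus data frame.
#' @param batch batch size for the forward passes.
#' @param ... unused.
#' @return data frame with `id`, `gold` (if labels present), `predicted`
#'   and `prob` (the winning class probability).
#' @export
predict.sll_model <- function(object, newdata, batch = 64L, ...) {
  toks <- lapply(newdata$sentence, tokenize, tokenizer = object$tokenizer,
                 max_len = object$max_len)
  ids_all <- do.call(rbind, lapply(toks, `[[`, "ids"))
  mask_all <- do.call(rbind, lapply(toks, `[[`, "mask"))
  n <- nrow(newdata)
  preds <- character(n)
  probs <- numeric(n)
  H <- object$encoder$config$H
  T <- object$max_len
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    ids <- ids_all[idx, , drop = FALSE]
    mask <- mask_all[idx, , drop = FALSE]
    fwd <- encoder_forward(object$encoder, ids, mask)
    top <- fwd$acts[[object$encoder$config$L + 1L]]
    hb <- sll_head_batch(top, ids, mask, object$tokenizer, object$head,
                         object$config, H, T)
    k <- max.col(hb$probs, ties.method = "first")
    preds[idx] <- object$scheme$labels[k]
    probs[idx] <- hb$probs[cbind(seq_along(idx), k)]
  }
  out <- data.frame(id = newdata$id, predicted = preds, prob = probs,
                    stringsAsFactors = FALSE)
  if (!is.null(newdata$label)) out$gold <- newdata$label
  out[, intersect(c("id", "gold", "predicted", "prob"), names(out))]
}

#' @export
print.sll_model <- function(x, ...) {
  cat(sprintf("<sll_model> summarizer=%s use_cls=%s classes=%d\n",
              x$config$summarizer, x$config$use_cls,
              ncol(x$head$Wc)))
  if (nrow(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final dev F1 %.3f after %d epoch(s)\n", last$f1,
                last$epoch))
  }
  invisible(x)
}

#' Write per-epoch metrics / predictions
#'
#' @param model an `sll_model`.
#' @param path destination file.
#' @export
write_metrics <- function(model, path) {
  utils::write.csv(model$metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @param predictions a data frame from [predict.sll_model()].
#' @export
write_predictions <- function(predictions, path) {
  cols <- intersect(c("id", "gold", "predicted", "prob"), names(predictions))
  utils::write.table(predictions[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
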