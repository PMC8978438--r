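test_that("attention summary reduces correctly on degenerate inputs", {
  H <- 4L
  v <- c(0.3, -1.2, 0.5, 2.0)
  h <- matrix(rep(v, each = 5L), 5L, H)  # all included vectors identical
  K <- rnorm(H)
  res <- attention_summarize(h, rep(TRUE, 5L), K)
  expect_equal(res$alpha, rep(1 / 5, 5L), tolerance = 1e-12)
  expect_equal(res$O, v, tolerance = 1e-12)

  h1 <- matrix(rnorm(H), 1L, H)
  res1 <- attention_summarize(h1, TRUE, K)
  expect_identical(res1$alpha, 1)
  expect_equal(res1$O, as.vector(h1), tolerance = 1e-12)
  expect_error(attention_summarize(h, rep(FALSE, 5L), K), "zero included")
})

test_that("attention matches the brute-force weighted-sum oracle", {
  set.seed(14)
  h <- matrix(c(0.5, -1, 2, 0.1, -0.4, 1.5), 3L, 2L)
  K <- c(0.8, -0.3)
  res <- attention_summarize(h, rep(TRUE, 3L), K)
  oracle <- oracle_attention(h, K)
  expect_lt(max(abs(res$O - oracle$O)), 1e-6)
  expect_lt(max(abs(res$alpha - oracle$alpha)), 1e-6)
})

test_that("attention weights normalise on random inputs and are permutation-equivariant", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:10, 1L)
    H <- sample(2:12, 1L)
    h <- matrix(rnorm(n * H), n, H)
    K <- rnorm(H)
    res <- attention_summarize(h, rep(TRUE, n), K)
    expect_true(all(res$alpha >= 0))
    expect_lt(abs(sum(res$alpha) - 1), 1e-6)
    perm <- sample(n)
    res_p <- attention_summarize(h[perm, , drop = FALSE], rep(TRUE, n), K)
    expect_equal(res_p$O, res$O, tolerance = 1e-12)
    expect_equal(res_p$alpha, res$alpha[perm], tolerance = 1e-12)
  }
})

test_that("recurrent summaries follow the step-by-step recurrence oracle", {
  p <- random_lstm_params(3L, 3L, seed = 8L)
  X <- matrix(rnorm(12), 4L, 3L)
  res <- rnn_summarize(X, rep(TRUE, 4L), "lstm", p)
  expect_lt(max(abs(res$O - oracle_lstm(X, p))), 1e-6)

  # biLSTM: forward final step + backward direction's own final step
  pb <- list(fwd = p, bwd = random_lstm_params(3L, 3L, seed = 9L))
  res_b <- rnn_summarize(X, rep(TRUE, 4L), "bilstm", pb)
  expect_length(res_b$O, 6L)
  expect_lt(max(abs(res_b$O - c(oracle_lstm(X, p),
                                oracle_lstm(X[4:1, ], pb$bwd)))), 1e-6)

  # length-1 sequence: both directions see the same single step
  X1 <- X[1, , drop = FALSE]
  res1 <- rnn_summarize(X1, TRUE, "bilstm", pb)
  expect_equal(res1$O, c(oracle_lstm(X1, p), oracle_lstm(X1, pb$bwd)),
               tolerance = 1e-10)
})

test_that("the LSTM summary is order-sensitive but attention is not", {
  set.seed(15)
  X <- matrix(rnorm(20), 5L, 4L)
  p <- random_lstm_params(4L, 4L, seed = 3L)
  o1 <- rnn_summarize(X, rep(TRUE, 5L), "lstm", p)$O
  o2 <- rnn_summarize(X[5:1, , drop = FALSE], rep(TRUE, 5L), "lstm", p)$O
  expect_gt(max(abs(o1 - o2)), 1e-6)
})

test_that("output assembly concatenates [CLS] with the summary", {
  h_cls <- rnorm(32)
  O <- rnorm(32)
  h <- assemble_output(h_cls, O, use_cls = TRUE)
  expect_length(h, 64L)
  expect_identical(h, c(h_cls, O))
  expect_identical(assemble_output(NULL, O, use_cls = FALSE), O)
  # full-scale arithmetic: H = 768, biLSTM summary 2 x 768
  expect_length(assemble_output(rnorm(768), rnorm(1536), TRUE), 2304L)
  expect_error(assemble_output(NULL, O, use_cls = TRUE), "CLS")
})

test_that("the softmax classifier behaves and matches an oracle", {
  h <- rnorm(6)
  expect_equal(classify(h, matrix(0, 4L, 6L), rep(0, 4L))$probs,
               rep(0.25, 4L), tolerance = 1e-12)
  big <- classify(h, matrix(0, 3L, 6L), c(0, 50, 0))
  expect_gt(big$probs[2], 0.99)
  expect_identical(big$predicted, 2L)

  set.seed(16)
  W <- matrix(rnorm(5 * 6), 5L, 6L)
  b <- rnorm(5)
  res <- classify(h, W, b)
  z <- as.vector(W %*% h + b)
  oracle <- exp(z - max(z)) / sum(exp(z - max(z)))
  expect_lt(max(abs(res$probs - oracle)), 1e-8)
  expect_lt(abs(sum(res$probs) - 1), 1e-6)
  expect_error(classify(h, matrix(Inf, 2L, 6L), c(0, 0)), "non-finite")
  expect_error(classify(h, matrix(0, 2L, 5L), c(0, 0)), "mismatch")
})

test_that("summarizer 'none' with [CLS] reproduces the original head", {
  corpus <- tiny_corpus(40, seed = 9)
  scheme <- synthetic_corpus_spec(1L)$scheme
  stack <- tiny_stack(corpus$sentence, seed = 4L)
  cfg <- sll_config("none", use_cls = TRUE, max_len = 24L, epochs = 0L)
  model <- fine_tune(stack$encoder, stack$tokenizer, corpus, corpus,
                     scheme, cfg, seed = 1L)
  tk <- tokenize(corpus$sentence[1], stack$tokenizer, 24L)
  fwd <- sllre:::encoder_forward(stack$encoder, matrix(tk$ids, 1L),
                                 matrix(tk$mask, 1L))
  h_cls <- fwd$acts[[3]][1L, ]
  want <- classify(h_cls, t(model$head$Wc), model$head$bc)
  got <- predict(model, corpus[1, ])
  expect_identical(got$predicted, scheme$labels[want$predicted])
  expect_equal(got$prob, max(want$probs), tolerance = 1e-10)
  expect_error(sll_config("none", use_cls = FALSE), "use_cls")
})

test_that("head gradients agree with central differences", {
  corpus <- tiny_corpus(6, seed = 30)
  scheme <- synthetic_corpus_spec(1L)$scheme
  stack <- tiny_stack(corpus$sentence, seed = 6L, H = 8L, heads = 2L,
                      max_len = 16L)
  tb <- tokenize_batch(corpus$sentence, stack$tokenizer, 16L)
  fwd <- sllre:::encoder_forward(stack$encoder, tb$ids, tb$mask)
  top <- fwd$acts[[3]]
  target <- match(corpus$label, scheme$labels)
  for (mode in c("attention", "lstm", "bilstm")) {
    cfg <- sll_config(mode, max_len = 16L)
    head <- sllre:::init_sll_head(cfg, 8L, 5L, seed = 2L)
    out <- sllre:::sll_head_batch(top, tb$ids, tb$mask, stack$tokenizer,
                                  head, cfg, 8L, 16L, target = target)
    loss_at <- function(h) {
      sllre:::sll_head_batch(top, tb$ids, tb$mask, stack$tokenizer, h,
                             cfg, 8L, 16L, target = target)$loss
    }
    probe_points <- list(c("Wc", 3L), c("bc", 2L))
    if (mode == "attention") {
      probe_points <- c(probe_points, list(c("K", 4L)))
    }
    for (pp in probe_points) {
      eps <- 1e-5
      h1 <- head; h2 <- head
      if (pp[1] %in% c("Wc", "bc")) {
        h1[[pp[1]]][as.integer(pp[2])] <- h1[[pp[1]]][as.integer(pp[2])] + eps
        h2[[pp[1]]][as.integer(pp[2])] <- h2[[pp[1]]][as.integer(pp[2])] - eps
        ana <- out$ghead[[pp[1]]][as.integer(pp[2])]
      } else {
        h1$summ$K[4L] <- h1$summ$K[4L] + eps
        h2$summ$K[4L] <- h2$summ$K[4L] - eps
        ana <- out$ghead$summ$K[4L]
      }
      num <- (loss_at(h1) - loss_at(h2)) / (2 * eps)
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
    # gradient into the encoder top layer
    eps <- 1e-5
    t1 <- top; t2 <- top
    t1[5L, 3L] <- t1[5L, 3L] + eps
    t2[5L, 3L] <- t2[5L, 3L] - eps
    num <- (sllre:::sll_head_batch(t1, tb$ids, tb$mask, stack$tokenizer,
                                   head, cfg, 8L, 16L, target)$loss -
              sllre:::sll_head_batch(t2, tb$ids, tb$mask, stack$tokenizer,
                                     head, cfg, 8L, 16L, target)$loss) /
      (2 * eps)
    expect_lt(abs(num - out$dtop[5L, 3L]) /
                max(1e-6, abs(num) + abs(out$dtop[5L, 3L])), 1e-4)
  }
})

test_that("fine-tuning honours epochs = 0, determinism and empty input", {
  corpus <- tiny_corpus(80, seed = 22)
  scheme <- synthetic_corpus_spec(1L)$scheme
  stack <- tiny_stack(corpus$sentence, seed = 5L)
  cfg0 <- sll_config("attention", max_len = 24L, epochs = 0L)
  m0 <- fine_tune(stack$encoder, stack$tokenizer, corpus, corpus, scheme,
                  cfg0, seed = 3L)
  expect_identical(m0$encoder$params, stack$encoder$params)

  cfg <- sll_config("attention", max_len = 24L, epochs = 2L, lr = 1e-3,
                    batch = 16L)
  m1 <- fine_tune(stack$encoder, stack$tokenizer, corpus[1:60, ],
                  corpus[61:80, ], scheme, cfg, seed = 3L)
  m2 <- fine_tune(stack$encoder, stack$tokenizer, corpus[1:60, ],
                  corpus[61:80, ], scheme, cfg, seed = 3L)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$encoder$params, m2$encoder$params)
  expect_error(fine_tune(stack$encoder, stack$tokenizer, corpus[0, ],
                         corpus, scheme, cfg), "empty training set")
})

test_that("lstm and bilstm heads train end-to-end on a small corpus", {
  corpus <- tiny_corpus(160, seed = 41)
  scheme <- synthetic_corpus_spec(1L)$scheme
  stack <- tiny_stack(corpus$sentence, seed = 8L)
  for (mode in c("lstm", "bilstm")) {
    cfg <- sll_config(mode, max_len = 24L, epochs = 3L, lr = 2e-3,
                      batch = 32L)
    m <- fine_tune(stack$encoder, stack$tokenizer, corpus[1:120, ],
                   corpus[121:160, ], scheme, cfg, seed = 4L)
    expect_lt(m$metrics$train_loss[3], m$metrics$train_loss[1])
  }
})

test_that("checkpoints round-trip through the directory layout", {
  corpus <- tiny_corpus(60, seed = 51)
  scheme <- synthetic_corpus_spec(1L)$scheme
  stack <- tiny_stack(corpus$sentence, seed = 2L)
  cfg <- sll_config("attention", max_len = 24L, epochs = 1L, lr = 1e-3)
  model <- fine_tune(stack$encoder, stack$tokenizer, corpus[1:40, ],
                     corpus[41:60, ], scheme, cfg, seed = 2L)
  dir <- withr::local_tempdir()
  save_sll_model(model, dir)
  back <- load_sll_model(dir)
  expect_identical(predict(back, corpus[41:60, ]),
                   predict(model, corpus[41:60, ]))
})
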