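# Shared desk-scale fixtures, built in code at test time.

# A two-positive-class scheme for small hand-built cases.
tiny_scheme <- function() label_scheme(c("A", "B"), "neg", task = "tiny")

# Tokenizer + tiny encoder over a set of sentences.
tiny_stack <- function(sentences, seed = 1L, max_len = 24L, L = 2L,
                       H = 32L, heads = 4L, piece_len = NULL) {
  tokenizer <- toy_tokenizer(sentences, piece_len = piece_len)
  encoder <- build_tiny_encoder(encoder_config(
    L = L, H = H, heads = heads, vocab = vocab_size(tokenizer),
    max_len = max_len, seed = seed))
  list(tokenizer = tokenizer, encoder = encoder)
}

# A small synthetic tagged corpus with the default DDI-like spec.
tiny_corpus <- function(n, seed = 1L) {
  generate_re_corpus(synthetic_corpus_spec(n = n, seed = seed))
}

# Random sentences over a fixed vocabulary, for tokenizer/doc tests.
random_sentences <- function(n, seed = 1L, vocab = letters_vocab()) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(vocab, sample(3:9, 1L), replace = TRUE), collapse = " ")
  }, character(1))
}

letters_vocab <- function() {
  c("alpha", "beta", "gammaprotein", "regulation", "bindingdomain",
    "cell", "expression", "of", "the", "in", "pathway", "signal")
}

# Independent brute-force micro metrics over non-negative classes,
# computed instance-by-instance from the definition.
oracle_micro <- function(gold, pred, positive, negative) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gold)) {
    if (gold[i] %in% positive && pred[i] == gold[i]) tp <- tp + 1L
    if (pred[i] %in% positive && pred[i] != gold[i]) fp <- fp + 1L
    if (gold[i] %in% positive && pred[i] != gold[i]) fn <- fn + 1L
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(p = p, r = r, f = f, tp = tp, fp = fp, fn = fn)
}

# Independent additive-attention oracle: explicit softmax-weighted sum.
oracle_attention <- function(hs, K) {
  s <- as.vector(hs %*% K)
  e <- exp(s - max(s))
  a <- e / sum(e)
  O <- rep(0, ncol(hs))
  for (i in seq_len(nrow(hs))) O <- O + a[i] * hs[i, ]
  list(O = O, alpha = a)
}

# Independent step-by-step LSTM recurrence oracle.
oracle_lstm <- function(X, p) {
  Hh <- nrow(p$U)
  h <- rep(0, Hh); cst <- rep(0, Hh)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(nrow(X))) {
    z <- as.vector(X[t, ] %*% p$W) + as.vector(h %*% p$U) + p$b
    i <- sig(z[1:Hh]); f <- sig(z[(Hh + 1):(2 * Hh)])
    g <- tanh(z[(2 * Hh + 1):(3 * Hh)]); o <- sig(z[(3 * Hh + 1):(4 * Hh)])
    cst <- f * cst + i * g
    h <- o * tanh(cst)
  }
  h
}

random_lstm_params <- function(H_in, Hh, seed) {
  set.seed(seed)
  list(W = matrix(rnorm(H_in * 4 * Hh, sd = 0.3), H_in),
       U = matrix(rnorm(Hh * 4 * Hh, sd = 0.3), Hh),
       b = rnorm(4 * Hh, sd = 0.3))
}
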