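# Tokenization. The package's working tokenizer is a whitespace tokenizer
# with an optional piece-splitting mode (words longer than `piece_len`
# characters are cut into fixed-width pieces, continuations prefixed "##")
# so that subword-dependent operations like whole-word masking are
# exercised on genuinely multi-piece words. Entity placeholder tags
# (@PROTEIN$, @DRUG$, @CHEMICAL$) are registered as atomic vocabulary items
# and are never split: a split tag would smear the entity position across
# subwords. WordPiece models live behind the pretrained-checkpoint adapter
# and must satisfy the same contract.

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Build a toy tokenizer
#'
#' @param texts character vector used to harvest the vocabulary (whitespace
#'   words, lower-cased except atomic tags/specials).
#' @param extra_tokens additional atomic tokens to register (entity tags are
#'   always registered).
#' @param piece_len if non-`NULL`, words longer than this many characters
#'   are split into pieces of at most `piece_len` characters, continuation
#'   pieces prefixed with `"##"`.
#' @param tags entity placeholder tags kept atomic.
#' @return an object of class `toy_tokenizer` with the vocabulary and the
#'   ids of the special tokens (`pad`, `unk`, `cls`, `sep`, `mask`).
#' @export
toy_tokenizer <- function(texts = character(), extra_tokens = character(),
                          piece_len = NULL, tags = default_entity_tags()) {
  words <- unique(unlist(strsplit(texts, "[ \t]+")))
  words <- words[nzchar(words)]
  pieces <- character()
  for (w in words) {
    if (w %in% tags) next
    pieces <- c(pieces, split_word(tolower(w), piece_len))
  }
  vocab <- c(SPECIAL_TOKENS, unname(tags), unique(c(extra_tokens, pieces)))
  vocab <- vocab[!duplicated(vocab)]
  structure(
    list(vocab = vocab, ids = stats::setNames(seq_along(vocab), vocab),
         pad = 1L, unk = 2L, cls = 3L, sep = 4L, mask = 5L,
         piece_len = piece_len, tags = unname(tags)),
    class = "toy_tokenizer")
}

split_word <- function(w, piece_len) {
  if (is.null(piece_len) || nchar(w) <= piece_len) return(w)
  n <- nchar(w)
  starts <- seq(1L, n, by = piece_len)
  pieces <- substring(w, starts, pmin(starts + piece_len - 1L, n))
  c(pieces[1], paste0("##", pieces[-1]))
}

#' Vocabulary size of a tokenizer
#' @param tokenizer a `toy_tokenizer`.
#' @export
vocab_size <- function(tokenizer) length(tokenizer$vocab)

# Ids of tokens eligible for random replacement in masked-language-model
# corruption (everything except specials; entity tags stay eligible targets
# but random replacement avoids specials only, as in standard collators).
non_special_ids <- function(tokenizer) {
  setdiff(seq_along(tokenizer$vocab), seq_along(SPECIAL_TOKENS))
}

#' Tokenize a sentence
#'
#' Produces the fixed-length model input: `[CLS]`, the sentence pieces, a
#' final `[SEP]`, then padding. When the pieces exceed `max_len - 2`, they
#' are truncated so the leading `[CLS]` is preserved and the last real
#' position is always the separator. `word_ids` aligns every piece to the
#' index of the whitespace word it came from (`NA` at `[CLS]`, `[SEP]` and
#' padding); entity tags are single atomic pieces.
#'
#' @param text a single non-empty string.
#' @param tokenizer a [toy_tokenizer()].
#' @param max_len total sequence length (>= 8).
#' @return a list of class `tokenized_input`: `ids` (integer, length
#'   `max_len`), `word_ids`, `mask` (logical, `TRUE` at real tokens),
#'   `tokens`, `n_words`.
#' @export
tokenize <- function(text, tokenizer, max_len = 32L) {
  assert_that(max_len >= 8L, "max_len must be at least 8")
  words <- strsplit(trimws(text), "[ \t]+")[[1]]
  words <- words[nzchar(words)]
  assert_that(length(words) > 0L, "text is empty after normalization")
  pieces <- character()
  wid <- integer()
  for (i in seq_along(words)) {
    w <- words[i]
    ps <- if (w %in% tokenizer$tags) w else split_word(tolower(w), tokenizer$piece_len)
    pieces <- c(pieces, ps)
    wid <- c(wid, rep.int(i, length(ps)))
  }
  keep <- min(length(pieces), max_len - 2L)
  pieces <- pieces[seq_len(keep)]
  wid <- wid[seq_len(keep)]
  ids <- unname(tokenizer$ids[pieces])
  ids[is.na(ids)] <- tokenizer$unk
  seq_ids <- c(tokenizer$cls, ids, tokenizer$sep)
  seq_wid <- c(NA_integer_, wid, NA_integer_)
  n_real <- length(seq_ids)
  pad_n <- max_len - n_real
  structure(
    list(ids = c(seq_ids, rep.int(tokenizer$pad, pad_n)),
         word_ids = c(seq_wid, rep(NA_integer_, pad_n)),
         mask = c(rep(TRUE, n_real), rep(FALSE, pad_n)),
         tokens = c("[CLS]", pieces, "[SEP]", rep("[PAD]", pad_n)),
         n_words = length(words)),
    class = "tokenized_input")
}

#' Tokenize a batch of sentences into matrices
#'
#' @param texts character vector.
#' @inheritParams tokenize
#' @return list with integer matrix `ids` (n x max_len), logical matrix
#'   `mask`, and the per-sentence `tokenized_input` objects in `inputs`.
#' @export
tokenize_batch <- function(texts, tokenizer, max_len = 32L) {
  inputs <- lapply(texts, tokenize, tokenizer = tokenizer, max_len = max_len)
  list(ids = do.call(rbind, lapply(inputs, `[[`, "ids")),
       mask = do.call(rbind, lapply(inputs, `[[`, "mask")),
       inputs = inputs)
}

# Tokenize a sentence pair "[CLS] A [SEP] B [SEP]" with segment ids, for
# next-sentence-prediction pre-training. Truncates B first, then A. Word
# ids number the whitespace words of A then B consecutively (NA at
# specials/padding) so whole-word masking works on pair inputs too.
tokenize_pair <- function(a, b, tokenizer, max_len = 32L) {
  ta <- tokenize(a, tokenizer, max_len)
  tb <- tokenize(b, tokenizer, max_len)
  strip <- function(tk) {
    keep <- tk$mask
    ids <- tk$ids[keep]
    wid <- tk$word_ids[keep]
    n <- length(ids)
    list(ids = ids[-c(1L, n)], wid = wid[-c(1L, n)])
  }
  sa <- strip(ta)
  sb <- strip(tb)
  budget <- max_len - 3L
  while (length(sa$ids) + length(sb$ids) > budget) {
    if (length(sb$ids) > 1L) {
      sb$ids <- sb$ids[-length(sb$ids)]
      sb$wid <- sb$wid[-length(sb$wid)]
    } else {
      sa$ids <- sa$ids[-length(sa$ids)]
      sa$wid <- sa$wid[-length(sa$wid)]
    }
  }
  seq_ids <- c(tokenizer$cls, sa$ids, tokenizer$sep, sb$ids, tokenizer$sep)
  seq_wid <- c(NA_integer_, sa$wid, NA_integer_,
               sb$wid + ta$n_words, NA_integer_)
  seg <- c(rep.int(1L, length(sa$ids) + 2L), rep.int(2L, length(sb$ids) + 1L))
  n_real <- length(seq_ids)
  pad_n <- max_len - n_real
  list(ids = c(seq_ids, rep.int(tokenizer$pad, pad_n)),
       word_ids = c(seq_wid, rep(NA_integer_, pad_n)),
       segments = c(seg, rep.int(1L, pad_n)),
       mask = c(rep(TRUE, n_real), rep(FALSE, pad_n)))
}
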