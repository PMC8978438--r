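# Synthetic data generators. These make every component of the toolkit
# testable on one CPU without licensed corpora or pretrained checkpoints:
# a trigger-word relation corpus whose labels are decidable by a rule
# (which trigger lexicon intersects the sentence), unlabeled document
# collections for the masked-language-model / next-sentence-prediction
# builders, and planted-signal layer activations for the probing series.

#' Specification of a synthetic trigger-word relation corpus
#'
#' Each generated sentence contains exactly two entity placeholder tags.
#' A positive-label sentence additionally carries exactly one trigger word
#' drawn from that label's lexicon, placed between or adjacent to the two
#' tags (always within three words of a tag, the window the corpus-level
#' attention analysis inspects); negative sentences contain no trigger.
#' All remaining slots hold filler vocabulary, so a rule that looks up
#' which trigger lexicon intersects the sentence recovers the label
#' perfectly.
#'
#' The defaults emulate a DDI-style task: four positive relation classes
#' plus one negative class with drug placeholder tags, a short trigger
#' lexicon per class, a generic clinical filler vocabulary, sentences of
#' 8-14 words, and a class mixture of 0.15 per positive class / 0.40
#' negative.
#'
#' @param n number of instances.
#' @param seed RNG seed.
#' @param scheme a [label_scheme()].
#' @param triggers named list mapping each positive label to its trigger
#'   word set; sets must be pairwise disjoint and disjoint from `fillers`.
#' @param fillers filler vocabulary.
#' @param len_range integer `c(min, max)` sentence length in words
#'   (excluding nothing: tags and trigger count as words).
#' @param mixture named numeric proportions over `scheme$labels`, summing
#'   to 1.
#' @param tag_pair the two placeholder tags inserted per sentence.
#' @param group_size instances per synthetic source document (for
#'   group-level folding).
#' @return an object of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n, seed = 1L,
                                  scheme = label_scheme(
                                    c("ADVICE", "EFFECT", "INT", "MECHANISM"),
                                    "negative", task = "synthetic-ddi"),
                                  triggers = list(
                                    ADVICE = c("recommended", "advised", "avoid"),
                                    EFFECT = c("enhances", "potentiates", "attenuates"),
                                    INT = c("interacts", "interaction", "interfere"),
                                    MECHANISM = c("increases", "decreases", "inhibits")),
                                  fillers = c(
                                    "patients", "plasma", "levels", "dose", "therapy",
                                    "treatment", "clinical", "study", "observed",
                                    "reported", "concentration", "oral", "daily",
                                    "renal", "hepatic", "serum", "administration",
                                    "single", "multiple", "healthy", "subjects",
                                    "during", "with", "after", "before", "under",
                                    "steady", "state", "exposure", "trial"),
                                  len_range = c(8L, 14L),
                                  mixture = NULL,
                                  tag_pair = c("@DRUG$", "@DRUG$"),
                                  group_size = 5L) {
  if (is.null(mixture)) {
    mixture <- stats::setNames(
      c(rep(0.6 / length(scheme$positive), length(scheme$positive)), 0.4),
      c(scheme$positive, scheme$negative))
  }
  assert_that(setequal(names(mixture), scheme$labels),
              "mixture must name every scheme label")
  assert_that(abs(sum(mixture) - 1) < 1e-9, "mixture must sum to 1")
  assert_that(setequal(names(triggers), scheme$positive),
              "triggers must map every positive label")
  assert_that(all(lengths(triggers) > 0L),
              "empty trigger lexicon for a positive label")
  all_trig <- unlist(triggers, use.names = FALSE)
  assert_that(!anyDuplicated(all_trig),
              "trigger sets must be pairwise disjoint")
  assert_that(length(intersect(all_trig, fillers)) == 0L,
              "trigger sets must be disjoint from fillers")
  assert_that(len_range[1] >= 6L && len_range[2] >= len_range[1],
              "sentence length range must allow two tags plus a trigger")
  structure(list(n = as.integer(n), seed = as.integer(seed), scheme = scheme,
                 triggers = triggers, fillers = fillers,
                 len_range = as.integer(len_range),
                 mixture = mixture[scheme$labels], tag_pair = tag_pair,
                 group_size = as.integer(group_size)),
            class = "synthetic_corpus_spec")
}

#' Generate a synthetic trigger-word relation corpus
#'
#' @param spec a [synthetic_corpus_spec()].
#' @return a relation corpus data frame (see [relation_corpus()]), tagged,
#'   deterministic given `spec$seed`.
#' @export
generate_re_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  n <- spec$n
  if (n == 0L) return(relation_corpus(character(), character(), character()))
  local_seed(spec$seed, {
    labels <- sample(spec$scheme$labels, n, replace = TRUE,
                     prob = spec$mixture)
    sentences <- vapply(labels, function(lab) {
      w <- sample(spec$len_range[1]:spec$len_range[2], 1L)
      words <- sample(spec$fillers, w, replace = TRUE)
      # two tag positions with a gap of 2..5 words so that a slot between or
      # adjacent to the tags always lies within 3 words of a tag
      gap <- sample(2:5, 1L)
      p1 <- sample.int(w - gap, 1L)
      p2 <- p1 + gap
      words[p1] <- spec$tag_pair[1]
      words[p2] <- spec$tag_pair[2]
      if (lab != spec$scheme$negative) {
        slots <- setdiff(max(1L, p1 - 1L):min(w, p2 + 1L), c(p1, p2))
        q <- if (length(slots) == 1L) slots else sample(slots, 1L)
        words[q] <- sample(spec$triggers[[lab]], 1L)
      }
      paste(words, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    ids <- sprintf("s%06d", seq_len(n))
    groups <- sprintf("doc%05d", (seq_len(n) - 1L) %/% spec$group_size)
    relation_corpus(ids, sentences, labels, groups)
  })
}

#' Classify synthetic sentences by trigger lexicon lookup
#'
#' The rule-based oracle for [generate_re_corpus()]: a sentence is assigned
#' the positive label whose trigger lexicon intersects its words, or the
#' negative label when none does.
#'
#' @param sentences character vector.
#' @param spec the [synthetic_corpus_spec()] that generated them.
#' @return character label vector.
#' @export
trigger_rule_labels <- function(sentences, spec) {
  vapply(sentences, function(s) {
    ws <- strsplit(s, " ", fixed = TRUE)[[1]]
    for (lab in names(spec$triggers)) {
      if (any(ws %in% spec$triggers[[lab]])) return(lab)
    }
    spec$scheme$negative
  }, character(1), USE.NAMES = FALSE)
}

#' Generate an unlabeled document collection
#'
#' @param n_docs number of documents (>= 0).
#' @param sentences_per_doc sentences in each document.
#' @param vocab word vocabulary (non-empty).
#' @param seed RNG seed.
#' @param words_range words per sentence, `c(min, max)`.
#' @return list of character vectors, one ordered sentence vector per
#'   document; deterministic given `seed`.
#' @export
generate_document_corpus <- function(n_docs, sentences_per_doc, vocab,
                                     seed = 1L, words_range = c(5L, 12L)) {
  assert_that(n_docs >= 0L, "n_docs must be non-negative")
  assert_that(length(vocab) > 0L, "vocabulary must be non-empty")
  if (n_docs == 0L) return(list())
  local_seed(seed, {
    lapply(seq_len(n_docs), function(d) {
      vapply(seq_len(sentences_per_doc), function(s) {
        w <- sample(words_range[1]:words_range[2], 1L)
        paste(sample(vocab, w, replace = TRUE), collapse = " ")
      }, character(1))
    })
  })
}

#' Specification of planted-signal layer activations
#'
#' Emulates the object the probing series measures: per-layer, per-position
#' hidden vectors where a label-discriminative linear direction first
#' appears at `signal_layer`. Layers below `signal_layer` are pure noise;
#' at and above it, one position's class-conditional means are separated by
#' `effect` along a fixed random unit direction.
#'
#' @param n number of examples.
#' @param L number of encoder layers (activations span layers `0..L`).
#' @param H hidden size.
#' @param N positions per example.
#' @param signal_layer first layer (1..L) carrying the signal.
#' @param effect separation between class means (>= 0).
#' @param noise standard deviation of the isotropic noise.
#' @param seed RNG seed.
#' @export
planted_activations_spec <- function(n, L, H, N, signal_layer, effect,
                                     noise = 1, seed = 1L) {
  assert_that(signal_layer >= 1L && signal_layer <= L,
              "signal_layer out of range")
  assert_that(effect >= 0, "effect must be non-negative")
  structure(list(n = as.integer(n), L = as.integer(L), H = as.integer(H),
                 N = as.integer(N), signal_layer = as.integer(signal_layer),
                 effect = effect, noise = noise, seed = as.integer(seed)),
            class = "planted_activations_spec")
}

#' Generate planted-signal layer activations
#'
#' @param spec a [planted_activations_spec()].
#' @return list with `acts` (a `layer_activations` object whose `hidden`
#'   array has shape `(n, L+1, N, H)`) and `labels` (character,
#'   "positive"/"negative", balanced in expectation); deterministic given
#'   `spec$seed`.
#' @export
generate_planted_activations <- function(spec) {
  stopifnot(inherits(spec, "planted_activations_spec"))
  local_seed(spec$seed, {
    n <- spec$n
    labels <- sample(c("positive", "negative"), n, replace = TRUE)
    u <- stats::rnorm(spec$H)
    u <- u / sqrt(sum(u * u))
    hidden <- array(stats::rnorm(n * (spec$L + 1L) * spec$N * spec$H,
                                 sd = spec$noise),
                    dim = c(n, spec$L + 1L, spec$N, spec$H))
    shift <- ifelse(labels == "positive", spec$effect / 2, -spec$effect / 2)
    pos <- 2L  # the position carrying the signal
    for (l in (spec$signal_layer + 1L):(spec$L + 1L)) {
      hidden[, l, pos, ] <- hidden[, l, pos, ] + outer(shift, u)
    }
    mask <- matrix(TRUE, n, spec$N)
    list(acts = structure(list(hidden = hidden, mask = mask),
                          class = "layer_activations"),
         labels = labels)
  })
}
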