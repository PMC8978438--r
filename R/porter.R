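#' Porter stemming
#'
#' The classic Porter (1980) suffix-stripping algorithm, used to collapse
#' inflected word forms when aggregating attention weights at corpus level:
#' "activate", "activates" and "activation" all map to the stem "activ", so
#' their weights pool under one table entry.
#'
#' @param words character vector; stemming is case-insensitive and returns
#'   lower-case stems. Non-alphabetic tokens are returned unchanged (lower
#'   cased).
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("activate", "activates", "activation"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(as.character(words)), porter_stem_one, character(1),
         USE.NAMES = FALSE)
}

porter_stem_one <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
  l <- strsplit(w, "", fixed = TRUE)[[1]]
  l <- p_step1a(l)
  l <- p_step1b(l)
  l <- p_step1c(l)
  l <- p_step2(l)
  l <- p_step3(l)
  l <- p_step4(l)
  l <- p_step5a(l)
  l <- p_step5b(l)
  paste(l, collapse = "")
}

# A consonant is any letter other than a,e,i,o,u, and other than y when y is
# preceded by a consonant.
p_cons <- function(l, i) {
  ch <- l[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!p_cons(l, i - 1L))
  }
  TRUE
}

# The measure m of a letter sequence: the number of vowel->consonant
# transitions in its [C](VC)^m[V] form.
p_measure <- function(l) {
  if (!length(l)) return(0L)
  types <- vapply(seq_along(l), function(i) p_cons(l, i), logical(1))
  m <- 0L
  for (i in seq_along(types)[-1]) {
    if (types[i] && !types[i - 1L]) m <- m + 1L
  }
  m
}

p_has_vowel <- function(l) {
  any(!vapply(seq_along(l), function(i) p_cons(l, i), logical(1)))
}

p_ends_double_cons <- function(l) {
  n <- length(l)
  n >= 2L && l[n] == l[n - 1L] && p_cons(l, n)
}

# *o condition: stem ends consonant-vowel-consonant and the final consonant
# is not w, x or y.
p_cvc <- function(l) {
  n <- length(l)
  n >= 3L && p_cons(l, n - 2L) && !p_cons(l, n - 1L) && p_cons(l, n) &&
    !(l[n] %in% c("w", "x", "y"))
}

p_ends <- function(l, suf) {
  s <- strsplit(suf, "", fixed = TRUE)[[1]]
  n <- length(l)
  k <- length(s)
  n > k && identical(l[(n - k + 1L):n], s)
}

p_stem_part <- function(l, suf) l[seq_len(length(l) - nchar(suf))]

p_replace <- function(l, suf, rep) {
  stem <- p_stem_part(l, suf)
  if (nzchar(rep)) c(stem, strsplit(rep, "", fixed = TRUE)[[1]]) else stem
}

p_step1a <- function(l) {
  if (p_ends(l, "sses")) return(p_replace(l, "sses", "ss"))
  if (p_ends(l, "ies")) return(p_replace(l, "ies", "i"))
  if (p_ends(l, "ss")) return(l)
  if (p_ends(l, "s")) return(p_replace(l, "s", ""))
  l
}

p_step1b <- function(l) {
  if (p_ends(l, "eed")) {
    if (p_measure(p_stem_part(l, "eed")) > 0L) return(p_replace(l, "eed", "ee"))
    return(l)
  }
  fix <- NULL
  if (p_ends(l, "ed") && p_has_vowel(p_stem_part(l, "ed"))) {
    fix <- p_replace(l, "ed", "")
  } else if (p_ends(l, "ing") && p_has_vowel(p_stem_part(l, "ing"))) {
    fix <- p_replace(l, "ing", "")
  }
  if (is.null(fix)) return(l)
  l <- fix
  if (p_ends(l, "at") || p_ends(l, "bl") || p_ends(l, "iz")) return(c(l, "e"))
  if (p_ends_double_cons(l) && !(l[length(l)] %in% c("l", "s", "z"))) {
    return(l[-length(l)])
  }
  if (p_measure(l) == 1L && p_cvc(l)) return(c(l, "e"))
  l
}

p_step1c <- function(l) {
  if (p_ends(l, "y") && p_has_vowel(p_stem_part(l, "y"))) {
    l[length(l)] <- "i"
  }
  l
}

# (condition on the stem) suffix -> replacement rule tables; the first
# matching suffix wins, as in the original description.
p_rule_table <- function(l, rules, min_m) {
  for (r in rules) {
    if (p_ends(l, r[[1]])) {
      if (p_measure(p_stem_part(l, r[[1]])) > min_m) {
        return(p_replace(l, r[[1]], r[[2]]))
      }
      return(l)
    }
  }
  l
}

p_step2 <- function(l) {
  p_rule_table(l, list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble")), 0L)
}

p_step3 <- function(l) {
  p_rule_table(l, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
    list("ness", "")), 0L)
}

p_step4 <- function(l) {
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")
  for (suf in sufs) {
    if (p_ends(l, suf)) {
      stem <- p_stem_part(l, suf)
      if (p_measure(stem) > 1L) {
        if (suf == "ion" && !(stem[length(stem)] %in% c("s", "t"))) return(l)
        return(stem)
      }
      return(l)
    }
  }
  l
}

p_step5a <- function(l) {
  if (p_ends(l, "e")) {
    stem <- p_stem_part(l, "e")
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_cvc(stem))) return(stem)
  }
  l
}

p_step5b <- function(l) {
  if (p_measure(l) > 1L && p_ends_double_cons(l) && l[length(l)] == "l") {
    return(l[-length(l)])
  }
  l
}
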