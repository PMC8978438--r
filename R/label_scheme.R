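#' Label schemes for relation-extraction tasks
#'
#' A label scheme names the relation classes of a task: an ordered set of
#' positive (non-negative) labels, a single negative label, and the entity
#' placeholder tags used in pre-processed sentences. Three standard
#' biomedical presets are provided: PPI (binary protein-protein interaction,
#' labels Positive/Negative), DDI (drug-drug interaction with positive
#' classes ADVICE, EFFECT, INT, MECHANISM) and ChemProt (chemical-protein
#' interaction with positive classes CPR:3, CPR:4, CPR:5, CPR:6, CPR:9).
#'
#' @param positive character vector of positive labels (ordered, non-empty).
#' @param negative the single negative label; must not be a positive label.
#' @param task a task name; free-form for custom schemes.
#' @param tags named character vector mapping entity types to placeholder
#'   tags. Defaults to the standard biomedical tags.
#' @return an object of class `label_scheme` with elements `task`,
#'   `positive`, `negative`, `labels` (positive then negative) and `tags`.
#' @examples
#' sc <- task_scheme("DDI")
#' sc$positive
#' @export
label_scheme <- function(positive, negative, task = "custom",
                         tags = default_entity_tags()) {
  positive <- as.character(positive)
  negative <- as.character(negative)
  assert_that(length(positive) >= 1L && !anyDuplicated(positive),
              "positive labels must be a non-empty set without duplicates")
  assert_that(length(negative) == 1L && !(negative %in% positive),
              "negative label must be a single label outside the positive set")
  assert_that(!is.null(names(tags)) && all(nzchar(names(tags))),
              "entity tags must be a named character vector")
  structure(
    list(task = task, positive = positive, negative = negative,
         labels = c(positive, negative), tags = tags),
    class = "label_scheme"
  )
}

#' @rdname label_scheme
#' @export
default_entity_tags <- function() {
  c(protein = "@PROTEIN$", drug = "@DRUG$", chemical = "@CHEMICAL$")
}

#' @rdname label_scheme
#' @param name one of `"PPI"`, `"DDI"`, `"ChemProt"`.
#' @export
task_scheme <- function(name = c("PPI", "DDI", "ChemProt")) {
  name <- match.arg(name)
  switch(name,
    PPI = label_scheme("Positive", "Negative", task = "PPI"),
    DDI = label_scheme(c("ADVICE", "EFFECT", "INT", "MECHANISM"),
                       "DDI-false", task = "DDI"),
    ChemProt = label_scheme(c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9"),
                            "false", task = "ChemProt")
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme>", x$task, "\n",
      " positive:", paste(x$positive, collapse = ", "), "\n",
      " negative:", x$negative, "\n",
      " tags:    ", paste(x$tags, collapse = " "), "\n")
  invisible(x)
}

# Number of entity placeholder tags (any type) occurring in each sentence.
count_entity_tags <- function(sentences, scheme) {
  counts <- integer(length(sentences))
  for (tag in scheme$tags) {
    hits <- gregexpr(tag, sentences, fixed = TRUE)
    counts <- counts + vapply(hits, function(m) sum(m > 0L), integer(1))
  }
  counts
}
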