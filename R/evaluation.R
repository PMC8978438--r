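# Precision / recall / F1 for relation extraction. Binary tasks score the
# single positive label; multi-class tasks use micro-averaged counts pooled
# over the non-negative classes, the standard protocol for DDI/ChemProt-style
# corpora. Zero denominators yield 0 by convention.

eval_metrics <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  data.frame(precision = p, recall = r, f1 = f, tp = tp, fp = fp, fn = fn)
}

check_labels <- function(gold, predicted, scheme) {
  assert_that(length(gold) == length(predicted),
              "gold and predicted must have equal length")
  bad <- setdiff(unique(c(gold, predicted)), scheme$labels)
  assert_that(length(bad) == 0L,
              paste("label outside scheme:", paste(bad, collapse = ", ")))
}

#' Binary precision / recall / F1
#'
#' Counts are computed on the positive label only: TP = both gold and
#' predicted positive, FP = predicted positive but gold negative, FN = gold
#' positive but predicted negative.
#'
#' @param gold,predicted equal-length character label vectors.
#' @param scheme a [label_scheme()] with a single positive label (the labels
#'   are validated against it).
#' @return one-row data frame with `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`.
#' @export
prf_binary <- function(gold, predicted, scheme) {
  check_labels(gold, predicted, scheme)
  pos <- scheme$positive[1]
  tp <- sum(gold == pos & predicted == pos)
  fp <- sum(gold != pos & predicted == pos)
  fn <- sum(gold == pos & predicted != pos)
  eval_metrics(tp, fp, fn)
}

#' Micro precision / recall / F1 over non-negative classes
#'
#' Pooled counts over all positive classes: TP = instances predicted as
#' their (positive) gold class; FP = instances predicted as some positive
#' class but whose gold label differs; FN = gold-positive instances not
#' predicted as their gold class. Negative-class agreements contribute
#' nothing. For a two-label scheme this reduces to [prf_binary()].
#'
#' @inheritParams prf_binary
#' @return one-row data frame as in [prf_binary()].
#' @examples
#' sc <- label_scheme(c("A", "B"), "neg")
#' prf_micro_nonneg(c("A", "A", "B", "neg", "neg"),
#'                  c("A", "B", "B", "A", "neg"), sc)
#' @export
prf_micro_nonneg <- function(gold, predicted, scheme) {
  check_labels(gold, predicted, scheme)
  pos <- scheme$positive
  tp <- sum(gold %in% pos & predicted == gold)
  fp <- sum(predicted %in% pos & predicted != gold)
  fn <- sum(gold %in% pos & predicted != gold)
  eval_metrics(tp, fp, fn)
}

# Dispatch: binary scoring for single-positive schemes, micro otherwise.
score_predictions <- function(gold, predicted, scheme) {
  if (length(scheme$positive) == 1L) prf_binary(gold, predicted, scheme)
  else prf_micro_nonneg(gold, predicted, scheme)
}

#' Aggregate cross-validation fold predictions
#'
#' `pooled` concatenates all fold predictions and scores once (the pooled
#' micro computation); `averaged` scores each fold separately and reports
#' the unweighted mean of the per-fold metrics. Both are computed; `mode`
#' selects which row is the headline. Fold test sets must partition the
#' prediction set (no instance in two folds).
#'
#' @param fold_predictions a list with one element per fold, each a data
#'   frame with columns `id`, `gold`, `predicted`.
#' @param scheme a [label_scheme()].
#' @param mode `"pooled"` or `"averaged"`.
#' @return a data frame with rows `pooled` and `averaged` (attribute
#'   `headline` names the selected mode).
#' @export
aggregate_folds <- function(fold_predictions, scheme,
                            mode = c("pooled", "averaged")) {
  mode <- match.arg(mode)
  ids <- unlist(lapply(fold_predictions, `[[`, "id"))
  assert_that(!anyDuplicated(ids), "fold test sets overlap")
  all_gold <- unlist(lapply(fold_predictions, `[[`, "gold"))
  all_pred <- unlist(lapply(fold_predictions, `[[`, "predicted"))
  pooled <- score_predictions(all_gold, all_pred, scheme)
  per <- do.call(rbind, lapply(fold_predictions, function(f) {
    score_predictions(f$gold, f$predicted, scheme)
  }))
  averaged <- data.frame(precision = mean(per$precision),
                         recall = mean(per$recall), f1 = mean(per$f1),
                         tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn))
  out <- rbind(pooled = pooled, averaged = averaged)
  attr(out, "headline") <- mode
  out
}
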