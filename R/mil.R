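# Multiple-instance learning: a patient is a "bag", each 224x224 patch an
# "instance". The bag score aggregates instance probabilities under one of
# four pooling strategies (mean, top-10 mean, top-100 mean, maximum).

#' Construct a bag (one patient)
#'
#' @param patient_id character scalar.
#' @param patch_ids character vector of instance identifiers (unique).
#' @param label `"high"` or `"low"` M2 infiltration.
#' @param split `"train"`, `"val"` or `"external"`.
#' @return Object of class `hemil_bag`.
#' @export
bag_record <- function(patient_id, patch_ids, label,
                       split = c("train", "val", "external")) {
  split <- match.arg(split)
  label <- match.arg(label, c("high", "low"))
  if (length(patch_ids) < 1L) stop_invalid("a bag needs at least one patch")
  if (anyDuplicated(patch_ids)) stop_invalid("patch_ids must be unique")
  structure(list(patient_id = as.character(patient_id),
                 patch_ids = as.character(patch_ids),
                 label = label, split = split),
            class = "hemil_bag")
}

#' Aggregate instance probabilities into a bag score
#'
#' Implements the four pooling strategies: `"mean"` averages all instance
#' probabilities; `"max"` takes the single largest; `"top10"`/`"top100"`
#' (generically top-k via `k`) average the `min(k, n)` largest. Bags smaller
#' than `k` use all their instances, which makes top-k coincide with the
#' mean when `k >= n` and with max when `k = 1`.
#'
#' @param instance_probs numeric vector of probabilities in `[0, 1]`.
#' @param strategy one of `"mean"`, `"top10"`, `"top100"`, `"max"`, `"topk"`.
#' @param k number of instances for top-k pooling (implied by `"top10"` /
#'   `"top100"`; required for `"topk"`).
#' @return Scalar bag probability; attribute `k_used` records how many
#'   instances entered the average.
#' @export
aggregate_bag <- function(instance_probs,
                          strategy = c("mean", "top10", "top100", "max", "topk"),
                          k = NULL) {
  strategy <- match.arg(strategy)
  n <- length(instance_probs)
  if (n == 0L) stop_invalid("empty bag: no instance probabilities")
  if (any(instance_probs < 0 | instance_probs > 1))
    stop_invalid("instance probabilities must lie in [0, 1]")
  k <- switch(strategy,
              mean  = n,
              max   = 1L,
              top10 = 10L,
              top100 = 100L,
              topk  = {
                if (is.null(k) || k < 1) stop_invalid("topk needs k >= 1")
                as.integer(k)
              })
  k_used <- min(k, n)
  val <- if (strategy == "mean") {
    mean(instance_probs)
  } else if (strategy == "max") {
    max(instance_probs)
  } else {
    mean(sort(instance_probs, decreasing = TRUE)[seq_len(k_used)])
  }
  structure(val, k_used = as.integer(k_used))
}

#' Bag-level predictions for a table of instance probabilities
#'
#' @param instance_preds data frame with columns `patient_id` and
#'   `prob_high` (and optionally `patch_id`).
#' @param strategies character vector of pooling strategies.
#' @param threshold bag probability at or above which the predicted label is
#'   `"high"` (inclusive boundary; default 0.5).
#' @return Data frame `patient_id, strategy, k_used, bag_prob,
#'   predicted_label`.
#' @export
predict_bags <- function(instance_preds,
                         strategies = c("mean", "top10", "top100", "max"),
                         threshold = 0.5) {
  stopifnot(all(c("patient_id", "prob_high") %in% names(instance_preds)))
  by_pat <- split(instance_preds$prob_high, instance_preds$patient_id)
  rows <- list()
  for (s in strategies) {
    agg <- lapply(by_pat, aggregate_bag, strategy = s)
    rows[[s]] <- data.frame(
      patient_id = names(by_pat),
      strategy = s,
      k_used = vapply(agg, attr, 0L, "k_used"),
      bag_prob = vapply(agg, as.numeric, 0),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  classify_bags(out, threshold)
}

#' Threshold bag probabilities into labels
#'
#' @param bag_preds data frame with a `bag_prob` column.
#' @param threshold decision threshold; `bag_prob >= threshold` is `"high"`.
#' @return `bag_preds` with a `predicted_label` column.
#' @export
classify_bags <- function(bag_preds, threshold = 0.5) {
  if (any(bag_preds$bag_prob < 0 | bag_preds$bag_prob > 1))
    stop_invalid("bag probabilities must lie in [0, 1]")
  bag_preds$predicted_label <-
    ifelse(bag_preds$bag_prob >= threshold, "high", "low")
  bag_preds
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`.
#'
#' @param precision,recall values in `[0, 1]`, not both zero.
#' @return F1 score.
#' @export
f1_from_pr <- function(precision, recall) {
  if (any(c(precision, recall) < 0) || any(c(precision, recall) > 1))
    stop_invalid("precision and recall must lie in [0, 1]")
  if (precision == 0 && recall == 0)
    stop_invalid("F1 undefined when precision and recall are both 0")
  2 * precision * recall / (precision + recall)
}

#' Rank-based AUC-ROC
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted 1/2 — the Mann-Whitney formulation, computed
#' from midranks.
#'
#' @param labels vector with positives marked `"high"` (or logical/0-1).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`, or `NA` with a warning if only one class is
#'   present.
#' @export
auc_roc <- function(labels, scores) {
  pos <- if (is.character(labels) || is.factor(labels)) labels == "high"
         else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric suite
#'
#' Confusion counts (positive class `"high"`), accuracy, precision, recall,
#' F1 and rank-based AUC for one set of bag predictions.
#'
#' @param true_labels character vector of `"high"`/`"low"` truths.
#' @param predicted_labels character vector of predicted labels.
#' @param bag_probs numeric bag scores used for the AUC.
#' @return List of class `hemil_metrics` with elements `tp, fp, fn, tn,
#'   accuracy, precision, recall, f1, auc, n`.
#' @export
compute_metrics <- function(true_labels, predicted_labels, bag_probs) {
  n <- length(true_labels)
  if (n < 1L || length(predicted_labels) != n || length(bag_probs) != n)
    stop_invalid("true labels, predictions and scores must have equal length >= 1")
  tp <- sum(true_labels == "high" & predicted_labels == "high")
  fp <- sum(true_labels == "low"  & predicted_labels == "high")
  fn <- sum(true_labels == "high" & predicted_labels == "low")
  tn <- sum(true_labels == "low"  & predicted_labels == "low")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall    <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    f1_from_pr(precision, recall) else NA_real_
  auc <- if (length(unique(true_labels)) < 2L) {
    warning("AUC undefined: single-class truth")
    NA_real_
  } else auc_roc(true_labels, bag_probs)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / n,
                 precision = precision, recall = recall, f1 = f1,
                 auc = auc, n = n),
            class = "hemil_metrics")
}

#' @export
print.hemil_metrics <- function(x, ...) {
  cat(sprintf(
    "hemil metrics (n=%d): AUC %.4f | accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
    x$n, x$auc, x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  confusion: tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
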