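#' Evaluation metrics from a confusion table
#'
#' Computes the standard presence-absence evaluation suite from the four
#' confusion counts: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' omission rate `1 - sensitivity`, proportion correct `(TP+TN)/N`, true
#' skill statistic `sensitivity + specificity - 1`, Jaccard index
#' `TP/(TP+FP+FN)`, and Cohen's kappa with chance agreement from the
#' marginal products.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts. Both classes must be
#'   represented (`TP+FN > 0` and `TN+FP > 0`), otherwise the metrics are
#'   undefined and an error is thrown.
#' @return One-row tibble with columns `sensitivity`, `specificity`,
#'   `omission_rate`, `prop_correct`, `kappa`, `tss`, `jaccard`.
#' @examples
#' confusion_metrics(tp = 40, fp = 15, tn = 35, fn = 10)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (tp + fn == 0 || tn + fp == 0) {
    stop("confusion metrics undefined: one observed class is empty", call. = FALSE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  tibble::tibble(
    sensitivity = sens,
    specificity = spec,
    omission_rate = 1 - sens,
    prop_correct = po,
    kappa = kappa,
    tss = sens + spec - 1,
    jaccard = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  )
}

#' Rank-based AUC
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a presence prediction exceeds an absence prediction, with ties
#' counted one half. Invariant under any strictly monotone transform of the
#' predictions.
#'
#' @param pred_pos Predictions at presence sites.
#' @param pred_neg Predictions at absence sites.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.9, 0.4), c(0.5, 0.1)) # 0.75
#' @export
auc_rank <- function(pred_pos, pred_neg) {
  if (!length(pred_pos) || !length(pred_neg)) {
    stop("both prediction vectors must be non-empty", call. = FALSE)
  }
  np <- length(pred_pos)
  nn <- length(pred_neg)
  r <- rank(c(pred_pos, pred_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' TSS-optimal binarisation threshold
#'
#' Scans the candidate set (the sorted unique prediction values) and returns
#' the threshold maximising sensitivity + specificity under the rule
#' "presence iff prediction >= threshold"; ties are broken by the smallest
#' qualifying threshold.
#'
#' @param predictions Numeric predictions in `[0, 1]`.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return The selected threshold (one of the prediction values).
#' @export
select_threshold <- function(predictions, labels) {
  labels <- as.integer(labels)
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` differ in length", call. = FALSE)
  }
  pos <- predictions[labels == 1]
  neg <- predictions[labels == 0]
  if (!length(pos) || !length(neg)) {
    stop("threshold selection needs both classes present", call. = FALSE)
  }
  cand <- sort(unique(predictions))
  # integer counts keep tie comparisons exact: at threshold t,
  # sens = #(pos >= t)/n_pos and spec = #(neg < t)/n_neg, so maximising
  # #(pos >= t) * n_neg + #(neg < t) * n_pos maximises sens + spec
  n_pos_ge <- length(pos) - findInterval(cand, sort(pos), left.open = TRUE)
  n_neg_lt <- findInterval(cand, sort(neg), left.open = TRUE)
  score <- n_pos_ge * length(neg) + n_neg_lt * length(pos)
  cand[which.max(score)]
}

# confusion counts for predictions vs labels at a threshold (internal)
confusion_at <- function(predictions, labels, threshold) {
  pred <- predictions >= threshold
  obs <- as.logical(labels)
  list(tp = sum(pred & obs), fp = sum(pred & !obs),
       tn = sum(!pred & !obs), fn = sum(!pred & obs))
}

# full metric row incl. AUC for predictions vs labels at a threshold
evaluate_predictions <- function(predictions, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (is.null(threshold)) threshold <- select_threshold(predictions, labels)
  cm <- confusion_at(predictions, labels, threshold)
  metrics <- confusion_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
  dplyr::bind_cols(
    tibble::tibble(auc = auc_rank(predictions[labels == 1],
                                  predictions[labels == 0])),
    metrics,
    tibble::tibble(threshold = threshold)
  )
}
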