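#' Confusion counts for binary predictions
#'
#' Cancer is the positive class: TP counts correctly predicted cancer
#' samples, TN correctly predicted normals, FP normals called cancer and FN
#' cancers called normal.
#'
#' @param truth 0/1 vector (1 = positive) or factor/character matching
#'   `positive`.
#' @param pred predictions, same coding as `truth`.
#' @param positive positive label when `truth` is not already 0/1.
#' @return a `ConfusionCounts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = NULL) {
  to01 <- function(x) {
    if (is.numeric(x) && all(x %in% c(0, 1))) return(as.integer(x))
    if (is.null(positive)) stop("supply 'positive' for non-binary coding")
    as.integer(as.character(x) == positive)
  }
  t01 <- to01(truth); p01 <- to01(pred)
  if (length(t01) != length(p01)) stop("truth/pred length mismatch")
  structure(list(TP = sum(t01 == 1 & p01 == 1), TN = sum(t01 == 0 & p01 == 0),
                 FP = sum(t01 == 0 & p01 == 1), FN = sum(t01 == 1 & p01 == 0)),
            class = "ConfusionCounts")
}

#' Classification metrics from confusion counts
#'
#' Evaluates accuracy, precision, recall, F1, F2, Matthews correlation and
#' balanced accuracy from the four confusion cells. A metric whose
#' denominator is zero is reported as 0 and flagged via the `"degenerate"`
#' attribute instead of propagating `NaN` into downstream products.
#'
#' @param cc a [confusion_counts()] result, or a list with `TP`,`TN`,`FP`,`FN`.
#' @return named numeric vector with `Ac`, `Pr`, `Re`, `F1`, `F2`, `MCC`,
#'   `BAc`; attribute `"degenerate"` names the zero-denominator metrics.
#' @export
compute_metrics <- function(cc) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("negative confusion counts")
  n <- TP + TN + FP + FN
  if (n == 0) stop("empty confusion table")
  degen <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { degen <<- c(degen, name); 0 } else num / den
  }
  Ac <- (TP + TN) / n
  Pr <- div(TP, TP + FP, "Pr")
  Re <- div(TP, TP + FN, "Re")
  F1 <- div(2 * Pr * Re, Pr + Re, "F1")
  F2 <- div(5 * Pr * Re, 4 * Pr + Re, "F2")
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  MCC <- div(TP * TN - FP * FN, mcc_den, "MCC")
  BAc <- (div(TP, TP + FN, "BAc.se") + div(TN, TN + FP, "BAc.sp")) / 2
  out <- c(Ac = Ac, Pr = Pr, Re = Re, F1 = F1, F2 = F2, MCC = MCC, BAc = BAc)
  attr(out, "degenerate") <- degen
  out
}

#' Area under the ROC curve from scores
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth 0/1 truth vector (1 = positive).
#' @return ROC-AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Area under the precision-recall curve from scores
#'
#' Average-precision estimator: precision summed over the recall increments
#' obtained by sweeping the decision threshold over the observed scores
#' (ties handled as a block).
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `(0, 1]`; `NA` if no positive samples.
#' @export
pr_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  P <- sum(truth == 1)
  if (P == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # process tied scores as one block
  blocks <- cumsum(!duplicated(s))
  tp_b <- tapply(y, blocks, sum)
  n_b <- tapply(y, blocks, length)
  tp <- cumsum(tp_b); nn <- cumsum(n_b)
  prec <- tp / nn
  rec <- tp / P
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}
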