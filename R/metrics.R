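#' Confusion matrix from labels and predictions
#'
#' Rows index the true class, columns the predicted class; both coded
#' `0 .. M-1`.
#'
#' @param true,pred integer vectors of equal length.
#' @param n_classes number of classes `M`.
#' @return `M x M` integer matrix of counts.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  if (length(true) != length(pred)) stop("true/pred length mismatch")
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true))
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  dimnames(cm) <- list(true = seq_len(n_classes) - 1L,
                       pred = seq_len(n_classes) - 1L)
  cm
}

#' Classification accuracy in percent
#'
#' The fraction of correctly classified trials (the diagonal of the confusion
#' matrix over its total; for two classes this is the familiar
#' (TP+TN)/(TP+TN+FP+FN)), scaled to percent.
#'
#' @param cm a confusion matrix.
#' @return accuracy in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed accuracy and `p_e` the expected chance agreement. By default
#' `p_e` uses the marginal-product (Cohen) form; for the balanced benchmark
#' sessions this coincides with the uniform `1/M` random-guess rate, which is
#' also available explicitly.
#'
#' @param cm a confusion matrix.
#' @param chance `"marginal"` (Cohen) or `"uniform"` (`p_e = 1/M`).
#' @return kappa in `[-1, 1]`.
#' @export
kappa_score <- function(cm, chance = c("marginal", "uniform")) {
  chance <- match.arg(chance)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- if (chance == "marginal")
    sum(rowSums(cm) * colSums(cm)) / total^2
  else 1 / nrow(cm)
  if (p_e >= 1) stop("degenerate chance agreement p_e = 1")
  (p_o - p_e) / (1 - p_e)
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on per-subject paired scores (exact null
#' distribution for n <= 25 when no ties among the nonzero differences;
#' zero differences are dropped, Wilcoxon's original policy). Significance
#' tiers follow the usual convention: `**` for p < 0.01, `*` for p < 0.05,
#' `n.s.` otherwise.
#'
#' @param a,b numeric vectors of per-subject scores, paired by position.
#' @return list with `p_value`, `tier`, `n_effective` (pairs after dropping
#'   zero differences).
#' @export
wilcoxon_compare <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 5L) stop("need at least 5 paired subjects")
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(p_value = 1, tier = "n.s.", n_effective = 0L))
  res <- suppressWarnings(
    stats::wilcox.test(nz, alternative = "two.sided",
                       exact = length(nz) <= 25L, correct = FALSE))
  p <- res$p.value
  tier <- if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
  list(p_value = p, tier = tier, n_effective = length(nz))
}

#' ROC curve and AUC for a binary task
#'
#' Computes the true-positive/false-positive trade-off over score thresholds
#' and the area under the curve; the AUC equals the Mann-Whitney probability
#' that a positive-class trial receives a higher score than a negative-class
#' trial (ties counted half).
#'
#' @param true_labels binary labels (0/1); both classes must be present.
#' @param scores positive-class probabilities or scores.
#' @return list with `fpr`, `tpr` (curve points, threshold-ordered) and `auc`.
#' @export
roc_auc <- function(true_labels, scores) {
  if (length(unique(true_labels)) < 2L)
    stop("ROC requires both classes present")
  r <- pROC::roc(response = true_labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  list(fpr = 1 - r$specificities, tpr = r$sensitivities,
       auc = as.numeric(r$auc))
}
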