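## Evaluation statistics: multiclass confusion matrix, benign/malignant
## grouping, TPR/FPR, ROC/AUC by threshold sweep, and McNemar's paired
## comparison of two classifiers.

#' Benign and malignant category groups
#'
#' The 6-vs-4 partition of the ten diagnostic categories; actinic keratosis
#' is counted malignant (a precancerous keratinocyte lesion).
#'
#' @return list with character vectors `benign` and `malignant`.
#' @export
benign_malignant_groups <- function() {
  cls <- lesion_classes()
  list(benign = cls[1:6], malignant = cls[7:10])
}

#' Multiclass confusion matrix
#'
#' @param true_labels,predicted_labels equal-length character vectors; every
#'   label must appear in `class_names`.
#' @param class_names ordered class list (default the 10 categories).
#' @return `confusion_matrix` object: an integer matrix with rows = true
#'   class, columns = predicted class.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_names = lesion_classes()) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tt <- table(factor(true_labels, levels = class_names),
              factor(predicted_labels, levels = class_names))
  m <- matrix(as.integer(tt), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Collapse a 10-class confusion matrix to benign vs malignant
#'
#' Block-sums the rows and columns over the two category groups; total count
#' is conserved.
#'
#' @param matrix a 10-class [confusion_matrix()] over [lesion_classes()].
#' @param groups category grouping, by default [benign_malignant_groups()].
#' @return 2x2 `confusion_matrix` with classes `benign`, `malignant`.
#' @export
group_benign_malignant <- function(matrix, groups = benign_malignant_groups()) {
  cls <- rownames(matrix)
  if (is.null(cls) || !setequal(cls, unlist(groups)))
    stop("matrix classes do not match the category groups")
  b <- cls %in% groups$benign
  m2 <- rbind(c(sum(matrix[b, b]), sum(matrix[b, !b])),
              c(sum(matrix[!b, b]), sum(matrix[!b, !b])))
  dimnames(m2) <- list(true = c("benign", "malignant"),
                       predicted = c("benign", "malignant"))
  structure(m2, class = c("confusion_matrix", "matrix"))
}

#' Binary classification rates
#'
#' `TPR = TP / (TP + FN) * 100` and `FPR = FP / (TN + FP) * 100`, reported
#' in percent.
#'
#' @param matrix2x2 a 2x2 confusion matrix (rows = true, cols = predicted).
#' @param positive_class row/column name of the positive class (default
#'   `"malignant"`).
#' @return list with `TP`, `TN`, `FP`, `FN`, `TPR`, `FPR`.
#' @export
binary_rates <- function(matrix2x2, positive_class = "malignant") {
  if (!all(dim(matrix2x2) == 2L)) stop("expected a 2x2 matrix")
  pos <- match(positive_class, rownames(matrix2x2))
  if (is.na(pos)) stop("positive class not found: ", positive_class)
  neg <- 3L - pos
  TP <- matrix2x2[pos, pos]; FN <- matrix2x2[pos, neg]
  FP <- matrix2x2[neg, pos]; TN <- matrix2x2[neg, neg]
  if (TP + FN == 0) stop("TPR undefined: no positive samples")
  if (TN + FP == 0) stop("FPR undefined: no negative samples")
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       TPR = TP / (TP + FN) * 100, FPR = FP / (TN + FP) * 100)
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique scores (tied scores form a
#' single step), producing the standard staircase from (0,0) to (1,1); AUC
#' is the trapezoidal integral, which counts tied score pairs as half
#' concordant (the Mann-Whitney identity).
#'
#' @param scores positive-class scores (e.g. malignant probabilities).
#' @param truths binary truths (logical, or 0/1), `TRUE`/1 = positive; both
#'   classes must be present.
#' @return object of class `roc_curve`: list with `points` (data.frame of
#'   `fpr`, `tpr`, ascending, including both endpoints) and `auc`.
#' @export
roc_curve <- function(scores, truths) {
  truths <- as.logical(truths)
  if (length(scores) != length(truths)) stop("scores/truths length mismatch")
  n_pos <- sum(truths); n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truths[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # one point per unique score
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (head_vec(tpr) + tail_vec(tpr)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

head_vec <- function(x) x[-length(x)]
tail_vec <- function(x) x[-1]

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' McNemar's chi-squared statistic
#'
#' `chi2 = (b - c)^2 / (b + c)` over the discordant counts of a paired
#' comparison; undefined (error) when `b + c = 0`.
#'
#' @param b samples the first system got wrong and the second got right.
#' @param c samples the second system got wrong and the first got right.
#' @return the statistic (0 iff `b == c`).
#' @export
mcnemar_chi2 <- function(b, c) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  if (b + c == 0) stop("McNemar statistic undefined: b + c = 0")
  (b - c)^2 / (b + c)
}

#' Discordant-pair table for two classifiers
#'
#' Tallies `b` (system A wrong, system B right) and `c` (system B wrong,
#' system A right) against a shared truth, and attaches the McNemar
#' statistic. By convention A is the proposed (multimodal) system and B the
#' baseline.
#'
#' @param preds_a,preds_b,truths equal-length label vectors.
#' @return list with `b`, `c` and `chi2` (`NA` when `b + c = 0`).
#' @export
paired_table <- function(preds_a, preds_b, truths) {
  if (length(preds_a) != length(truths) || length(preds_b) != length(truths))
    stop("prediction and truth vectors must have equal length")
  right_a <- preds_a == truths
  right_b <- preds_b == truths
  b <- sum(!right_a & right_b)
  c <- sum(right_a & !right_b)
  list(b = b, c = c,
       chi2 = if (b + c > 0) mcnemar_chi2(b, c) else NA_real_)
}

#' Full evaluation report
#'
#' Convenience wrapper producing the reporting structure used for the
#' dermoscopy system: the 10-class confusion matrix, its benign/malignant
#' collapse, binary rates with malignant positive, and the ROC/AUC of the
#' malignant-group score (sum of the four malignant class probabilities).
#'
#' @param truths true class labels.
#' @param predictions predicted class labels.
#' @param probabilities optional n x 10 matrix of class probabilities
#'   (columns in [lesion_classes()] order) for the ROC.
#' @return list with `confusion`, `confusion2`, `rates`, and (if
#'   probabilities were given) `roc`; `rates` and `roc` are `NULL` when the
#'   truth set lacks one of the two groups.
#' @export
evaluation_report <- function(truths, predictions, probabilities = NULL) {
  cm <- confusion_matrix(truths, predictions)
  cm2 <- group_benign_malignant(cm)
  both <- all(rowSums(cm2) > 0)  # rates/ROC need both groups in the truth
  out <- list(confusion = cm, confusion2 = cm2,
              rates = if (both) binary_rates(cm2, "malignant"))
  if (!is.null(probabilities) && both) {
    mal <- lesion_classes() %in% benign_malignant_groups()$malignant
    score <- rowSums(probabilities[, mal, drop = FALSE])
    out$roc <- roc_curve(score, truths %in% benign_malignant_groups()$malignant)
  }
  out
}
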