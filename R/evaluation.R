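#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred equal-length 0/1 label vectors (1 = positive class).
#' @return a `confusion_counts` list with `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0),
                 n = length(y_true)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/total`, Matthews correlation
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (the
#' standard Matthews denominator), and
#' `F1 = 2*precision*recall/(precision+recall)` with
#' `precision = TP/(TP+FP)` and `recall = SE`. Any metric whose denominator
#' is zero is defined as 0 and listed in the report's `zero_denominator`
#' flags.
#'
#' @param cc a `confusion_counts` from [confusion()], or a list/vector with
#'   `tp`, `fp`, `tn`, `fn`.
#' @return a `metric_report` list with `se`, `sp`, `acc`, `mcc`, `f1` and
#'   `zero_denominator` (character vector of flagged metrics).
#' @export
metrics <- function(cc) {
  tp <- as.numeric(cc[["tp"]]); fp <- as.numeric(cc[["fp"]])
  tn <- as.numeric(cc[["tn"]]); fn <- as.numeric(cc[["fn"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated molecules", call. = FALSE)
  flags <- character(0)
  safe <- function(num, den, metric) {
    if (den == 0) { flags <<- c(flags, metric); 0 } else num / den
  }
  se <- safe(tp, tp + fn, "se")
  sp <- safe(tn, tn + fp, "sp")
  acc <- (tp + tn) / total
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fn * fp, mcc_den, "mcc")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- safe(2 * precision * se, precision + se, "f1")
  structure(list(se = se, sp = sp, acc = acc, mcc = mcc, f1 = f1,
                 zero_denominator = flags),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("SE %.3f  SP %.3f  ACC %.3f  MCC %.3f  F1 %.3f\n",
              x$se, x$sp, x$acc, x$mcc, x$f1))
  if (!is.null(x$auc)) cat(sprintf("AUC %.3f\n", x$auc))
  if (length(x$zero_denominator))
    cat("zero-denominator metrics set to 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps every score threshold to build the ROC curve from (0,0) to (1,1)
#' and integrates it by the trapezoidal rule, which equals the probability
#' that a random positive outscores a random negative with ties counted 1/2
#' (the Mann-Whitney identity).
#'
#' @param y_true 0/1 labels with both classes present.
#' @param scores real-valued scores, higher = more positive.
#' @return list with `auc` and `roc_points` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stop("labels and scores differ in length", call. = FALSE)
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]; ss <- scores[ord]
  grp_end <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  tpr <- c(0, cumsum(ys == 1)[grp_end] / np)
  fpr <- c(0, cumsum(ys == 0)[grp_end] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Full metric report for a prediction
#'
#' Convenience wrapper combining [confusion()], [metrics()] and (when scores
#' are supplied) [roc_auc()].
#'
#' @param y_true,y_pred 0/1 labels.
#' @param scores optional continuous scores for ROC/AUC.
#' @return a `metric_report`, with `auc` and `roc_points` when scores are
#'   given.
#' @export
metric_report <- function(y_true, y_pred, scores = NULL) {
  rep <- metrics(confusion(y_true, y_pred))
  if (!is.null(scores)) {
    ra <- roc_auc(y_true, scores)
    rep$auc <- ra$auc
    rep$roc_points <- ra$roc_points
  }
  rep
}

#' Yule's Q diversity of two classifiers
#'
#' With `N11` = both classifiers correct, `N00` = both wrong, `N10` = only
#' the first correct, `N01` = only the second correct:
#' `Q = (N11*N00 - N01*N10) / (N11*N00 + N01*N10)`. Q ranges over
#' `[-1, 1]`, equals 1 for classifiers that err on the same molecules, and
#' 0 for statistically independent classifiers; it is defined as 0 when the
#' denominator vanishes.
#'
#' @param pred_a,pred_b 0/1 predictions of the two classifiers.
#' @param y_true 0/1 reference labels.
#' @return Q in `[-1, 1]`.
#' @export
yule_q <- function(pred_a, pred_b, y_true) {
  if (length(pred_a) != length(pred_b) || length(pred_a) != length(y_true))
    stop("prediction and label vectors differ in length", call. = FALSE)
  a_ok <- as.integer(pred_a) == as.integer(y_true)
  b_ok <- as.integer(pred_b) == as.integer(y_true)
  n11 <- sum(a_ok & b_ok); n00 <- sum(!a_ok & !b_ok)
  n10 <- sum(a_ok & !b_ok); n01 <- sum(!a_ok & b_ok)
  den <- n11 * n00 + n01 * n10
  if (den == 0) return(0)
  (n11 * n00 - n01 * n10) / den
}

#' Tree-level diversity of one forest member
#'
#' Computes Yule's Q for every unordered pair of decision trees in a forest
#' (each tree judged against the supplied true labels on `X`) and averages
#' them. Low average Q means the trees err on different molecules, i.e. the
#' forest's base learners are diverse.
#'
#' @param member a fitted `randomForest` classifier with at least two trees.
#' @param X matrix of descriptor values to predict on.
#' @param y_true 0/1 labels for `X`.
#' @return a `diversity_report` list with `pairwise_q` (data frame `i`, `j`,
#'   `q`) and `average_q`.
#' @export
forest_tree_diversity <- function(member, X, y_true) {
  if (member$ntree < 2)
    stop("forest has fewer than 2 trees; diversity is undefined",
         call. = FALSE)
  ind <- predict(member, as.matrix(X), predict.all = TRUE)$individual
  pos <- levels(member$y)[2]
  votes <- matrix(as.integer(ind == pos), nrow = nrow(ind))
  pairs <- combn(member$ntree, 2)
  q <- vapply(seq_len(ncol(pairs)), function(k)
    yule_q(votes[, pairs[1, k]], votes[, pairs[2, k]], y_true), numeric(1))
  structure(list(pairwise_q = data.frame(i = pairs[1, ], j = pairs[2, ], q = q),
                 average_q = mean(q)),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Tree-pair Yule's Q over", nrow(x$pairwise_q), "pairs; average Q =",
      sprintf("%.3f", x$average_q), "\n")
  invisible(x)
}
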