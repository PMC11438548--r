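#' Area under the ROC curve
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, with ties counted half — the rank-statistic (Mann-Whitney)
#' form, equivalent to the trapezoidal ROC area.
#'
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @return AUROC in [0,1]
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area: scores are sorted decreasingly, tied
#' scores are processed as one block, and each block contributes
#' (delta recall) x (precision at the block end).
#'
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @return AUPRC in [0,1]
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels))
    stop("need both positive and negative labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  k <- seq_along(y)
  last <- which(!duplicated(s, fromLast = TRUE))  # block ends
  prec <- tp[last] / k[last]
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Positive rate of a label vector
#' @param labels 0/1 vector
#' @export
positive_rate <- function(labels) mean(as.integer(labels) == 1)

#' F1-maximizing score threshold
#'
#' Scans the observed score values as candidate thresholds (prediction:
#' score >= threshold) and returns the one maximizing F1; ties are resolved
#' toward the smallest threshold.
#'
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @return list(threshold, f1, table = data.frame(threshold, f1))
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("no positive labels; F1 undefined at every threshold")
  cand <- sort(unique(scores))
  f1 <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / n1
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  best <- which.max(f1)  # first max = smallest threshold
  list(threshold = cand[best], f1 = f1[best],
       table = data.frame(threshold = cand, f1 = f1))
}

#' Evaluation report for one score vector
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @return object of class \code{eval_report}: auroc, auprc, positive_rate,
#'   f1_by_threshold
#' @export
eval_report <- function(scores, labels) {
  th <- select_threshold(scores, labels)
  structure(list(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 positive_rate = positive_rate(labels),
                 best_threshold = th$threshold, best_f1 = th$f1,
                 f1_by_threshold = th$table),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "AUROC %.4f | AUPRC %.4f | positive rate %.4f | best F1 %.4f at %.4f\n",
    x$auroc, x$auprc, x$positive_rate, x$best_f1, x$best_threshold))
  invisible(x)
}

#' Cross-condition generalization matrix
#'
#' Applies each condition's trained model to every other condition's
#' labeled dataset and records the AUROC; diagonal entries (a model on its
#' own dataset) are left NA, since within-condition performance is measured
#' on held-out splits instead.
#'
#' @param models named list of \code{spider_model}s
#' @param datasets named list of labeled \code{spider_dataset}s (same names)
#' @param edges optional function(dataset) -> integer edge indices to score
#'   (default: all labeled candidate edges)
#' @return condition x condition numeric matrix of AUROCs with NA diagonal
#' @export
generalization_matrix <- function(models, datasets, edges = NULL) {
  stopifnot(identical(names(models), names(datasets)))
  k <- length(models)
  out <- matrix(NA_real_, k, k, dimnames = list(model = names(models),
                                                dataset = names(datasets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    d <- datasets[[j]]
    idx <- if (is.null(edges)) seq_len(nrow(d$edge_index)) else edges(d)
    out[i, j] <- auroc(predict(models[[i]], d, edges = idx),
                       d$labels[idx])
  }
  out
}
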