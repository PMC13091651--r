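# Evaluation metrics: AUC (rank statistic, average-rank tie handling),
# AUPR (step-wise precision-recall integration over all unique score
# thresholds), NDCG (binary gains, log2 discount, global ranking), and
# threshold metrics (F1/precision/recall at a probability cutoff).

# Mann-Whitney AUC with average ranks; NA if a class is missing
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# step-wise PR integration: thresholds at each unique score (descending);
# AUPR = sum over steps of (recall gain) x (precision at that threshold)
aupr_step <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0L || all(labels == 1)) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

ndcg_binary <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0L) return(NA_real_)
  ord <- order(-scores)  # stable: ties keep input order
  gains <- labels[ord]
  disc <- 1 / log2(seq_along(gains) + 1)
  dcg <- sum(gains * disc)
  idcg <- sum(disc[seq_len(P)])
  dcg / idcg
}

#' Compute the full metric report
#'
#' AUC by the Mann-Whitney rank statistic with average-rank tie handling;
#' AUPR by step-wise precision-recall integration over all unique score
#' thresholds; NDCG on the globally ranked list with binary gains and
#' `1/log2(rank + 1)` discount, normalized by the ideal ranking; F1,
#' precision and recall from the confusion matrix at `threshold`. If the
#' label vector contains a single class, ranking metrics are returned as
#' `NA` and `degenerate` is flagged.
#'
#' @param scores numeric prediction scores/probabilities
#' @param labels binary labels (0/1)
#' @param threshold classification cutoff applied to `scores`
#' @return list of class `metrics_report` with F1, AUC, AUPR, NDCG, Pre,
#'   Rec, threshold, n_pos, n_neg, degenerate
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop_fmt("scores and labels differ in length (%d vs %d)",
             length(scores), length(labels))
  }
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stop_fmt("labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  degenerate <- n_pos == 0L || n_neg == 0L
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  pre <- if (tp + fp > 0L) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  structure(list(F1 = f1,
                 AUC = if (degenerate) NA_real_ else auc_rank(scores, labels),
                 AUPR = if (degenerate) NA_real_ else aupr_step(scores, labels),
                 NDCG = if (n_pos == 0L) NA_real_ else ndcg_binary(scores, labels),
                 Pre = pre, Rec = rec, threshold = threshold,
                 n_pos = n_pos, n_neg = n_neg, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics (n_pos=%d, n_neg=%d, threshold=%.2f)\n", x$n_pos, x$n_neg,
    x$threshold))
  for (m in c("F1", "AUC", "AUPR", "NDCG", "Pre", "Rec")) {
    cat(sprintf("  %-5s %.4f\n", m, x[[m]]))
  }
  invisible(x)
}
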