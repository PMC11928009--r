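# Rank-based (Mann-Whitney) area under the ROC curve with tie correction.
roc_auc_binary <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve as average precision: the mean of
# the precision values at the ranks of the positives (step interpolation).
pr_auc_binary <- function(scores, positive) {
  n1 <- sum(positive)
  if (n1 == 0 || all(positive)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  prec <- cumsum(pos) / seq_along(pos)
  sum(prec[pos]) / n1
}

#' Multiclass classification metrics
#'
#' Accuracy plus macro-averaged precision, recall, F1, one-vs-rest ROC-AUC
#' and AUPR from class-probability scores. Classes absent from `truth` are
#' skipped in the macro averages with a warning. Per-class values are
#' returned alongside the aggregates.
#'
#' @param truth factor of true classes.
#' @param prob samples x classes probability/score matrix (columns named by
#'   class).
#' @return list of class `metrics_row`: `metrics` (named list with
#'   accuracy, precision, recall, f1, roc_auc, aupr) and `per_class`
#'   (data.frame, one row per evaluated class).
#' @export
classification_metrics <- function(truth, prob) {
  truth <- as.factor(truth)
  classes <- colnames(prob)
  pred <- factor(classes[max.col(prob, ties.method = "first")],
                 levels = classes)
  acc <- mean(as.character(pred) == as.character(truth))
  rows <- list()
  for (cl in classes) {
    if (!any(truth == cl)) {
      warning("class ", cl, " absent from the evaluated samples; ",
              "skipped in macro averages")
      next
    }
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    pos <- truth == cl
    rows[[cl]] <- data.frame(
      class = cl, precision = prec, recall = rec, f1 = f1,
      roc_auc = roc_auc_binary(prob[, cl], pos),
      aupr = pr_auc_binary(prob[, cl], pos),
      accuracy = mean((pred == cl) == pos),
      stringsAsFactors = FALSE)
  }
  per_class <- do.call(rbind, rows)
  structure(list(
    metrics = list(accuracy = acc,
                   precision = mean(per_class$precision),
                   recall = mean(per_class$recall),
                   f1 = mean(per_class$f1),
                   roc_auc = mean(per_class$roc_auc, na.rm = TRUE),
                   aupr = mean(per_class$aupr, na.rm = TRUE)),
    per_class = per_class),
    class = "metrics_row")
}

#' Evaluate a trained model on a sample mask
#'
#' @param fit a [train_model()] result.
#' @param mask logical mask (or indices) of samples to evaluate.
#' @return a [classification_metrics()] result.
#' @export
evaluate <- function(fit, mask) {
  stopifnot(inherits(fit, "mognn_fit"))
  prob <- predict(fit, type = "prob")
  idx <- if (is.logical(mask)) which(mask) else mask
  classification_metrics(droplevels_keep(fit$graph$labels[idx], fit$classes),
                         prob[idx, , drop = FALSE])
}

# keep the full class set so per-class skipping is explicit
droplevels_keep <- function(x, classes) factor(as.character(x), levels = classes)

#' Aggregate per-fold metric rows to mean and standard deviation
#'
#' @param df data.frame with a `fold` column and one column per metric.
#' @param by grouping columns (default everything except fold and metrics).
#' @return data.frame with mean and sd per metric per group.
#' @export
aggregate_metrics <- function(df, by = setdiff(names(df),
                                               c("fold", metric_names()))) {
  mets <- intersect(metric_names(), names(df))
  agg <- stats::aggregate(df[mets], df[by], function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  out <- agg[by]
  for (m in mets) {
    out[[paste0(m, "_mean")]] <- agg[[m]][, "mean"]
    out[[paste0(m, "_sd")]] <- agg[[m]][, "sd"]
  }
  out
}

metric_names <- function() c("accuracy", "precision", "recall", "f1",
                             "roc_auc", "aupr")
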