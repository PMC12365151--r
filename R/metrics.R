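## Evaluation: macro-averaged classification metrics, one-vs-rest AUC,
## paired t-test, and class-count bookkeeping.
##
## Conventions (pinned by the degenerate all-majority baseline): per-class
## precision/recall/F1 are macro-averaged with undefined values set to 0;
## AUC is one-vs-rest macro-averaged with midrank tie handling, so constant
## scores give exactly 0.5.

#' Merge and tabulate class counts
#'
#' Applies a class-merging rule to labelled counts (e.g. folding a rare
#' precursor class into its nearest subtype) and reports merged counts and
#' proportions.
#'
#' @param counts Named integer vector of per-class counts.
#' @param merge Named list: new class name -> character vector of old class
#'   names to combine. Old classes not mentioned are kept as-is.
#' @return Data frame with `class`, `count`, `prop` (proportions of the
#'   total), in the order first-mentioned.
#' @export
merge_class_counts <- function(counts, merge = list()) {
  if (is.null(names(counts))) stop("merge_class_counts(): counts must be named")
  used <- unlist(merge)
  if (!all(used %in% names(counts))) {
    stop("merge_class_counts(): unknown class in merge rule")
  }
  out_names <- character(0)
  out_counts <- integer(0)
  consumed <- character(0)
  for (cls in names(counts)) {
    if (cls %in% consumed) next
    hit <- which(vapply(merge, function(g) cls %in% g, logical(1)))
    if (length(hit) > 0) {
      grp <- merge[[hit[1]]]
      out_names <- c(out_names, names(merge)[hit[1]])
      out_counts <- c(out_counts, sum(counts[grp]))
      consumed <- c(consumed, grp)
    } else {
      out_names <- c(out_names, cls)
      out_counts <- c(out_counts, counts[[cls]])
    }
  }
  data.frame(class = out_names, count = out_counts,
             prop = out_counts / sum(out_counts))
}

auc_binary <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Computes the confusion matrix, accuracy, macro precision / recall / F1
#' (percent; per-class values that are undefined because the class was
#' never predicted count as 0) and macro one-vs-rest AUC (in `[0, 1]`;
#' constant scores give 0.5).
#'
#' @param true,pred 0-based integer class labels.
#' @param scores N x n_classes matrix of class probabilities (rows sum
#'   to 1); optional, AUC is omitted without it.
#' @param n_classes Number of classes (default: inferred as `max + 1`, at
#'   least 3).
#' @return A `metrics_report` list: `confusion` (rows = truth, cols =
#'   prediction), `accuracy`, `precision`, `recall`, `f1` (macro, percent),
#'   `auc`, and `per_class`.
#' @export
evaluate_predictions <- function(true, pred, scores = NULL,
                                 n_classes = max(3L, max(true, pred) + 1L)) {
  true <- as.integer(true); pred <- as.integer(pred)
  if (length(true) != length(pred)) {
    stop("evaluate_predictions(): length mismatch")
  }
  if (any(true < 0L | true >= n_classes) || any(pred < 0L | pred >= n_classes)) {
    stop("evaluate_predictions(): label outside 0..", n_classes - 1L)
  }
  if (!is.null(scores)) {
    if (nrow(scores) != length(true) || ncol(scores) != n_classes) {
      stop("evaluate_predictions(): scores shape mismatch")
    }
    if (max(abs(rowSums(scores) - 1)) > 1e-6) {
      stop("evaluate_predictions(): score rows must sum to 1")
    }
  }
  cls <- seq_len(n_classes) - 1L
  confusion <- table(factor(true, levels = cls), factor(pred, levels = cls))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(true = cls, pred = cls))
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  auc <- NA_real_
  auc_per_class <- rep(NA_real_, n_classes)
  if (!is.null(scores)) {
    auc_per_class <- vapply(cls, function(c) {
      auc_binary(scores[, c + 1L], true == c)
    }, numeric(1))
    auc <- mean(auc_per_class, na.rm = TRUE)
  }
  structure(list(
    confusion = confusion,
    accuracy = 100 * sum(tp) / sum(confusion),
    precision = 100 * mean(precision),
    recall = 100 * mean(recall),
    f1 = 100 * mean(f1),
    auc = auc,
    per_class = data.frame(class = cls, precision = 100 * precision,
                           recall = 100 * recall, f1 = 100 * f1,
                           auc = auc_per_class),
    n = length(true)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  acc %.2f%%  macro P %.2f%%  R %.2f%%  F1 %.2f%%  AUC %s\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Paired two-sided Student's t-test
#'
#' Classic paired t on the per-fold differences of two matched metric
#' series, with `n - 1` degrees of freedom.
#'
#' @param a,b Equal-length paired samples (e.g. a metric per fold for two
#'   model variants).
#' @return List with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired_ttest(): unequal lengths")
  if (length(a) < 2L) stop("paired_ttest(): need at least 2 pairs")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    stop("paired_ttest(): zero variance of differences; t is undefined")
  }
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p_value = 2 * pt(-abs(t_stat), df = n - 1L),
       mean_diff = mean(d))
}
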