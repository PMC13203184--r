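## Evaluation metrics -------------------------------------------------------
##
## Everything downstream of a classifier consumes a prediction table:
## per-frame (or per-sequence) records of the true label and the class
## probability vector.  Argmax ties break toward the lowest class index.

#' Construct a prediction table
#'
#' @param frame_id,sequence_id character vectors (one entry per row).
#' @param true_label character vector of true classes (may be `NA`).
#' @param probs numeric matrix, one column per class (named), rows summing
#'   to 1 within `1e-6`.
#' @return Object of class `prediction_table` (a data frame with columns
#'   `frame_id`, `sequence_id`, `true_label`, `predicted_label` and one
#'   `prob_<class>` column per class; attribute `classes` records class
#'   order).
#' @export
prediction_table <- function(frame_id, sequence_id, true_label, probs) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) stop("probs must have class column names")
  if (any(probs < -1e-9) || any(!is.finite(probs)))
    stop("probabilities must be finite and non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1 (within 1e-6)")
  classes <- colnames(probs)
  pred <- classes[max.col(probs, ties.method = "first")]
  df <- data.frame(frame_id = as.character(frame_id),
                   sequence_id = as.character(sequence_id),
                   true_label = as.character(true_label),
                   predicted_label = pred,
                   stringsAsFactors = FALSE)
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("prob_", classes)
  df <- cbind(df, pcols)
  rownames(df) <- NULL
  structure(df, classes = classes,
            class = c("prediction_table", "data.frame"))
}

#' Class order of a prediction table
#' @param table a [prediction_table()].
#' @return Character vector of class names.
#' @export
pt_classes <- function(table) attr(table, "classes")

#' Probability matrix of a prediction table
#' @param table a [prediction_table()].
#' @return Numeric matrix, one column per class.
#' @export
pt_probs <- function(table) {
  cl <- pt_classes(table)
  out <- as.matrix(table[paste0("prob_", cl)])
  dimnames(out) <- list(NULL, cl)
  out
}

## row subset preserving class metadata (used heavily by the bootstrap)
pt_subset <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, classes = attr(table, "classes"),
            class = c("prediction_table", "data.frame"))
}

#' @export
#' @method print prediction_table
print.prediction_table <- function(x, ...) {
  cat(sprintf("<prediction_table: %d rows, %d sequences, classes %s>\n",
              nrow(x), length(unique(x$sequence_id)),
              paste(pt_classes(x), collapse = "/")))
  invisible(x)
}

## Classification metrics ---------------------------------------------------

#' F1 score from precision and recall
#'
#' `2PR / (P + R)`, defined as 0 when `P + R = 0` (standard convention).
#'
#' @param precision,recall numeric vectors.
#' @return Numeric vector.
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Confusion matrix of a prediction table
#'
#' @param table a [prediction_table()].
#' @return Integer matrix, rows = true class, columns = predicted class,
#'   in the table's class order.
#' @export
confusion_matrix <- function(table) {
  cl <- pt_classes(table)
  t_f <- factor(table$true_label, levels = cl)
  p_f <- factor(table$predicted_label, levels = cl)
  as.matrix(stats::xtabs(~ t_f + p_f, drop.unused.levels = FALSE))
}

#' Balanced accuracy
#'
#' The arithmetic mean of per-class recalls.  For a prediction table,
#' recalls are computed over the classes actually present among the true
#' labels (absent classes are dropped, which keeps bootstrap replicates
#' well-defined when a rare class is not drawn).  A numeric vector is
#' treated directly as per-class recalls.
#'
#' @param x a [prediction_table()] or a numeric vector of recalls.
#' @param ... unused.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(x, ...) UseMethod("balanced_accuracy")

#' @rdname balanced_accuracy
#' @export
balanced_accuracy.numeric <- function(x, ...) {
  stopifnot(all(x >= 0 & x <= 1))
  mean(x)
}

#' @rdname balanced_accuracy
#' @export
balanced_accuracy.prediction_table <- function(x, ...) {
  cl <- pt_classes(x)
  tr <- match(x$true_label, cl)
  pr <- match(x$predicted_label, cl)
  tot <- tabulate(tr, nbins = length(cl))
  cor <- tabulate(tr[tr == pr], nbins = length(cl))
  present <- tot > 0
  mean(cor[present] / tot[present])
}

#' One-vs-rest AUC per class and macro-AUC
#'
#' Each class's AUC is the rank-sum (Mann-Whitney) statistic of its
#' probability scores with midrank tie handling, equivalent to the
#' trapezoidal ROC area.  Classes lacking positives or negatives get `NA`
#' (with a warning) and are excluded from the macro mean.
#'
#' @param table a [prediction_table()].
#' @return List with `per_class` (named numeric) and `macro_auc` (scalar).
#' @export
auc_ovr <- function(table) {
  cl <- pt_classes(table)
  probs <- pt_probs(table)
  auc <- stats::setNames(rep(NA_real_, length(cl)), cl)
  for (k in seq_along(cl)) {
    pos <- table$true_label == cl[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(probs[, k])                 # midranks for ties
    auc[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (anyNA(auc))
    warning("AUC undefined for class(es) without positives or negatives: ",
            paste(cl[is.na(auc)], collapse = ", "))
  list(per_class = auc, macro_auc = mean(auc, na.rm = TRUE))
}

#' Macro one-vs-rest AUC
#' @param table a [prediction_table()].
#' @return Scalar macro-AUC.
#' @export
macro_auc <- function(table) auc_ovr(table)$macro_auc

#' Full metrics report for a prediction table
#'
#' Per-class precision, recall, F1, one-vs-rest AUC and support; overall
#' accuracy; balanced accuracy (mean per-class recall); unweighted macro
#' precision/recall/F1 and macro-AUC; and the confusion matrix.
#'
#' @param table a non-empty [prediction_table()].
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(table) {
  if (!inherits(table, "prediction_table") || nrow(table) == 0L)
    stop("need a non-empty prediction_table")
  cl <- pt_classes(table)
  cm <- confusion_matrix(table)
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  precision <- ifelse(pred_tot == 0, 0, tp / pred_tot)
  recall <- ifelse(support == 0, NA_real_, tp / support)
  f1 <- f1_score(precision, ifelse(is.na(recall), 0, recall))
  f1[is.na(recall)] <- NA_real_
  aucs <- suppressWarnings(auc_ovr(table))
  present <- support > 0
  structure(list(
    classes = cl,
    per_class = data.frame(class = cl, precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1),
                           auc = unname(aucs$per_class),
                           support = unname(support),
                           stringsAsFactors = FALSE),
    accuracy = sum(tp) / nrow(table),
    balanced_accuracy = mean(recall[present]),
    macro_precision = mean(precision[present]),
    macro_recall = mean(recall[present]),
    macro_f1 = mean(f1[present]),
    macro_auc = aucs$macro_auc,
    confusion = cm,
    n = nrow(table)), class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, digits = 3, ...) {
  tab <- x$per_class
  tab[2:5] <- lapply(tab[2:5], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("accuracy %.*f | balanced accuracy %.*f | macro-F1 %.*f | macro-AUC %.*f (n = %d)\n",
              digits, x$accuracy, digits, x$balanced_accuracy,
              digits, x$macro_f1, digits, x$macro_auc, x$n))
  invisible(x)
}

#' Serialize a metrics report like a per-class results table
#'
#' One row per class plus `accuracy` and `balanced accuracy` footer rows.
#'
#' @param x a [metrics_report()].
#' @param ... unused.
#' @return Data frame.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  body <- x$per_class
  foot <- data.frame(class = c("accuracy", "balanced accuracy"),
                     precision = NA, recall = NA, f1 = NA,
                     auc = c(x$accuracy, x$balanced_accuracy),
                     support = c(x$n, NA))
  names(foot) <- names(body)
  rbind(body, foot)
}

## Sequence aggregation -----------------------------------------------------

#' Aggregate frame-level predictions to sequence level
#'
#' Frame class probabilities are averaged within each sequence and the
#' sequence label is the class with the highest mean probability (ties to
#' the lowest class index).
#'
#' @param table a frame-level [prediction_table()].
#' @return A sequence-level [prediction_table()] (one row per sequence,
#'   `frame_id` = `sequence_id`).
#' @export
aggregate_sequences <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  lab_per_seq <- tapply(table$true_label, table$sequence_id,
                        function(l) length(unique(l)))
  if (any(lab_per_seq != 1L))
    stop("sequences with inconsistent true labels")
  cl <- pt_classes(table)
  probs <- pt_probs(table)
  sid <- factor(table$sequence_id, levels = unique(table$sequence_id))
  mean_probs <- apply(probs, 2, function(p) tapply(p, sid, mean))
  if (is.null(dim(mean_probs)))
    mean_probs <- matrix(mean_probs, nrow = 1,
                         dimnames = list(levels(sid), cl))
  truth <- tapply(table$true_label, sid, `[`, 1L)
  prediction_table(frame_id = rownames(mean_probs),
                   sequence_id = rownames(mean_probs),
                   true_label = unname(truth[rownames(mean_probs)]),
                   probs = mean_probs)
}
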