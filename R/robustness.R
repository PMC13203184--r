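## Degradation curves, failure cases, learning curves -----------------------

#' Compute an artifact-by-severity degradation curve
#'
#' For every severity on the family's grid, every test frame is corrupted
#' ([apply_artifact()] with deterministic per-frame seeding), predictions
#' are recomputed, frame- and sequence-level metrics are reported, and each
#' tracked metric's change versus the severity-0 baseline is quantified by
#' the paired clustered bootstrap.  Raw p-values are Holm-adjusted within
#' the curve (one family = all severities of one model-artifact table,
#' including severity 0).  Baseline predictions are computed once and
#' reused, so the severity-0 row has `delta = 0`, CI `[0, 0]`, `p = 1`
#' exactly.
#'
#' @param model a trained classifier with a [predict_proba()] method.
#' @param frames named list of test [echo_frame()]s (must be disjoint from
#'   training sequences; not checked here).
#' @param family artifact family (see [severity_grid()]).
#' @param severities severity vector (default the family's grid).
#' @param boot a [bootstrap_config()].
#' @param base_seed seed for artifact noise streams.
#' @param metrics named list of tracked metric functions; deltas are
#'   computed for each (defaults: frame-level macro-AUC and sequence-level
#'   balanced accuracy).
#' @return Object of class `degradation_curve`.
#' @export
degradation_curve <- function(model, frames, family, severities = NULL,
                              boot = bootstrap_config(), base_seed = 0L,
                              metrics = list(
                                macro_auc = macro_auc,
                                seq_balanced_accuracy = function(t)
                                  balanced_accuracy(aggregate_sequences(t)))) {
  if (is.null(severities)) severities <- severity_grid(family)
  stopifnot(severities[1] == 0, !is.unsorted(severities, strictly = TRUE))
  baseline <- predict_proba(model, frames)
  frame_reports <- list(); seq_reports <- list(); deltas <- list()
  tables <- list()
  for (s in severities) {
    key <- format(s)
    tab <- if (s == 0) baseline else {
      spec <- artifact_spec(family, s)
      degraded <- lapply(frames, apply_artifact, spec = spec,
                         base_seed = base_seed)
      predict_proba(model, degraded)
    }
    tables[[key]] <- tab
    frame_reports[[key]] <- metrics_report(tab)
    seq_reports[[key]] <- metrics_report(aggregate_sequences(tab))
    deltas[[key]] <- lapply(metrics, function(m)
      paired_delta(baseline, tab, m, boot))
  }
  ## Holm family: all severities within this curve, per tracked metric
  for (mname in names(metrics)) {
    praw <- vapply(deltas, function(d) d[[mname]]$p_raw, numeric(1))
    ph <- holm_adjust(praw)
    for (i in seq_along(deltas)) {
      deltas[[i]][[mname]]$p_holm <- ph[i]
      deltas[[i]][[mname]]$significant <- ph[i] <= boot$alpha
    }
  }
  structure(list(family = family, severities = severities,
                 baseline_table = baseline, tables = tables,
                 frame_reports = frame_reports, seq_reports = seq_reports,
                 deltas = deltas, metrics = names(metrics),
                 boot = boot, base_seed = base_seed),
            class = "degradation_curve")
}

#' Tabulate a degradation curve like the published delta tables
#'
#' One row per severity with baseline metric, degraded metric, delta,
#' percentile CI, raw and Holm-adjusted empirical p-values and the
#' significance flag at the bootstrap alpha.
#'
#' @param x a [degradation_curve()].
#' @param metric which tracked metric to tabulate (default the first).
#' @param ... unused.
#' @return Data frame.
#' @export
as.data.frame.degradation_curve <- function(x, metric = x$metrics[1], ...) {
  rows <- lapply(seq_along(x$severities), function(i) {
    d <- x$deltas[[i]][[metric]]
    data.frame(severity = x$severities[i],
               baseline = metric_point(x, 1L, metric),
               degraded = metric_point(x, i, metric),
               delta = d$delta, ci_low = d$ci_low, ci_high = d$ci_high,
               p_raw = d$p_raw, p_holm = d$p_holm,
               significant = d$significant)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

metric_point <- function(x, i, metric) {
  rep_f <- x$frame_reports[[i]]; rep_s <- x$seq_reports[[i]]
  switch(metric,
         macro_auc = rep_f$macro_auc,
         balanced_accuracy = rep_f$balanced_accuracy,
         seq_balanced_accuracy = rep_s$balanced_accuracy,
         NA_real_)
}

#' @export
#' @method print degradation_curve
print.degradation_curve <- function(x, ...) {
  cat(sprintf("<degradation_curve: %s, %d severities, metrics %s>\n",
              x$family, length(x$severities),
              paste(x$metrics, collapse = ", ")))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
plot.degradation_curve <- function(x, metric = x$metrics[1], ...) {
  df <- as.data.frame(x, metric = metric)
  plot(df$severity, df$degraded, type = "b", pch = 19,
       xlab = sprintf("%s severity", x$family), ylab = metric,
       ylim = range(c(df$degraded, df$baseline)), ...)
  graphics::abline(h = df$baseline[1], lty = 2, col = "grey50")
  invisible(df)
}

## Failure cases -------------------------------------------------------------

#' Extract failure cases caused by an artifact
#'
#' A failure case is a unit (sequence by default) that the model classifies
#' correctly at baseline with true-class probability above `threshold`, but
#' misclassifies after artifact introduction.  The reported
#' `delta_true_prob` is degraded minus baseline probability of the true
#' class; rows are sorted by it, most severe drop first.
#'
#' @param baseline,degraded [prediction_table()]s over the same frames.
#' @param threshold baseline true-class probability cutoff.
#' @param level `"sequence"` (aggregate first) or `"frame"`.
#' @return Data frame with one row per failure case.
#' @export
failure_cases <- function(baseline, degraded, threshold = 0.8,
                          level = c("sequence", "frame")) {
  level <- match.arg(level)
  if (!setequal(baseline$frame_id, degraded$frame_id))
    stop("tables must cover the same frames")
  if (level == "sequence") {
    baseline <- aggregate_sequences(baseline)
    degraded <- aggregate_sequences(degraded)
  }
  degraded <- pt_subset(degraded, match(baseline$frame_id, degraded$frame_id))
  cl <- pt_classes(baseline)
  pb <- pt_probs(baseline); pd <- pt_probs(degraded)
  ti <- match(baseline$true_label, cl)
  true_pb <- pb[cbind(seq_len(nrow(pb)), ti)]
  true_pd <- pd[cbind(seq_len(nrow(pd)), ti)]
  keep <- baseline$predicted_label == baseline$true_label &
    true_pb > threshold &
    degraded$predicted_label != degraded$true_label
  out <- data.frame(
    sequence_id = baseline$sequence_id[keep],
    true_view = baseline$true_label[keep],
    baseline_predicted = baseline$predicted_label[keep],
    baseline_true_prob = true_pb[keep],
    degraded_predicted = degraded$predicted_label[keep],
    degraded_true_prob = true_pd[keep],
    delta_true_prob = true_pd[keep] - true_pb[keep],
    stringsAsFactors = FALSE)
  out[order(out$delta_true_prob), , drop = FALSE]
}

## Learning curves ------------------------------------------------------------

#' Learning curve over training-set fractions
#'
#' Trains on stratified sequence-level subsamples of the training split
#' (25/50/75/100% by default) while validation and test sets stay fixed,
#' repeating each fraction over several seeds.
#'
#' @param frames named list of all [echo_frame()]s.
#' @param manifest dataset manifest.
#' @param split a [split_sequences()] assignment.
#' @param trainer function `(frames, seed) -> model` fitting a classifier
#'   on the supplied training frames.
#' @param fractions numeric vector in (0, 1].
#' @param seeds integer vector of replication seeds.
#' @param metric evaluation metric on the sequence-aggregated test table
#'   (default balanced accuracy).
#' @return Data frame `(fraction, seed, value)` plus per-fraction summary
#'   in attribute `"summary"`.
#' @export
learning_curve <- function(frames, manifest, split, trainer,
                           fractions = c(0.25, 0.5, 0.75, 1),
                           seeds = 1L,
                           metric = balanced_accuracy) {
  stopifnot(all(fractions > 0), all(fractions <= 1), length(seeds) >= 1)
  train_man <- manifest[manifest$sequence_id %in% split$train_sequences, ]
  test_frames <- frames[manifest$frame_id[
    manifest$sequence_id %in% split$test_sequences]]
  seq_label <- tapply(train_man$label, train_man$sequence_id, `[`, 1L)
  classes <- sort(unique(unname(seq_label)))
  rows <- list()
  for (f in fractions) for (s in seeds) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(derive_seed(s, "learning_curve", f))
    picked <- character(0)
    for (cl in classes) {
      ids <- sort(names(seq_label)[seq_label == cl])
      k <- round(f * length(ids))
      if (k < 1L)
        stop(sprintf("fraction %.2f leaves class %s without sequences", f, cl))
      picked <- c(picked, if (f == 1) ids else sample(ids, k))
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    sub_frames <- frames[train_man$frame_id[train_man$sequence_id %in% picked]]
    model <- trainer(sub_frames, s)
    tab <- aggregate_sequences(predict_proba(model, test_frames))
    rows[[length(rows) + 1L]] <- data.frame(fraction = f, seed = s,
                                            value = metric(tab))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  summ <- do.call(rbind, lapply(split(df, df$fraction), function(d)
    data.frame(fraction = d$fraction[1], mean = mean(d$value),
               sd = stats::sd(d$value), n = nrow(d))))
  rownames(summ) <- NULL
  attr(df, "summary") <- summ
  df
}
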