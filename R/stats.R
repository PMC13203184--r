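## Sequence-clustered bootstrap inference -----------------------------------
##
## Frames within a clip are temporally correlated, so uncertainty is
## quantified by resampling whole sequences (clusters) with replacement,
## keeping all their frames.  Paired designs reuse one sequence resample
## for both tables per replicate, removing shared cluster noise from the
## difference.

#' Bootstrap configuration
#'
#' @param B number of bootstrap replicates.
#' @param alpha two-sided CI level complement (CI = `alpha/2`,
#'   `1 - alpha/2` percentiles).
#' @param seed integer seed for the resampling stream.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed)),
            class = "bootstrap_config")
}

## row indices per sequence, in order of first appearance
rows_by_sequence <- function(sequence_id) {
  sid <- factor(sequence_id, levels = unique(sequence_id))
  split(seq_along(sequence_id), sid)
}

#' Clustered percentile bootstrap confidence interval
#'
#' Resamples sequences with replacement (same count as observed), keeps all
#' frames of each sampled sequence, recomputes `metric` on the concatenated
#' table, and reports the empirical `alpha/2` / `1 - alpha/2` percentiles
#' (interpolated order statistics, [stats::quantile()] type 7) over `B`
#' replicates.  Deterministic given `config$seed`.
#'
#' @param table a [prediction_table()] with at least one sequence (a single
#'   sequence yields a degenerate CI with a warning).
#' @param metric function `prediction_table -> scalar`, e.g.
#'   [balanced_accuracy()] or [macro_auc()].
#' @param config a [bootstrap_config()].
#' @return List with `point`, `ci_low`, `ci_high` and the replicate vector
#'   `replicates`.
#' @export
clustered_bootstrap_ci <- function(table, metric,
                                   config = bootstrap_config()) {
  stopifnot(inherits(table, "prediction_table"))
  groups <- rows_by_sequence(table$sequence_id)
  n_seq <- length(groups)
  if (n_seq < 2L)
    warning("only one sequence: bootstrap CI degenerates to the point estimate")
  point <- metric(table)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, "clustered_bootstrap"))
  reps <- vapply(seq_len(config$B), function(b) {
    idx <- unlist(groups[sample.int(n_seq, n_seq, replace = TRUE)],
                  use.names = FALSE)
    suppressWarnings(metric(pt_subset(table, idx)))
  }, numeric(1))
  reps <- drop_undefined_replicates(reps)
  ci <- unname(stats::quantile(reps, c(config$alpha / 2, 1 - config$alpha / 2),
                               type = 7))
  list(point = point, ci_low = ci[1], ci_high = ci[2], replicates = reps)
}

#' Paired clustered bootstrap for a metric difference
#'
#' Computes `delta = metric(degraded) - metric(baseline)` and its paired
#' clustered bootstrap distribution: per replicate one sequence resample
#' drives both tables.  The empirical two-sided p-value is
#' `min(1, 2 * min(#\{delta* >= 0\} + 1, #\{delta* <= 0\} + 1) / (B + 1))`,
#' which yields exactly `p = 1` when every replicate difference is zero
#' (identity degradation) and `p = 0.002` at `B = 1000` for extreme effects.
#'
#' @param baseline,degraded [prediction_table()]s covering identical
#'   `frame_id`/`sequence_id` sets (the degraded table is realigned to the
#'   baseline row order).
#' @param metric function `prediction_table -> scalar`.
#' @param config a [bootstrap_config()].
#' @return Object of class `paired_delta`: `delta`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_holm` (`NA` until adjusted across a family), `significant`,
#'   `replicates`.
#' @export
paired_delta <- function(baseline, degraded, metric,
                         config = bootstrap_config()) {
  stopifnot(inherits(baseline, "prediction_table"),
            inherits(degraded, "prediction_table"))
  if (!setequal(baseline$frame_id, degraded$frame_id) ||
      nrow(baseline) != nrow(degraded))
    stop("baseline and degraded tables must cover identical frame ids")
  degraded <- pt_subset(degraded, match(baseline$frame_id, degraded$frame_id))
  if (!identical(baseline$sequence_id, degraded$sequence_id))
    stop("baseline and degraded tables must share sequence ids per frame")
  groups <- rows_by_sequence(baseline$sequence_id)
  n_seq <- length(groups)
  delta <- metric(degraded) - metric(baseline)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, "paired_bootstrap"))
  reps <- vapply(seq_len(config$B), function(b) {
    idx <- unlist(groups[sample.int(n_seq, n_seq, replace = TRUE)],
                  use.names = FALSE)
    suppressWarnings(metric(pt_subset(degraded, idx)) -
                       metric(pt_subset(baseline, idx)))
  }, numeric(1))
  reps <- drop_undefined_replicates(reps)
  ci <- unname(stats::quantile(reps, c(config$alpha / 2, 1 - config$alpha / 2),
                               type = 7))
  p_raw <- empirical_p(reps)
  structure(list(delta = delta, ci_low = ci[1], ci_high = ci[2],
                 p_raw = p_raw, p_holm = NA_real_,
                 significant = NA, alpha = config$alpha, B = config$B,
                 replicates = reps),
            class = "paired_delta")
}

## absent-class policy: replicates where the metric is undefined (e.g. a
## resample that lost every negative of a class) are dropped with a logged
## warning rather than poisoning the CI and p-value
drop_undefined_replicates <- function(reps) {
  bad <- !is.finite(reps)
  if (any(bad)) {
    warning(sprintf("dropping %d/%d bootstrap replicate(s) with undefined metric",
                    sum(bad), length(reps)))
    reps <- reps[!bad]
    if (!length(reps)) stop("metric undefined on every bootstrap replicate")
  }
  reps
}

## two-sided, +1-corrected, capped empirical bootstrap p-value
empirical_p <- function(reps) {
  B <- length(reps)
  min(1, 2 * min(sum(reps >= 0) + 1, sum(reps <= 0) + 1) / (B + 1))
}

#' @export
#' @method print paired_delta
print.paired_delta <- function(x, ...) {
  cat(sprintf(
    "<paired_delta: delta %+.4f, 95%% CI [%.4f, %.4f], p_raw %.4f%s>\n",
    x$delta, x$ci_low, x$ci_high, x$p_raw,
    if (!is.na(x$p_holm)) sprintf(", p_holm %.4f", x$p_holm) else ""))
  invisible(x)
}

#' Holm step-down multiple-testing adjustment
#'
#' The i-th smallest p-value is multiplied by `(m - i + 1)` with enforced
#' monotonicity and capping at 1, returned in the original order
#' (delegates to [stats::p.adjust()], whose formula is identical).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order, elementwise `>=` the input.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Paired clustered bootstrap comparison of two models
#'
#' Identical machinery to [paired_delta()] with
#' `delta = metric(table_b) - metric(table_a)` on the same test frames.
#'
#' @param table_a,table_b [prediction_table()]s of two models on the same
#'   frames.
#' @param metric function `prediction_table -> scalar`.
#' @param config a [bootstrap_config()].
#' @return A `paired_delta` object.
#' @export
compare_models <- function(table_a, table_b, metric,
                           config = bootstrap_config()) {
  paired_delta(table_a, table_b, metric, config)
}
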