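test_that("clustered bootstrap CI brackets the replicate distribution", {
  set.seed(31)
  tab <- random_clustered_table(n_seq = 30, frames_per_seq = 5)
  cfg <- bootstrap_config(B = 400, seed = 2)
  res <- clustered_bootstrap_ci(tab, balanced_accuracy, cfg)
  # endpoints recomputed independently from the stored replicate vector
  srt <- sort(res$replicates)
  idx_lo <- 0.025 * (length(srt) - 1) + 1
  idx_hi <- 0.975 * (length(srt) - 1) + 1
  interp <- function(i) {
    f <- floor(i)
    srt[f] + (i - f) * (srt[min(f + 1, length(srt))] - srt[f])
  }
  expect_equal(res$ci_low, interp(idx_lo))
  expect_equal(res$ci_high, interp(idx_hi))
  expect_lte(res$ci_low, res$ci_high)
  # determinism
  res2 <- clustered_bootstrap_ci(tab, balanced_accuracy, cfg)
  expect_identical(res$replicates, res2$replicates)
})

test_that("constant metrics and single sequences give degenerate CIs", {
  tab <- random_clustered_table(n_seq = 10, frames_per_seq = 3)
  res <- clustered_bootstrap_ci(tab, function(t) 0.42,
                                bootstrap_config(B = 50, seed = 1))
  expect_equal(c(res$ci_low, res$ci_high), c(0.42, 0.42))
  one <- echorobust:::pt_subset(tab, which(tab$sequence_id == tab$sequence_id[1]))
  expect_warning(
    r1 <- clustered_bootstrap_ci(one, balanced_accuracy,
                                 bootstrap_config(B = 20, seed = 1)),
    "one sequence")
  expect_equal(r1$ci_low, r1$point)
  expect_equal(r1$ci_high, r1$point)
})

test_that("paired delta is exactly degenerate for identical tables", {
  set.seed(13)
  tab <- random_clustered_table(n_seq = 25, frames_per_seq = 5)
  pd <- paired_delta(tab, tab, balanced_accuracy,
                     bootstrap_config(B = 500, seed = 3))
  expect_identical(pd$delta, 0)
  expect_identical(c(pd$ci_low, pd$ci_high), c(0, 0))
  expect_identical(pd$p_raw, 1)
})

test_that("the empirical p-value follows its +1-corrected two-sided formula", {
  emp <- echorobust:::empirical_p
  expect_equal(emp(c(-3, -2, -1)), 0.5)          # 2 * (0+1) / 4
  expect_equal(emp(rep(0, 100)), 1)              # all-zero replicates
  expect_equal(emp(c(-1, -1, 1)), 1)             # both sides occupied
  expect_equal(emp(rep(-1, 999)), 2 / 1000)      # extreme effect floor
})

test_that("delta sign convention is degraded minus baseline", {
  set.seed(41)
  truth <- rep(view_classes(), each = 10)
  sid <- rep(sprintf("s%02d", 1:20), each = 2)
  good <- matrix(0.04, 40, 4, dimnames = list(NULL, view_classes()))
  good[cbind(1:40, match(truth, view_classes()))] <- 0.88
  base_tab <- make_table(good, truth, sequence_id = sid)
  worse <- good
  flip <- 1:8                                     # degrade two sequences
  worse[flip, ] <- 0.04
  worse[cbind(flip, (match(truth[flip], view_classes()) %% 4) + 1)] <- 0.88
  deg_tab <- make_table(worse, truth, sequence_id = sid)
  pd <- paired_delta(base_tab, deg_tab, balanced_accuracy,
                     bootstrap_config(B = 300, seed = 5))
  expect_lt(pd$delta, 0)
  expect_equal(pd$delta,
               balanced_accuracy(deg_tab) - balanced_accuracy(base_tab))
})

test_that("Holm adjustment matches the step-down formula and is monotone", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  # independent oracle: direct step-down computation
  holm_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
    out <- numeric(m); out[o] <- adj
    out
  }
  set.seed(17)
  for (r in 1:20) {
    p <- round(runif(sample(2:12, 1)), 3)
    expect_equal(holm_adjust(p), holm_oracle(p))
    expect_true(all(holm_adjust(p) >= p))
  }
})

test_that("model comparison is antisymmetric and detects dominance", {
  set.seed(51)
  truth <- rep(view_classes(), each = 12)
  sid <- rep(sprintf("s%02d", 1:24), each = 2)
  strong <- matrix(0.02, 48, 4, dimnames = list(NULL, view_classes()))
  strong[cbind(1:48, match(truth, view_classes()))] <- 0.94
  weak <- matrix(0.04, 48, 4, dimnames = list(NULL, view_classes()))
  wrong <- seq(1, 48, by = 2)                     # half the frames wrong
  hit <- setdiff(1:48, wrong)
  weak[cbind(hit, match(truth[hit], view_classes()))] <- 0.88
  weak[cbind(wrong, (match(truth[wrong], view_classes()) %% 4) + 1)] <- 0.88
  A <- make_table(weak, truth, sequence_id = sid)
  B <- make_table(strong, truth, sequence_id = sid)
  cfg <- bootstrap_config(B = 400, seed = 9)
  same <- compare_models(A, A, balanced_accuracy, cfg)
  expect_equal(same$delta, 0)
  expect_equal(same$p_raw, 1)
  ab <- compare_models(A, B, balanced_accuracy, cfg)
  ba <- compare_models(B, A, balanced_accuracy, cfg)
  expect_equal(ab$delta, -ba$delta)
  expect_gt(ab$ci_low, 0)                         # CI excludes 0
  expect_lt(ab$p_raw, 0.05)
})

test_that("pairing shrinks replicate variance relative to unpaired resampling", {
  set.seed(61)
  base_tab <- random_clustered_table(n_seq = 40, frames_per_seq = 5, q = 0.8)
  # degraded: flip predictions of 30% of frames
  P <- pt_probs(base_tab)
  n <- nrow(P)
  flip <- sample(n, round(0.3 * n))
  P2 <- P
  P2[flip, ] <- P[flip, sample(4)]
  colnames(P2) <- pt_classes(base_tab)
  deg_tab <- prediction_table(frame_id = base_tab$frame_id,
                              sequence_id = base_tab$sequence_id,
                              true_label = base_tab$true_label,
                              probs = P2)
  cfg <- bootstrap_config(B = 500, seed = 4)
  paired <- paired_delta(base_tab, deg_tab, balanced_accuracy, cfg)
  r_base <- clustered_bootstrap_ci(base_tab, balanced_accuracy,
                                   bootstrap_config(B = 500, seed = 5))
  r_deg <- clustered_bootstrap_ci(deg_tab, balanced_accuracy,
                                  bootstrap_config(B = 500, seed = 6))
  unpaired_var <- stats::var(r_deg$replicates - r_base$replicates)
  expect_lte(stats::var(paired$replicates), unpaired_var)
})

test_that("mismatched tables are rejected", {
  tab <- random_clustered_table(n_seq = 5, frames_per_seq = 2)
  other <- echorobust:::pt_subset(tab, 1:8)
  expect_error(paired_delta(tab, other, balanced_accuracy,
                            bootstrap_config(B = 10, seed = 1)),
               "identical frame ids")
})
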