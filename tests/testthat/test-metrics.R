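test_that("prediction tables enforce the probability contract", {
  P <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.8, 0.1), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  tab <- make_table(P, c("A", "B"))
  expect_equal(tab$predicted_label, c("A", "B"))
  bad <- P; bad[1, 1] <- 0.9
  expect_error(make_table(bad, c("A", "B")), "sum to 1")
  neg <- P; neg[1, ] <- c(1.2, -0.1, -0.1)
  expect_error(make_table(neg, c("A", "B")), "non-negative")
  # argmax ties break to the lowest class index
  tie <- make_table(matrix(c(0.5, 0.5), 1, 2,
                           dimnames = list(NULL, c("A", "B"))), "B")
  expect_equal(tie$predicted_label, "A")
})

test_that("per-class metrics reproduce hand arithmetic", {
  expect_equal(round(f1_score(0.741, 1.000), 3), 0.851)
  expect_equal(f1_score(0, 0), 0)
  # 3-class toy confusion [[2,1,0],[0,3,0],[1,0,1]]
  truth <- c(rep("a", 3), rep("b", 3), rep("c", 2))
  pred  <- c("a", "a", "b", "b", "b", "b", "a", "c")
  P <- matrix(0.05, 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  P[cbind(1:8, match(pred, c("a", "b", "c")))] <- 0.9
  tab <- make_table(P, truth)
  rep_ <- metrics_report(tab)
  expect_equal(unname(rep_$confusion),
               matrix(c(2, 1, 0, 0, 3, 0, 1, 0, 1), 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(rep_$per_class$recall, c(2/3, 1, 1/2))
  expect_equal(rep_$balanced_accuracy, mean(c(2/3, 1, 1/2)))
  expect_equal(balanced_accuracy(tab), rep_$balanced_accuracy)
  # perfect predictor
  perfect <- make_table(P[c(1, 4, 8), ], c("a", "b", "c"))
  r2 <- metrics_report(perfect)
  expect_equal(r2$accuracy, 1)
  expect_equal(r2$balanced_accuracy, 1)
  expect_equal(r2$macro_f1, 1)
})

test_that("balanced accuracy handles recall vectors and degenerate predictors", {
  expect_equal(balanced_accuracy(c(0.760, 0.850, 0.856, 1.000)), 0.8665)
  expect_equal(round(balanced_accuracy(c(0.870, 0.775, 0.898, 0.700)), 3),
               0.811)
  # constant single-class predictor over 4 present classes
  P <- matrix(0.1, 8, 4, dimnames = list(NULL, view_classes()))
  P[, 1] <- 0.7
  tab <- make_table(P, rep(view_classes(), each = 2))
  expect_equal(balanced_accuracy(tab), 0.25)
})

test_that("balanced accuracy of label-permuted predictions is centred on 1/K", {
  set.seed(11)
  vals <- replicate(200, {
    truth <- sample(view_classes(), 40, TRUE)
    P <- matrix(0.04, 40, 4, dimnames = list(NULL, view_classes()))
    P[cbind(1:40, sample(4, 40, TRUE))] <- 0.88
    balanced_accuracy(make_table(P, truth))
  })
  expect_lt(abs(mean(vals) - 0.25), 3 * stats::sd(vals) / sqrt(200))
})

test_that("rank-statistic AUC agrees with brute-force pair counting", {
  # worked example: labels (+,+,-,-), scores (0.9, 0.4, 0.6, 0.1)
  P <- cbind(pos = c(0.9, 0.4, 0.6, 0.1), neg = c(0.1, 0.6, 0.4, 0.9))
  tab <- make_table(P, c("pos", "pos", "neg", "neg"))
  expect_equal(auc_ovr(tab)$per_class[["pos"]], 0.75)
  # exhaustive check on random small tables (<= 12 rows), with ties
  set.seed(21)
  for (r in 1:40) {
    n <- sample(4:12, 1)
    truth <- sample(c("x", "y"), n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("x", "y")
    sx <- round(runif(n), 1)            # coarse grid forces ties
    P <- cbind(x = sx, y = 1 - sx)
    tab <- make_table(P, truth)
    a <- auc_ovr(tab)
    expect_equal(a$per_class[["x"]], auc_bruteforce(sx, truth == "x"))
    expect_equal(a$per_class[["y"]], auc_bruteforce(1 - sx, truth == "y"))
  }
  # all scores identical -> every AUC 0.5 by midranks
  same <- make_table(matrix(0.5, 6, 2, dimnames = list(NULL, c("x", "y"))),
                     rep(c("x", "y"), 3))
  expect_equal(unname(auc_ovr(same)$per_class), c(0.5, 0.5))
  # perfectly separating scores
  sep <- make_table(cbind(x = c(0.9, 0.8, 0.2, 0.1),
                          y = c(0.1, 0.2, 0.8, 0.9)),
                    c("x", "x", "y", "y"))
  expect_equal(auc_ovr(sep)$macro_auc, 1)
})

test_that("macro metrics are equivariant under class relabelling", {
  set.seed(5)
  truth <- sample(view_classes(), 60, TRUE)
  P <- matrix(runif(240), 60, 4, dimnames = list(NULL, view_classes()))
  P <- P / rowSums(P)
  tab <- make_table(P, truth)
  r <- metrics_report(tab)
  perm <- c(3, 1, 4, 2)
  P2 <- P[, perm]
  colnames(P2) <- view_classes()
  map <- stats::setNames(view_classes(), view_classes()[perm])
  tab2 <- make_table(P2, unname(map[truth]))
  r2 <- metrics_report(tab2)
  expect_equal(r2$balanced_accuracy, r$balanced_accuracy)
  expect_equal(r2$macro_f1, r$macro_f1)
  expect_equal(r2$macro_auc, r$macro_auc)
})

test_that("sequence aggregation averages probabilities with stable ties", {
  P <- matrix(c(0.6, 0.4,
                0.2, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("c1", "c2")))
  tab <- make_table(P, c("c2", "c2"), sequence_id = c("s1", "s1"))
  agg <- aggregate_sequences(tab)
  expect_equal(nrow(agg), 1L)
  expect_equal(unname(pt_probs(agg)[1, ]), c(0.4, 0.6))
  expect_equal(agg$predicted_label, "c2")
  # exact tie -> lowest class index
  Pt <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("c1", "c2")))
  tt <- aggregate_sequences(make_table(Pt, c("c1", "c1"),
                                       sequence_id = c("s1", "s1")))
  expect_equal(tt$predicted_label, "c1")
  # frame order and duplication invariance
  set.seed(9)
  truth <- rep(sample(view_classes(), 6, TRUE), each = 4)
  Pr <- matrix(runif(96), 24, 4, dimnames = list(NULL, view_classes()))
  Pr <- Pr / rowSums(Pr)
  big <- make_table(Pr, truth, sequence_id = rep(sprintf("s%d", 1:6), each = 4))
  a1 <- aggregate_sequences(big)
  shuf <- echorobust:::pt_subset(big, sample(nrow(big)))
  a2 <- aggregate_sequences(shuf)
  expect_equal(pt_probs(a2)[match(a1$frame_id, a2$frame_id), ], pt_probs(a1))
  dup <- echorobust:::pt_subset(big, rep(seq_len(nrow(big)), 2))
  a3 <- aggregate_sequences(dup)
  expect_equal(pt_probs(a3)[match(a1$frame_id, a3$frame_id), ], pt_probs(a1))
  # inconsistent truth within a sequence is rejected
  badtab <- big
  badtab$true_label[1] <- setdiff(view_classes(), badtab$true_label[1])[1]
  expect_error(aggregate_sequences(badtab), "inconsistent")
})
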