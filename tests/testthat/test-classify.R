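test_that("HOG+SVM separates well-separated phantom classes perfectly", {
  cfg <- phantom_config(image_height = 96, image_width = 96,
                        frames_per_sequence = 5,
                        sequences_per_class = c(A2C = 4L, A5C = 4L))
  ds <- generate_dataset(cfg, seed = 8)          # 40 frames, 2 vs 5 chambers
  mod <- train_hog_svm(ds$frames, config = small_hog_config(), seed = 1)
  tab <- predict_proba(mod, ds$frames)
  expect_equal(mean(tab$true_label == tab$predicted_label), 1)
  probs <- pt_probs(tab)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(probs >= 0))
  # same data, same seed -> identical behaviour
  mod2 <- train_hog_svm(ds$frames, config = small_hog_config(), seed = 1)
  tab2 <- predict_proba(mod2, ds$frames)
  expect_identical(pt_probs(tab), pt_probs(tab2))
  expect_error(train_hog_svm(ds$frames[tab$true_label == "A2C"]),
               "2 classes")
})

test_that("prediction tables are stateless and schema-stable", {
  mod <- small_svm()
  fr <- small_test_frames()[1:10]
  tab <- predict_proba(mod, fr)
  perm <- sample(length(fr))
  tab_perm <- predict_proba(mod, fr[perm])
  expect_equal(pt_probs(tab_perm)[match(tab$frame_id, tab_perm$frame_id), ],
               pt_probs(tab))
  # argmax consistent with probabilities
  expect_equal(tab$predicted_label,
               pt_classes(tab)[max.col(pt_probs(tab), ties.method = "first")])
  # degraded copies keep schema and frame ids
  deg <- lapply(fr, apply_artifact, spec = artifact_spec("speckle", 2),
                base_seed = 3)
  tab_deg <- predict_proba(mod, deg)
  expect_identical(tab_deg$frame_id, tab$frame_id)
  expect_identical(names(tab_deg), names(tab))
})

test_that("the small CNN can drive training accuracy to 100%", {
  ds <- small_dataset()
  m <- ds$manifest
  sub <- m$frame_id[seq(1, nrow(m), by = 8)][1:20]
  fr <- ds$frames[sub]
  cc <- cnn_config(lr_backbone = 5e-3, lr_head = 1e-2, max_epochs = 100,
                   patience = Inf, dropout = 0, weighted_sampling = FALSE,
                   batch_size = 8)
  mod <- train_small_cnn(fr, val_frames = fr, config = cc, seed = 1)
  tab <- predict_proba(mod, fr)
  expect_equal(mean(tab$true_label == tab$predicted_label), 1)
  expect_true(all(abs(rowSums(pt_probs(tab)) - 1) < 1e-6))
  # bitwise training determinism under a fixed seed
  mod2 <- train_small_cnn(fr, val_frames = fr, config = cc, seed = 1)
  expect_identical(mod$par, mod2$par)
})

test_that("early stopping halts within patience of the validation minimum", {
  ds <- small_dataset()
  m <- ds$manifest
  tr <- m$frame_id[seq(1, nrow(m), by = 5)][1:30]
  va <- m$frame_id[seq(2, nrow(m), by = 11)][1:12]
  cc <- cnn_config(lr_backbone = 2e-3, lr_head = 8e-3, max_epochs = 25,
                   patience = 3, batch_size = 16)
  mod <- train_small_cnn(ds$frames[tr], val_frames = ds$frames[va],
                         config = cc, seed = 2)
  ran <- nrow(mod$history)
  expect_lte(ran - mod$best_epoch, cc$patience)
  expect_equal(mod$best_epoch, which.min(mod$history$val_loss))
  expect_error(train_small_cnn(ds$frames[tr], val_frames = list(),
                               config = cc, seed = 1), "non-empty")
})

test_that("frozen-feature logistic regression honours its contracts", {
  ds <- small_dataset()
  m <- ds$manifest
  tr <- m$frame_id[seq(1, nrow(m), by = 3)]
  va <- m$frame_id[seq(2, nrow(m), by = 7)]
  # perfectly informative features: one-hot of the true class
  onehot <- function(f) {
    v <- numeric(4)
    v[match(attr(f, "label"), view_classes())] <- 1
    v + 0.01 * as.vector(unclass(f))[1:4]       # break exact constancy
  }
  mod <- frozen_features_lr(ds$frames[tr], extractor = onehot,
                            val_frames = ds$frames[va], seed = 1)
  tab <- predict_proba(mod, ds$frames[va])
  expect_equal(mean(tab$true_label == tab$predicted_label), 1)
  expect_true(all(abs(rowSums(pt_probs(tab)) - 1) < 1e-6))
  expect_true(is.numeric(mod$lambda) && length(mod$lambda) == 1)
  expect_true(is.finite(mod$validation_logloss))
  expect_error(
    frozen_features_lr(ds$frames[tr], extractor = function(f) c(1, 1),
                       val_frames = ds$frames[va]),
    "degenerate")
})

test_that("sequence-level competence on the study-shaped dataset", {
  ds <- default_dataset()
  m <- ds$manifest
  sp <- split_sequences(m, 0.2, seed = 42)
  train_man <- m[m$sequence_id %in% sp$train_sequences, ]
  vs <- split_validation_frames(train_man, 0.2, seed = 42)
  te <- ds$frames[m$frame_id[m$sequence_id %in% sp$test_sequences]]
  # HOG + SVM baseline
  svm_mod <- train_hog_svm(ds$frames[vs$fit_frames], seed = 42)
  svm_seq <- aggregate_sequences(predict_proba(svm_mod, te))
  expect_gte(balanced_accuracy(svm_seq), 0.90)
  # small CNN, desk-scale recipe
  cc <- cnn_config(input_size = 48, channels = c(12L, 24L, 48L),
                   lr_backbone = 2e-3, lr_head = 8e-3,
                   max_epochs = 30, patience = 8)
  cnn_mod <- train_small_cnn(ds$frames[vs$fit_frames],
                             val_frames = ds$frames[vs$validation_frames],
                             config = cc, seed = 42)
  cnn_seq <- aggregate_sequences(predict_proba(cnn_mod, te))
  expect_gte(balanced_accuracy(cnn_seq), 0.90)
})
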