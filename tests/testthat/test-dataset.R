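# a light-weight manifest with the study's sequence counts, no pixels needed
fake_manifest <- function(seqs = c(A2C = 52, A3C = 39, A4C = 107, A5C = 19),
                          frames_per_seq = 10) {
  rows <- list()
  for (cl in names(seqs)) for (i in seq_len(seqs[[cl]])) {
    sid <- sprintf("%s_s%03d", cl, i)
    rows[[sid]] <- data.frame(
      frame_id = sprintf("%s_f%02d", sid, seq_len(frames_per_seq) - 1L),
      sequence_id = sid, label = cl,
      frame_index = seq_len(frames_per_seq) - 1L,
      path = "x.png", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("sequence split is stratified, leak-free and deterministic", {
  man <- fake_manifest()
  sp <- split_sequences(man, 0.2, seed = 7)
  expect_length(sp$test_sequences, 43)          # round(0.2 * 217)
  expect_length(intersect(sp$train_sequences, sp$test_sequences), 0)
  # per-class share within one sequence of the global fraction
  seq_label <- tapply(man$label, man$sequence_id, `[`, 1)
  for (cl in view_classes()) {
    n_cl <- sum(seq_label == cl)
    n_test <- sum(seq_label[sp$test_sequences] == cl)
    expect_lte(abs(n_test - 0.2 * n_cl), 1)
  }
  # frames of one sequence never straddle the split
  side <- sp$sequence[man$sequence_id]
  expect_true(all(tapply(side, man$sequence_id,
                         function(s) length(unique(s))) == 1))
  sp2 <- split_sequences(man, 0.2, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test_sequences,
                         split_sequences(man, 0.2, seed = 8)$test_sequences))
})

test_that("degenerate split requests are rejected", {
  man <- fake_manifest()
  expect_error(split_sequences(man, 0), "between 0 and 1")
  expect_error(split_sequences(man, 1), "between 0 and 1")
  tiny <- fake_manifest(seqs = c(A2C = 1, A4C = 5))
  expect_error(split_sequences(tiny, 0.2), "at least 2")
})

test_that("validation split is a stratified frame-level partition", {
  man <- fake_manifest(seqs = c(A2C = 10), frames_per_seq = 10)  # 100 frames
  vs <- split_validation_frames(man, 0.2, seed = 1)
  expect_length(vs$validation_frames, 20)
  expect_setequal(c(vs$fit_frames, vs$validation_frames), man$frame_id)
  expect_length(intersect(vs$fit_frames, vs$validation_frames), 0)
  expect_identical(vs, split_validation_frames(man, 0.2, seed = 1))
  # frame-level protocol: one clip's frames may land on both sides
  man2 <- fake_manifest(seqs = c(A2C = 5, A3C = 5), frames_per_seq = 10)
  vs2 <- split_validation_frames(man2, 0.2, seed = 3)
  sides <- ifelse(man2$frame_id %in% vs2$validation_frames, "val", "fit")
  expect_gt(sum(tapply(sides, man2$sequence_id,
                       function(s) length(unique(s))) == 2), 0)
  # sequence-level escape hatch keeps clips together
  vs3 <- split_validation_frames(man2, 0.2, seed = 3, by_sequence = TRUE)
  sides3 <- ifelse(man2$frame_id %in% vs3$validation_frames, "val", "fit")
  expect_true(all(tapply(sides3, man2$sequence_id,
                         function(s) length(unique(s))) == 1))
})

test_that("preprocessing standardizes to 256x256x3 with ImageNet constants", {
  f <- matrix(runif(256 * 256), 256, 256)
  out <- preprocess_frame(f)
  expect_equal(dim(out), c(256, 256, 3))
  norm <- imagenet_norm()
  expect_equal(out[, , 2], (f - norm$mean[2]) / norm$sd[2])
  const <- matrix(norm$mean[1], 256, 256)
  expect_equal(max(abs(preprocess_frame(const)[, , 1])), 0)
  odd <- matrix(runif(128 * 200), 128, 200)
  expect_equal(dim(preprocess_frame(odd)), c(256, 256, 3))
  expect_error(preprocess_frame(matrix(numeric(0), 0, 0)), "empty")
})

test_that("augmentation identities: zero transform, flip involution, rotation round-trip", {
  # smooth frame (no speckle texture): interpolation error is measurable
  # but small; high-frequency texture would inflate it
  f <- generate_sequence("A4C", seed = 1,
                         config = phantom_config(image_height = 96,
                                                 image_width = 96,
                                                 baseline_speckle_sigma = 0)
                         )$frames[[1]]
  expect_identical(augment_frame(f, angle = 0, flip = FALSE), f)
  expect_identical(augment_frame(augment_frame(f, angle = 0, flip = TRUE),
                                 angle = 0, flip = TRUE), f)
  rt <- augment_frame(augment_frame(f, angle = 10, flip = FALSE),
                      angle = -10, flip = FALSE)
  expect_lt(mean(abs(unclass(rt) - unclass(f))), 0.02)
})

test_that("manifest validation catches identity violations", {
  man <- fake_manifest(seqs = c(A2C = 2), frames_per_seq = 2)
  expect_silent(validate_manifest(man))
  dup <- man; dup$frame_id[2] <- dup$frame_id[1]
  expect_error(validate_manifest(dup), "unique")
  mixed <- man; mixed$label[1] <- "A4C"
  expect_error(validate_manifest(mixed), "exactly one label")
})
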