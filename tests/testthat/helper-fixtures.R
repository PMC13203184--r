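# Shared fixtures, built lazily and memoized for the whole test run.
# All fixture seeds are fixed constants.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# full study-shaped dataset (217 sequences / 2170 frames, 256x256)
default_dataset <- function() {
  memo("default_ds", generate_dataset(phantom_config(), seed = 42))
}

# small dataset for classifier/bootstrap tests: 8 clips/class x 5 frames, 96px
small_dataset <- function() {
  memo("small_ds", generate_dataset(
    phantom_config(image_height = 96, image_width = 96,
                   frames_per_sequence = 5,
                   sequences_per_class = c(A2C = 8L, A3C = 8L,
                                           A4C = 8L, A5C = 8L)),
    seed = 42))
}

# smaller descriptor + stiffer margin: the 96-px fixtures have soft,
# low-gradient chamber edges that need finer cells and a higher cost
small_hog_config <- function() hog_config(resize = 64, cell = 8,
                                          svm_cost = 100)

# split + trained HOG+SVM on the small dataset
small_split <- function() {
  memo("small_split", split_sequences(small_dataset()$manifest, 0.25, seed = 42))
}

small_svm <- function() {
  memo("small_svm", {
    ds <- small_dataset()
    sp <- small_split()
    tr <- ds$manifest$frame_id[ds$manifest$sequence_id %in% sp$train_sequences]
    train_hog_svm(ds$frames[tr], config = small_hog_config(), seed = 42)
  })
}

small_test_frames <- function() {
  ds <- small_dataset()
  sp <- small_split()
  ds$frames[ds$manifest$frame_id[
    ds$manifest$sequence_id %in% sp$test_sequences]]
}

# bare pixel matrix of a frame, identity attributes stripped
pixels_of <- function(f) {
  m <- unclass(f)
  attributes(m) <- list(dim = dim(m))
  m
}

# deterministic prediction table built from explicit probabilities
make_table <- function(probs, truth, sequence_id = NULL, classes = NULL) {
  probs <- as.matrix(probs)
  if (!is.null(classes)) colnames(probs) <- classes
  n <- nrow(probs)
  if (is.null(sequence_id)) sequence_id <- sprintf("s%03d", seq_len(n))
  prediction_table(frame_id = sprintf("f%03d", seq_len(n)),
                   sequence_id = sequence_id,
                   true_label = truth, probs = probs)
}

# brute-force AUC oracle: fraction of positive-negative pairs ranked
# correctly, ties counted half
auc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# clustered prediction table with known population balanced accuracy q:
# per-sequence correct probability ~ Beta with mean q (cluster effect)
random_clustered_table <- function(n_seq = 100, frames_per_seq = 10,
                                   q = 0.7, beta_shape = 7) {
  sid <- rep(sprintf("s%03d", seq_len(n_seq)), each = frames_per_seq)
  truth_seq <- sample(view_classes(), n_seq, TRUE)
  p_seq <- stats::rbeta(n_seq, beta_shape, beta_shape * (1 - q) / q)
  truth <- rep(truth_seq, each = frames_per_seq)
  correct <- stats::runif(n_seq * frames_per_seq) < rep(p_seq, each = frames_per_seq)
  pred <- ifelse(correct, truth,
                 vapply(truth, function(t)
                   sample(setdiff(view_classes(), t), 1), character(1)))
  P <- matrix(0.02, n_seq * frames_per_seq, 4,
              dimnames = list(NULL, view_classes()))
  P[cbind(seq_along(pred), match(pred, view_classes()))] <- 0.94
  prediction_table(sprintf("f%05d", seq_along(sid)), sid, truth, P)
}
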