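## Manifest handling, splitting, preprocessing, augmentation ----------------

#' Validate a dataset manifest
#'
#' A manifest catalogs frames: columns `frame_id`, `sequence_id`, `label`,
#' `frame_index`, `path`.  Frame ids must be unique and every sequence must
#' carry exactly one label.
#'
#' @param manifest data frame.
#' @return The manifest, invisibly, or an error.
#' @export
validate_manifest <- function(manifest) {
  need <- c("frame_id", "sequence_id", "label", "frame_index")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$frame_id))
    stop("frame_id values must be unique")
  per_seq <- tapply(manifest$label, manifest$sequence_id,
                    function(l) length(unique(l)))
  if (any(per_seq != 1L))
    stop("every sequence_id must map to exactly one label")
  invisible(manifest)
}

#' Write a manifest as CSV and JSON
#'
#' @param manifest data frame (see [validate_manifest()]).
#' @param dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  validate_manifest(manifest)
  csv <- file.path(dir, "manifest.csv")
  json <- file.path(dir, "manifest.json")
  utils::write.csv(manifest, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, json, dataframe = "rows", auto_unbox = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Read a manifest from a dataset directory (CSV preferred)
#'
#' @param dir dataset directory containing `manifest.csv` or `manifest.json`.
#' @return Manifest data frame.
#' @export
read_manifest <- function(dir) {
  csv <- file.path(dir, "manifest.csv")
  json <- file.path(dir, "manifest.json")
  m <- if (file.exists(csv)) {
    utils::read.csv(csv, stringsAsFactors = FALSE)
  } else if (file.exists(json)) {
    as.data.frame(jsonlite::read_json(json, simplifyVector = TRUE))
  } else stop("no manifest.csv or manifest.json in ", dir)
  validate_manifest(m)
  m
}

#' Load PNG frames listed in a manifest
#'
#' @param manifest manifest data frame with relative `path` column.
#' @param dir dataset root directory.
#' @return Named list of [echo_frame()] keyed by `frame_id`.
#' @export
load_frames <- function(manifest, dir) {
  validate_manifest(manifest)
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$frame_id
  for (i in seq_len(nrow(manifest))) {
    px <- png::readPNG(file.path(dir, manifest$path[i]))
    if (length(dim(px)) == 3L) px <- px[, , 1]
    out[[i]] <- echo_frame(px, frame_id = manifest$frame_id[i],
                           sequence_id = manifest$sequence_id[i],
                           frame_index = manifest$frame_index[i],
                           label = manifest$label[i])
  }
  out
}

## Splitting ----------------------------------------------------------------

## largest-remainder allocation of the global test quota across classes,
## keeping at least one test and one train sequence per class
allocate_test_counts <- function(n_k, test_fraction) {
  total <- round(test_fraction * sum(n_k))
  q <- test_fraction * n_k
  a <- pmax(floor(q), 1L)
  a <- pmin(a, n_k - 1L)
  rem <- total - sum(a)
  frac <- q - floor(q)
  ord <- order(frac, decreasing = TRUE)
  i <- 1L
  while (rem > 0 && i <= length(ord)) {
    k <- ord[i]
    if (a[k] < n_k[k] - 1L) { a[k] <- a[k] + 1L; rem <- rem - 1L }
    i <- i + 1L
  }
  ord2 <- order(frac)
  i <- 1L
  while (rem < 0 && i <= length(ord2)) {
    k <- ord2[i]
    if (a[k] > 1L) { a[k] <- a[k] - 1L; rem <- rem + 1L }
    i <- i + 1L
  }
  a
}

#' Sequence-level stratified train/test split
#'
#' All frames of a sequence land on the same side.  The per-class test
#' quota follows largest-remainder allocation of `round(test_fraction * n)`
#' sequences overall (each class keeps at least one test and one training
#' sequence), so the global share is hit exactly whenever possible.
#'
#' @param manifest manifest data frame.
#' @param test_fraction fraction of sequences assigned to test, in (0, 1).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return Object of class `split_assignment`: named character vector
#'   `$sequence` (`"train"`/`"test"` per sequence id) plus bookkeeping.
#' @export
split_sequences <- function(manifest, test_fraction = 0.2, seed = 1L) {
  validate_manifest(manifest)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  seq_label <- tapply(manifest$label, manifest$sequence_id, `[`, 1L)
  classes <- sort(unique(unname(seq_label)))
  n_k <- vapply(classes, function(cl) sum(seq_label == cl), integer(1))
  if (any(n_k < 2L))
    stop("every class needs at least 2 sequences to split")
  counts <- allocate_test_counts(n_k, test_fraction)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "sequence_split"))
  assign_vec <- character(0)
  for (i in seq_along(classes)) {
    ids <- sort(names(seq_label)[seq_label == classes[i]])
    test_ids <- sample(ids, counts[i])
    v <- stats::setNames(rep("train", length(ids)), ids)
    v[test_ids] <- "test"
    assign_vec <- c(assign_vec, v)
  }
  structure(list(sequence = assign_vec,
                 test_sequences = names(assign_vec)[assign_vec == "test"],
                 train_sequences = names(assign_vec)[assign_vec == "train"],
                 test_fraction = test_fraction, seed = seed),
            class = "split_assignment")
}

#' @export
#' @method print split_assignment
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment: %d train / %d test sequences (seed %d)>\n",
              length(x$train_sequences), length(x$test_sequences), x$seed))
  invisible(x)
}

#' Frame-level stratified validation split of the training frames
#'
#' Reproduces the frame-level protocol: a stratified random hold-out of
#' `fraction` of the training frames per class, so frames of one clip may
#' appear on both sides.  (This intentionally leaks intra-clip correlation
#' into validation; pass `by_sequence = TRUE` for a leakage-free variant.)
#'
#' @param train_manifest manifest rows of the training sequences.
#' @param fraction validation share per class.
#' @param seed integer seed.
#' @param by_sequence if `TRUE`, hold out whole sequences instead.
#' @return List with character vectors `fit_frames` and `validation_frames`
#'   (frame ids; a disjoint partition of the input) and `seed`.
#' @export
split_validation_frames <- function(train_manifest, fraction = 0.2,
                                    seed = 1L, by_sequence = FALSE) {
  validate_manifest(train_manifest)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  classes <- sort(unique(train_manifest$label))
  if (any(vapply(classes, function(cl)
    sum(train_manifest$label == cl), integer(1)) < 1L))
    stop("every class needs at least one training frame")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "validation_split", by_sequence))
  val <- character(0)
  for (cl in classes) {
    rows <- train_manifest[train_manifest$label == cl, ]
    if (by_sequence) {
      ids <- sort(unique(rows$sequence_id))
      pick <- sample(ids, max(1L, round(fraction * length(ids))))
      val <- c(val, rows$frame_id[rows$sequence_id %in% pick])
    } else {
      ids <- sort(rows$frame_id)
      val <- c(val, sample(ids, max(1L, round(fraction * length(ids)))))
    }
  }
  list(fit_frames = setdiff(train_manifest$frame_id, val),
       validation_frames = val, seed = seed)
}

## Preprocessing ------------------------------------------------------------

#' ImageNet channel normalization constants
#'
#' Recorded as configuration data for the preprocessing convention of
#' pretrained backbones.
#'
#' @return List with `mean` and `sd`, each length 3 (RGB).
#' @export
imagenet_norm <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Preprocess a frame into a standardized model input
#'
#' Bilinear resize to `size x size` (skipped when already that size),
#' replication of the grayscale plane to three channels, and per-channel
#' standardization with the supplied normalization constants.
#'
#' @param frame an [echo_frame()] or matrix.
#' @param size target side length in pixels.
#' @param norm list with `mean` and `sd` per channel (default
#'   [imagenet_norm()]).
#' @return Numeric array `size x size x 3`.
#' @export
preprocess_frame <- function(frame, size = 256L, norm = imagenet_norm()) {
  px <- unclass(frame)
  if (length(px) == 0L) stop("empty image")
  if (nrow(px) != size || ncol(px) != size)
    px <- as.matrix(EBImage::resize(px, w = size, h = size))
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- (px - norm$mean[ch]) / norm$sd[ch]
  out
}

## Augmentation -------------------------------------------------------------

#' Training-time augmentation: random rotation and horizontal flip
#'
#' Rotation angle uniform in `[-max_rotation, +max_rotation]` degrees
#' (bilinear interpolation, zero fill outside the frame), then a horizontal
#' flip with probability `flip_prob`.  Pass `angle`/`flip` to force a
#' deterministic transform.
#'
#' @param frame an [echo_frame()] or matrix.
#' @param max_rotation maximal absolute rotation, degrees.
#' @param flip_prob probability of a horizontal flip.
#' @param angle forced rotation angle (otherwise drawn from the RNG).
#' @param flip forced flip decision (logical).
#' @return Frame of the same class/attributes.
#' @export
augment_frame <- function(frame, max_rotation = 10, flip_prob = 0.5,
                          angle = NULL, flip = NULL) {
  px <- unclass(frame)
  if (is.null(angle)) angle <- stats::runif(1, -max_rotation, max_rotation)
  if (is.null(flip)) flip <- stats::runif(1) < flip_prob
  if (angle != 0) {
    px <- as.matrix(EBImage::rotate(px, angle, filter = "bilinear",
                                    output.dim = dim(px), bg.col = 0))
    px <- clip01(px)
  }
  if (flip) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  if (inherits(frame, "echo_frame")) rewrap_frame(frame, px) else px
}
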