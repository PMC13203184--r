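## Histogram of Oriented Gradients descriptor -------------------------------
##
## Classical handcrafted representation: local gradient-orientation
## histograms over a cell grid with block-wise L2-hys normalization.
## Parameters are documented configuration, not claims of fidelity to any
## particular reference implementation.

#' HOG + SVM configuration
#'
#' @param resize side length the grayscale frame is resized to before
#'   descriptor computation.
#' @param cell cell side length in pixels.
#' @param block block size in cells (square), stride one cell.
#' @param orientations number of unsigned orientation bins over `[0, pi)`.
#' @param svm_kernel,svm_cost,svm_gamma SVM kernel, regularization constant
#'   and RBF width (`NULL` = `1/descriptor length`).
#' @return Object of class `hog_config`.
#' @export
hog_config <- function(resize = 128L, cell = 16L, block = 2L,
                       orientations = 9L, svm_kernel = "radial",
                       svm_cost = 10, svm_gamma = NULL) {
  stopifnot(resize %% cell == 0, block >= 1, orientations >= 2, svm_cost > 0)
  ncells <- resize %/% cell
  if (ncells < block) stop("descriptor would be empty: block exceeds cell grid")
  structure(list(resize = as.integer(resize), cell = as.integer(cell),
                 block = as.integer(block),
                 orientations = as.integer(orientations),
                 svm_kernel = svm_kernel, svm_cost = svm_cost,
                 svm_gamma = svm_gamma),
            class = "hog_config")
}

#' Compute the HOG descriptor of a frame
#'
#' Gradients by central differences (replicated edges), unsigned
#' orientations soft-assigned to the two nearest of `orientations` bins,
#' magnitude-weighted cell histograms, and L2-hys block normalization
#' (L2-normalize, clip at 0.2, renormalize).
#'
#' @param frame an [echo_frame()] or grayscale matrix.
#' @param config a [hog_config()].
#' @return Numeric feature vector of fixed length.
#' @export
hog_features <- function(frame, config = hog_config()) {
  px <- unclass(frame)
  S <- config$resize
  if (nrow(px) != S || ncol(px) != S)
    px <- as.matrix(EBImage::resize(px, w = S, h = S))
  gx <- (px[, c(2:S, S)] - px[, c(1, 1:(S - 1))]) / 2
  gy <- (px[c(2:S, S), ] - px[c(1, 1:(S - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                     # unsigned [0, pi)
  nb <- config$orientations
  o <- ang / (pi / nb)                           # continuous bin coordinate
  b0 <- floor(o)
  w1 <- o - b0                                   # weight of the next bin
  b0 <- b0 %% nb
  b1 <- (b0 + 1) %% nb

  cellpx <- config$cell
  nc <- S %/% cellpx
  ci <- (row(px) - 1L) %/% cellpx
  cj <- (col(px) - 1L) %/% cellpx
  cell_id <- ci + nc * cj                        # 0-based cell index
  acc_id0 <- cell_id * nb + b0 + 1L
  acc_id1 <- cell_id * nb + b1 + 1L
  hist <- numeric(nc * nc * nb)
  h0 <- rowsum(as.vector(mag * (1 - w1)), as.vector(acc_id0))
  h1 <- rowsum(as.vector(mag * w1), as.vector(acc_id1))
  hist[as.integer(rownames(h0))] <- hist[as.integer(rownames(h0))] + h0
  hist[as.integer(rownames(h1))] <- hist[as.integer(rownames(h1))] + h1
  H <- array(hist, c(nb, nc, nc))                # bins x cell-row x cell-col

  bl <- config$block
  nbk <- nc - bl + 1L
  out <- numeric(nbk * nbk * bl * bl * nb)
  pos <- 1L
  len <- bl * bl * nb
  for (bj in seq_len(nbk)) for (bi in seq_len(nbk)) {
    v <- as.vector(H[, bi:(bi + bl - 1L), bj:(bj + bl - 1L)])
    v <- v / sqrt(sum(v^2) + 1e-12)
    v <- pmin(v, 0.2)                            # hys clipping
    v <- v / sqrt(sum(v^2) + 1e-12)
    out[pos:(pos + len - 1L)] <- v
    pos <- pos + len
  }
  out
}

#' Train the HOG + SVM baseline classifier
#'
#' Grayscale resize, HOG descriptor, then a probability-calibrated SVM
#' (Platt sigmoid fitting on held-out folds via the underlying libsvm).
#' Deterministic given `seed`.
#'
#' @param frames named list of [echo_frame()] (training frames).
#' @param labels character vector of view labels (default: taken from the
#'   frames' `label` attributes).
#' @param config a [hog_config()].
#' @param seed integer training seed.
#' @return Object of classes `hog_svm`, `echo_classifier` with a
#'   [predict_proba()] method.
#' @export
train_hog_svm <- function(frames, labels = NULL, config = hog_config(),
                          seed = 1L) {
  if (is.null(labels))
    labels <- vapply(frames, function(f) attr(f, "label"), character(1))
  classes <- intersect(view_classes(), unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  X <- t(vapply(frames, hog_features, numeric(hog_length(config)),
                config = config))
  y <- factor(labels, levels = classes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "hog_svm"))
  gamma <- if (is.null(config$svm_gamma)) 1 / ncol(X) else config$svm_gamma
  fit <- e1071::svm(x = X, y = y, kernel = config$svm_kernel,
                    cost = config$svm_cost, gamma = gamma,
                    probability = TRUE, scale = FALSE)
  structure(list(fit = fit, classes = classes, config = config,
                 seed = seed, preprocessing = "grayscale+hog"),
            class = c("hog_svm", "echo_classifier"))
}

hog_length <- function(config) {
  nc <- config$resize %/% config$cell
  nbk <- nc - config$block + 1L
  nbk * nbk * config$block^2 * config$orientations
}

#' @export
#' @method print hog_svm
print.hog_svm <- function(x, ...) {
  cat(sprintf("<hog_svm: %d classes, %d support vectors, cost %g>\n",
              length(x$classes), x$fit$tot.nSV, x$config$svm_cost))
  invisible(x)
}
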