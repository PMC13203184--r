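## Classifier prediction interface ------------------------------------------
##
## Every trained classifier emits a prediction table (frame identity, true
## label if known, one probability column per class, argmax prediction),
## the sole input to all metrics and statistics.

#' Predict class probabilities as a prediction table
#'
#' @param model a trained classifier (`hog_svm`, `small_cnn`, `frozen_lr`).
#' @param frames named list of [echo_frame()]; identity attributes populate
#'   the table.
#' @param ... method-specific arguments.
#' @return A [prediction_table()] with one row per frame, probabilities in
#'   the model's fixed class order.
#' @export
predict_proba <- function(model, frames, ...) UseMethod("predict_proba")

frames_to_table <- function(frames, probs, classes) {
  colnames(probs) <- classes
  prediction_table(
    frame_id = vapply(frames, function(f) attr(f, "frame_id"), character(1)),
    sequence_id = vapply(frames, function(f) attr(f, "sequence_id"),
                         character(1)),
    true_label = vapply(frames, function(f) attr(f, "label"), character(1)),
    probs = probs)
}

#' @rdname predict_proba
#' @export
predict_proba.hog_svm <- function(model, frames, ...) {
  X <- t(vapply(frames, hog_features, numeric(hog_length(model$config)),
                config = model$config))
  pr <- stats::predict(model$fit, X, probability = TRUE)
  probs <- attr(pr, "probabilities")[, model$classes, drop = FALSE]
  probs <- probs / rowSums(probs)
  frames_to_table(frames, probs, model$classes)
}

#' @rdname predict_proba
#' @export
predict_proba.small_cnn <- function(model, frames, ...) {
  X <- cnn_prepare_x(frames, model$geom_input)
  geom <- cnn_geometry(model$config)
  fw <- cnn_forward(model$par, X, geom, train = FALSE)
  probs <- t(softmax_cols(fw$logits))
  frames_to_table(frames, probs, model$classes)
}

## Frozen-extractor + logistic regression ------------------------------------

#' Multinomial logistic regression on frozen feature embeddings
#'
#' A fixed feature extractor maps each frame to a vector; a ridge-penalized
#' multinomial logistic regression (glmnet) is fit on top, with the
#' regularization strength chosen by validation log-loss over the fitted
#' lambda path and recorded in the model metadata.
#'
#' @param frames training frames (named list of [echo_frame()]).
#' @param labels training labels (default: frame `label` attributes).
#' @param extractor function `frame -> numeric vector` of fixed length.
#' @param val_frames,val_labels validation set for selecting lambda.
#' @param seed integer seed.
#' @return Object of classes `frozen_lr`, `echo_classifier`.
#' @export
frozen_features_lr <- function(frames, labels = NULL, extractor,
                               val_frames, val_labels = NULL, seed = 1L) {
  if (is.null(labels))
    labels <- vapply(frames, function(f) attr(f, "label"), character(1))
  if (is.null(val_labels))
    val_labels <- vapply(val_frames, function(f) attr(f, "label"), character(1))
  X <- t(vapply(frames, extractor, extractor(frames[[1]])))
  if (all(apply(X, 2, stats::var) == 0))
    stop("degenerate (constant) features")
  Xv <- t(vapply(val_frames, extractor, extractor(val_frames[[1]])))
  classes <- intersect(view_classes(), unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  y <- factor(labels, levels = classes)
  set.seed(derive_seed(seed, "frozen_lr"))
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0)
  pv <- stats::predict(fit, Xv, type = "response")   # n x K x nlambda
  yv_idx <- match(val_labels, classes)
  logloss <- apply(pv, 3, function(P)
    -mean(log(pmax(P[cbind(seq_along(yv_idx), yv_idx)], 1e-12))))
  lambda <- fit$lambda[which.min(logloss)]
  structure(list(fit = fit, lambda = lambda, classes = classes,
                 extractor = extractor, seed = seed,
                 validation_logloss = min(logloss),
                 preprocessing = "frozen_extractor"),
            class = c("frozen_lr", "echo_classifier"))
}

#' @rdname predict_proba
#' @export
predict_proba.frozen_lr <- function(model, frames, ...) {
  X <- t(vapply(frames, model$extractor, model$extractor(frames[[1]])))
  P <- stats::predict(model$fit, X, s = model$lambda, type = "response")[, , 1]
  if (is.null(dim(P))) P <- matrix(P, nrow = 1, dimnames = list(NULL, names(P)))
  P <- P[, model$classes, drop = FALSE]
  P <- P / rowSums(P)
  frames_to_table(frames, P, model$classes)
}

#' @export
#' @method print frozen_lr
print.frozen_lr <- function(x, ...) {
  cat(sprintf("<frozen_lr: %d classes, lambda %.4g (val logloss %.4f)>\n",
              length(x$classes), x$lambda, x$validation_logloss))
  invisible(x)
}
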