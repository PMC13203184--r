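## Small trainable convolutional classifier ---------------------------------
##
## Desk-scale from-scratch CNN: three 3x3 convolution blocks (ReLU, 2x2
## max-pooling after the first two, global average pooling after the third),
## dropout head and a linear classifier.  Trained with AdamW (decoupled
## weight decay, two learning-rate groups), class-weighted label-smoothed
## cross-entropy, inverse-frequency weighted sampling, cosine learning-rate
## annealing and early stopping on validation loss.  Implemented with
## vectorized im2col matrix products; no GPU or external framework needed.

#' CNN training configuration
#'
#' @param input_size input side length (frames are resized; must be a
#'   multiple of 4).
#' @param channels integer vector of length 3: filters per conv block.
#' @param lr_backbone,lr_head AdamW learning rates for the convolutional
#'   layers and the linear head.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param dropout dropout probability on the pooled features.
#' @param label_smoothing label-smoothing mass.
#' @param batch_size minibatch size.
#' @param max_epochs maximal number of epochs (cosine schedule horizon).
#' @param patience early-stopping patience in epochs (`Inf` disables).
#' @param class_weighting `"inverse"` (`N / (K * n_k)`) or `"none"`.
#' @param weighted_sampling draw minibatch indices with inverse-frequency
#'   probabilities.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 32L, channels = c(8L, 16L, 32L),
                       lr_backbone = 1e-4, lr_head = 5e-4,
                       weight_decay = 1e-4, dropout = 0.3,
                       label_smoothing = 0.05, batch_size = 32L,
                       max_epochs = 30L, patience = 5L,
                       class_weighting = c("inverse", "none"),
                       weighted_sampling = TRUE) {
  stopifnot(input_size %% 4 == 0, length(channels) == 3,
            lr_backbone > 0, lr_head > 0, weight_decay >= 0,
            dropout >= 0, dropout < 1, label_smoothing >= 0,
            label_smoothing < 1, batch_size >= 1, max_epochs >= 1)
  if (is.finite(patience) && patience >= max_epochs)
    stop("patience must be smaller than max_epochs")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 lr_backbone = lr_backbone, lr_head = lr_head,
                 weight_decay = weight_decay, dropout = dropout,
                 label_smoothing = label_smoothing,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 class_weighting = match.arg(class_weighting),
                 weighted_sampling = isTRUE(weighted_sampling)),
            class = "cnn_config")
}

## im2col index matrix for a 3x3 kernel with zero padding 1:
## (9 * Cin) x (H * W); entry = linear index ch + Cin*(pixel-1), 0 = pad.
im2col_idx <- function(H, W, Cin) {
  p <- seq_len(H * W)
  r <- (p - 1L) %% H + 1L
  c <- (p - 1L) %/% H + 1L
  rows <- matrix(0L, 9L * Cin, H * W)
  o <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    o <- o + 1L
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    q <- integer(H * W)
    q[ok] <- rr[ok] + H * (cc[ok] - 1L)
    for (ch in seq_len(Cin)) {
      idx <- integer(H * W)
      idx[ok] <- ch + Cin * (q[ok] - 1L)
      rows[ch + Cin * (o - 1L), ] <- idx
    }
  }
  rows
}

## conv forward: M (Cin*H*W) x N -> list(Z = (Cout) x (H*W*N), A = im2col)
conv_fwd <- function(M, Wt, b, idx, N) {
  Mpad <- rbind(0, M)
  A <- Mpad[as.vector(idx) + 1L, , drop = FALSE]   # (9Cin*HW) x N
  dim(A) <- c(nrow(idx), ncol(idx) * N)            # (9Cin) x (HW*N)
  Z <- Wt %*% A + b
  list(Z = Z, A = A)
}

## conv backward: returns gradients and upstream dM
conv_bwd <- function(dZ, A, Wt, idx, N) {
  dW <- dZ %*% t(A)
  db <- rowSums(dZ)
  dA <- t(Wt) %*% dZ                               # (9Cin) x (HW*N)
  dim(dA) <- c(nrow(idx) * ncol(idx), N)
  tgt <- as.vector(idx) + 1L
  rs <- rowsum(dA, tgt)
  dMpad <- matrix(0, max(tgt), N)
  dMpad[as.integer(rownames(rs)), ] <- rs
  list(dW = dW, db = db, dM = dMpad[-1L, , drop = FALSE])
}

## 2x2 max pooling over Z (C x HW*N); returns pooled matrix and gather info
pool_idx <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  p2 <- seq_len(H2 * W2)
  r2 <- (p2 - 1L) %% H2 + 1L
  c2 <- (p2 - 1L) %/% H2 + 1L
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
    (2L * r2 - 1L + d[1]) + H * (2L * c2 - 2L + d[2])
  })
}

pool_fwd <- function(Z, q, HW, N) {
  cols <- lapply(q, function(qk) as.vector(outer(qk, (seq_len(N) - 1L) * HW, "+")))
  parts <- lapply(cols, function(ck) Z[, ck, drop = FALSE])
  P <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  masks <- vector("list", 4L)
  taken <- matrix(FALSE, nrow(P), ncol(P))
  for (k in 1:4) {
    masks[[k]] <- (parts[[k]] == P) & !taken
    taken <- taken | masks[[k]]
  }
  list(P = P, cols = cols, masks = masks)
}

pool_bwd <- function(dP, pool, C, HW, N) {
  dZ <- matrix(0, C, HW * N)
  for (k in 1:4)
    dZ[, pool$cols[[k]]] <- pool$masks[[k]] * dP
  dZ
}

cnn_init <- function(config, K, seed) {
  set.seed(derive_seed(seed, "cnn_init"))
  ch <- config$channels
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  list(W1 = he(ch[1], 9L), b1 = numeric(ch[1]),
       W2 = he(ch[2], 9L * ch[1]), b2 = numeric(ch[2]),
       W3 = he(ch[3], 9L * ch[2]), b3 = numeric(ch[3]),
       Wd = he(K, ch[3]), bd = numeric(K))
}

## forward pass; X: (s*s) x N in [-1, 1]; returns caches when train = TRUE
cnn_forward <- function(par, X, geom, dropout = 0, train = FALSE) {
  N <- ncol(X)
  c1 <- conv_fwd(X, par$W1, par$b1, geom$idx1, N)
  Z1 <- pmax(c1$Z, 0)
  p1 <- pool_fwd(Z1, geom$q1, geom$HW1, N)
  M2 <- matrix(p1$P, nrow(p1$P) * geom$HW2, N)
  c2 <- conv_fwd(M2, par$W2, par$b2, geom$idx2, N)
  Z2 <- pmax(c2$Z, 0)
  p2 <- pool_fwd(Z2, geom$q2, geom$HW2, N)
  M3 <- matrix(p2$P, nrow(p2$P) * geom$HW3, N)
  c3 <- conv_fwd(M3, par$W3, par$b3, geom$idx3, N)
  Z3 <- pmax(c3$Z, 0)
  C3 <- nrow(Z3)
  Fm <- colSums(aperm(array(Z3, c(C3, geom$HW3, N)), c(2, 1, 3))) / geom$HW3
  dim(Fm) <- c(C3, N)
  mask <- NULL
  Fd <- Fm
  if (train && dropout > 0) {
    mask <- matrix(stats::runif(length(Fm)) >= dropout, C3, N) / (1 - dropout)
    Fd <- Fm * mask
  }
  logits <- par$Wd %*% Fd + par$bd
  out <- list(logits = logits)
  if (train)
    out <- c(out, list(c1 = c1, Z1 = Z1, p1 = p1, c2 = c2, Z2 = Z2, p2 = p2,
                       c3 = c3, Z3 = Z3, Fd = Fd, mask = mask, N = N))
  out
}

softmax_cols <- function(L) {
  L <- L - rep(apply(L, 2, max), each = nrow(L))
  E <- exp(L)
  E / rep(colSums(E), each = nrow(L))
}

## weighted label-smoothed cross-entropy; y integer 1..K
cnn_loss <- function(P, y, K, smooth, w) {
  Ysm <- matrix(smooth / K, K, length(y))
  Ysm[cbind(y, seq_along(y))] <- Ysm[cbind(y, seq_along(y))] + (1 - smooth)
  wn <- w[y]
  loss <- -sum(wn * colSums(Ysm * log(pmax(P, 1e-12)))) / sum(wn)
  dlogits <- sweep(P - Ysm, 2, wn / sum(wn), `*`)
  list(loss = loss, dlogits = dlogits)
}

adamw_step <- function(state, par, grads, lrs, wd, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    decay <- if (grepl("^W", nm)) wd else 0   # no decay on biases
    par[[nm]] <- par[[nm]] - lrs[[nm]] * (mhat / (sqrt(vhat) + eps) +
                                          decay * par[[nm]])
  }
  list(state = state, par = par)
}

cnn_prepare_x <- function(frames, s) {
  X <- vapply(frames, function(f) {
    px <- unclass(f)
    if (nrow(px) != s || ncol(px) != s)
      px <- as.matrix(EBImage::resize(px, w = s, h = s))
    as.vector(px)
  }, numeric(s * s))
  2 * X - 1                                     # centre to [-1, 1]
}

cnn_geometry <- function(config) {
  s <- config$input_size
  ch <- config$channels
  list(idx1 = im2col_idx(s, s, 1L),
       q1 = pool_idx(s, s), HW1 = s * s,
       idx2 = im2col_idx(s %/% 2L, s %/% 2L, ch[1]),
       q2 = pool_idx(s %/% 2L, s %/% 2L), HW2 = (s %/% 2L)^2,
       idx3 = im2col_idx(s %/% 4L, s %/% 4L, ch[2]),
       HW3 = (s %/% 4L)^2)
}

#' Train the small convolutional view classifier
#'
#' See [cnn_config()] for the recipe.  Training runs for at most
#' `max_epochs` epochs with cosine-annealed AdamW and stops early when the
#' validation loss has not improved for `patience` epochs; the weights of
#' the best validation epoch are retained.  Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param frames named list of training [echo_frame()]s.
#' @param labels training labels (default: frame `label` attributes).
#' @param val_frames,val_labels validation frames/labels (required).
#' @param config a [cnn_config()].
#' @param seed integer training seed (initialization, sampling, dropout).
#' @param verbose print per-epoch losses.
#' @return Object of classes `small_cnn`, `echo_classifier`.
#' @export
train_small_cnn <- function(frames, labels = NULL, val_frames,
                            val_labels = NULL, config = cnn_config(),
                            seed = 1L, verbose = FALSE) {
  if (is.null(labels))
    labels <- vapply(frames, function(f) attr(f, "label"), character(1))
  if (is.null(val_labels))
    val_labels <- vapply(val_frames, function(f) attr(f, "label"), character(1))
  if (length(val_frames) == 0L) stop("validation set must be non-empty")
  classes <- intersect(view_classes(), unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  K <- length(classes)
  y <- match(labels, classes)
  yv <- match(val_labels, classes)
  s <- config$input_size
  X <- cnn_prepare_x(frames, s)
  Xv <- cnn_prepare_x(val_frames, s)
  geom <- cnn_geometry(config)
  par <- cnn_init(config, K, seed)
  n_k <- tabulate(y, K)
  w <- if (config$class_weighting == "inverse")
    length(y) / (K * pmax(n_k, 1L)) else rep(1, K)
  samp_prob <- if (config$weighted_sampling) w[y] else rep(1, length(y))
  lrs_of <- function(scale) list(
    W1 = scale * config$lr_backbone, b1 = scale * config$lr_backbone,
    W2 = scale * config$lr_backbone, b2 = scale * config$lr_backbone,
    W3 = scale * config$lr_backbone, b3 = scale * config$lr_backbone,
    Wd = scale * config$lr_head, bd = scale * config$lr_head)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "cnn_train"))
  best <- list(loss = Inf, par = par, epoch = 0L)
  t <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    scale <- 0.5 * (1 + cos(pi * (epoch - 1) / config$max_epochs))
    lrs <- lrs_of(scale)
    ord <- sample.int(length(y), length(y), replace = config$weighted_sampling,
                      prob = if (config$weighted_sampling) samp_prob)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      fw <- cnn_forward(par, X[, bidx, drop = FALSE], geom,
                        dropout = config$dropout, train = TRUE)
      P <- softmax_cols(fw$logits)
      ls <- cnn_loss(P, y[bidx], K, config$label_smoothing, w)
      if (!is.finite(ls$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      grads <- cnn_backward(par, fw, ls$dlogits, geom, config)
      t <- t + 1L
      upd <- adamw_step(state, par, grads, lrs, config$weight_decay, t)
      state <- upd$state; par <- upd$par
    }
    vl <- cnn_eval_loss(par, Xv, yv, K, config, geom, w)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %2d: train %.4f val %.4f", epoch,
                      ep_loss / nb, vl))
    if (vl < best$loss - 1e-9) best <- list(loss = vl, par = par, epoch = epoch)
    if (is.finite(config$patience) && epoch - best$epoch >= config$patience)
      break
  }
  structure(list(par = best$par, classes = classes, config = config,
                 seed = seed, geom_input = s, history = history,
                 best_epoch = best$epoch,
                 preprocessing = sprintf("grayscale+resize%d", s)),
            class = c("small_cnn", "echo_classifier"))
}

cnn_eval_loss <- function(par, Xv, yv, K, config, geom, w) {
  fw <- cnn_forward(par, Xv, geom, train = FALSE)
  P <- softmax_cols(fw$logits)
  cnn_loss(P, yv, K, config$label_smoothing, w)$loss
}

cnn_backward <- function(par, fw, dlogits, geom, config) {
  N <- fw$N
  dWd <- dlogits %*% t(fw$Fd)
  dbd <- rowSums(dlogits)
  dFd <- t(par$Wd) %*% dlogits
  dF <- if (!is.null(fw$mask)) dFd * fw$mask else dFd
  C3 <- nrow(dF)
  ## broadcast to (C3 x HW3*N); columns are (p, n) pairs with p fastest
  dZ3 <- dF[, rep(seq_len(N), each = geom$HW3), drop = FALSE] / geom$HW3
  dZ3 <- dZ3 * (fw$Z3 > 0)
  bw3 <- conv_bwd(dZ3, fw$c3$A, par$W3, geom$idx3, N)
  C2 <- length(par$b2)
  dP2 <- matrix(bw3$dM, C2, geom$HW3 * N)
  dZ2 <- pool_bwd(dP2, fw$p2, C2, geom$HW2, N)
  dZ2 <- dZ2 * (fw$Z2 > 0)
  bw2 <- conv_bwd(dZ2, fw$c2$A, par$W2, geom$idx2, N)
  C1 <- length(par$b1)
  dP1 <- matrix(bw2$dM, C1, geom$HW2 * N)
  dZ1 <- pool_bwd(dP1, fw$p1, C1, geom$HW1, N)
  dZ1 <- dZ1 * (fw$Z1 > 0)
  bw1 <- conv_bwd(dZ1, fw$c1$A, par$W1, geom$idx1, N)
  list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db,
       W3 = bw3$dW, b3 = bw3$db, Wd = dWd, bd = dbd)
}

#' @export
#' @method print small_cnn
print.small_cnn <- function(x, ...) {
  cat(sprintf("<small_cnn: input %dx%d, channels %s, best epoch %d>\n",
              x$geom_input, x$geom_input,
              paste(x$config$channels, collapse = "-"), x$best_epoch))
  invisible(x)
}
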