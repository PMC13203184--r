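## Parametric artifact simulators ------------------------------------------
##
## Three families, each an exact identity at severity 0:
##   motion blur     I_blur = I * K,  K a normalized horizontal box of
##                   length L (fractional lengths get partial end taps)
##   acoustic shadow pixels inside a top-centred cone of base width
##                   wf * W replaced by low-level noise |eps|
##   speckle         I_noisy = I + I * N(0, sigma^2), clipped to [0, 1]

#' Severity grids of the degradation protocol
#'
#' @param family `"motion_blur"`, `"acoustic_shadow"` or `"speckle"`.
#' @return Numeric vector: blur length 0..20 step 2.5; shadow width
#'   fraction 0..0.7 step 0.1; speckle sigma 0..3 step 0.5.
#' @export
severity_grid <- function(family = c("motion_blur", "acoustic_shadow",
                                     "speckle")) {
  switch(match.arg(family),
         motion_blur = seq(0, 20, by = 2.5),
         acoustic_shadow = seq(0, 0.7, by = 0.1),
         speckle = seq(0, 3, by = 0.5))
}

#' Artifact specification
#'
#' @param family artifact family (see [severity_grid()]).
#' @param severity scalar severity: blur length `L` in pixels, shadow base
#'   width as a fraction of image width, or speckle standard deviation.
#' @param epsilon_sigma_fraction shadow-fill noise level relative to mean
#'   image brightness (shadow family only).
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(family = c("motion_blur", "acoustic_shadow",
                                     "speckle"),
                          severity, epsilon_sigma_fraction = 0.03) {
  family <- match.arg(family)
  grid <- severity_grid(family)
  if (!is.numeric(severity) || length(severity) != 1L || severity < 0 ||
      severity > max(grid))
    stop(sprintf("severity for %s must lie in [0, %g]", family, max(grid)))
  structure(list(family = family, severity = severity,
                 epsilon_sigma_fraction = epsilon_sigma_fraction),
            class = "artifact_spec")
}

#' @export
#' @method print artifact_spec
print.artifact_spec <- function(x, ...) {
  cat(sprintf("<artifact_spec %s, severity %g>\n", x$family, x$severity))
  invisible(x)
}

## Motion blur --------------------------------------------------------------

#' Build a normalized horizontal blur kernel
#'
#' The kernel is a continuous box of width `L` sampled on the integer grid:
#' the tap at offset `i` receives the overlap of the unit cell
#' `[i - 0.5, i + 0.5]` with `[-L/2, L/2]`, divided by `L`.  Taps are
#' symmetric and sum to one; `L <= 1` returns the identity kernel.
#'
#' @param L blur length in pixels, `>= 0` (fractional values allowed).
#' @return Numeric vector of taps (odd length, centred).
#' @export
build_blur_kernel <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 0)
    stop("blur length L must be a finite non-negative scalar")
  if (L <= 1) return(1)
  half <- L / 2
  m <- ceiling(half - 0.5)           # largest tap offset with overlap
  offsets <- seq(-m, m)
  lo <- pmax(offsets - 0.5, -half)
  hi <- pmin(offsets + 0.5, half)
  taps <- pmax(hi - lo, 0) / L
  taps / sum(taps)                   # guard residual rounding; already ~1
}

## reflect-padded column index (border mode "reflect", edge pixel mirrored:
## ... 3 2 1 | 1 2 3 ... | W W-1 ...)
reflect_index <- function(idx, W) {
  period <- 2L * W
  i <- ((idx - 1L) %% period + period) %% period   # 0 .. 2W-1
  ifelse(i < W, i + 1L, period - i)
}

#' Apply horizontal motion blur
#'
#' 1-D convolution of each row with [build_blur_kernel()] using reflect
#' border handling.  `L = 0` (or any `L <= 1`) returns a pixel-identical
#' copy; a constant image is preserved exactly.
#'
#' @param frame an [echo_frame()] or plain matrix in `[0, 1]`.
#' @param L blur length in pixels.
#' @return Frame of the same class and attributes.
#' @export
motion_blur <- function(frame, L) {
  taps <- build_blur_kernel(L)
  if (length(taps) == 1L) return(frame)
  px <- unclass(frame)
  W <- ncol(px)
  m <- (length(taps) - 1L) / 2L
  out <- matrix(0, nrow(px), W)
  for (k in seq_along(taps)) {
    off <- k - 1L - m
    cols <- reflect_index(seq_len(W) + off, W)
    out <- out + taps[k] * px[, cols, drop = FALSE]
  }
  out <- clip01(out)
  if (inherits(frame, "echo_frame")) rewrap_frame(frame, out) else out
}

## Acoustic shadow ----------------------------------------------------------

#' Conical shadow mask
#'
#' Filled triangle with vertex at the top centre and base on the bottom row,
#' of width `wf * W`: pixel `(x, y)` is masked iff
#' `|x - W/2| <= (wf * W / 2) * (y / (H - 1))` (x, y measured at pixel
#' centres, zero-based from the top-left).
#'
#' @param H,W image size in pixels.
#' @param wf base width as a fraction of image width, in `[0, 1]`.
#' @return Logical `H x W` matrix.
#' @export
shadow_mask <- function(H, W, wf) {
  stopifnot(H >= 1, W >= 1, wf >= 0, wf <= 1)
  if (wf == 0) return(matrix(FALSE, H, W))
  x <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)   # pixel-centre x
  y <- matrix(seq_len(H) - 1, H, W)                   # zero-based row
  halfwidth <- (wf * W / 2) * y / (H - 1)
  abs(x - W / 2) <= halfwidth
}

#' Shadow specification
#'
#' @param width_fraction cone base width as a fraction of image width.
#' @param epsilon_sigma_fraction standard deviation of the fill noise
#'   relative to the mean image brightness.
#' @return An object of class `shadow_spec`.
#' @export
shadow_spec <- function(width_fraction, epsilon_sigma_fraction = 0.03) {
  stopifnot(width_fraction >= 0, width_fraction <= 1,
            epsilon_sigma_fraction >= 0)
  structure(list(width_fraction = width_fraction,
                 epsilon_sigma_fraction = epsilon_sigma_fraction),
            class = "shadow_spec")
}

#' Apply an acoustic shadow
#'
#' Pixels inside the conical mask are replaced by `|eps|` with
#' `eps ~ N(0, (f * mean(I))^2)` drawn i.i.d. per pixel from the current
#' RNG stream (`f` = `spec$epsilon_sigma_fraction`), clipped to `[0, 1]`;
#' pixels outside are untouched.  Width 0 returns an identical copy.
#'
#' @param frame an [echo_frame()] or matrix.
#' @param spec a [shadow_spec()].
#' @return Frame of the same class and attributes.
#' @export
acoustic_shadow <- function(frame, spec) {
  stopifnot(inherits(spec, "shadow_spec"))
  if (spec$width_fraction == 0) return(frame)
  px <- unclass(frame)
  mask <- shadow_mask(nrow(px), ncol(px), spec$width_fraction)
  n <- sum(mask)
  sigma <- spec$epsilon_sigma_fraction * mean(px)
  fill <- if (sigma > 0) abs(stats::rnorm(n, 0, sigma)) else numeric(n)
  out <- px
  out[mask] <- clip01(fill)
  if (inherits(frame, "echo_frame")) rewrap_frame(frame, out) else out
}

## Speckle ------------------------------------------------------------------

#' Apply multiplicative speckle noise
#'
#' Each pixel becomes `I * (1 + z)` with `z ~ N(0, sigma^2)` i.i.d. from the
#' current RNG stream, clipped to `[0, 1]`.  `sigma = 0` returns an
#' identical copy and an all-zero image stays all-zero for any `sigma`.
#'
#' @param frame an [echo_frame()] or matrix.
#' @param sigma dimensionless noise standard deviation, `>= 0`.
#' @return Frame of the same class and attributes.
#' @export
speckle <- function(frame, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(frame)
  px <- unclass(frame)
  z <- matrix(stats::rnorm(length(px), 0, sigma), nrow(px), ncol(px))
  out <- clip01(px * (1 + z))
  if (inherits(frame, "echo_frame")) rewrap_frame(frame, out) else out
}

## Dispatch -----------------------------------------------------------------

#' Apply an artifact to a frame with deterministic seeding
#'
#' Dispatches to the family-specific simulator.  Stochastic families use an
#' RNG stream seeded from `(base_seed, frame_id, family, severity)`, so a
#' given frame/spec/seed triple always yields the same output while
#' different frames remain mutually independent.
#'
#' @param frame an [echo_frame()] (its `frame_id` attribute keys the RNG
#'   stream) or a matrix (supply `frame_id`).
#' @param spec an [artifact_spec()].
#' @param base_seed integer experiment seed.
#' @param frame_id override for the RNG key.
#' @return Degraded frame; pixel-identical to the input at severity 0.
#' @export
apply_artifact <- function(frame, spec, base_seed = 0L, frame_id = NULL) {
  stopifnot(inherits(spec, "artifact_spec"))
  if (is.null(frame_id))
    frame_id <- attr(frame, "frame_id")
  if (is.null(frame_id)) frame_id <- "frame"
  if (spec$severity == 0) return(frame)
  if (spec$family == "motion_blur")
    return(motion_blur(frame, spec$severity))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(base_seed, frame_id, spec$family, spec$severity))
  switch(spec$family,
         acoustic_shadow = acoustic_shadow(
           frame, shadow_spec(spec$severity, spec$epsilon_sigma_fraction)),
         speckle = speckle(frame, spec$severity))
}
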