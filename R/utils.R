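#' @keywords internal
"_PACKAGE"

## Deterministic seed derivation -------------------------------------------

#' Derive a reproducible sub-seed from a base seed and string context
#'
#' Stage- and frame-specific random-number streams are derived from a single
#' global seed by hashing a context string (e.g. stage name, frame id,
#' artifact family, severity).  The hash is a 31-bit polynomial rolling hash,
#' so derived seeds are valid R integer seeds and independent runs that share
#' `(base, ...)` reproduce each other exactly.
#'
#' @param base integer base seed.
#' @param ... character/numeric context fields, concatenated with `"/"`.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(base, ...) {
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  ctx <- paste(vapply(list(...), function(x) paste(format(x, trim = TRUE),
                                                   collapse = ","),
                      character(1)), collapse = "/")
  h <- as.double(base) %% 2147483647
  for (code in utf8ToInt(ctx)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## clamp to [0, 1] ----------------------------------------------------------

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Frame objects ------------------------------------------------------------

#' Construct an echo frame
#'
#' A frame is a numeric `H x W` matrix with intensities in `[0, 1]` plus
#' identity attributes.  Rows index the vertical (depth) axis, columns the
#' horizontal axis; the sector apex sits at the top centre.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param frame_id,sequence_id character identifiers.
#' @param frame_index integer position within the clip, 0-based.
#' @param label optional view label (`"A2C"`, `"A3C"`, `"A4C"`, `"A5C"`).
#' @return An object of class `echo_frame` (a matrix).
#' @export
echo_frame <- function(pixels, frame_id = "f0", sequence_id = "s0",
                       frame_index = 0L, label = NA_character_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("frame pixels must be finite and within [0, 1]")
  structure(pixels, frame_id = as.character(frame_id),
            sequence_id = as.character(sequence_id),
            frame_index = as.integer(frame_index),
            label = as.character(label),
            class = c("echo_frame", "matrix", "array"))
}

## keep identity attributes when pixels are transformed
rewrap_frame <- function(template, pixels) {
  a <- attributes(template)
  structure(pixels,
            frame_id = a$frame_id, sequence_id = a$sequence_id,
            frame_index = a$frame_index, label = a$label,
            class = c("echo_frame", "matrix", "array"))
}

#' @export
#' @method print echo_frame
print.echo_frame <- function(x, ...) {
  cat(sprintf("<echo_frame %s (seq %s, view %s): %d x %d, range [%.3f, %.3f]>\n",
              attr(x, "frame_id"), attr(x, "sequence_id"), attr(x, "label"),
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

frame_meta <- function(frame) {
  list(frame_id = attr(frame, "frame_id"),
       sequence_id = attr(frame, "sequence_id"),
       frame_index = attr(frame, "frame_index"),
       label = attr(frame, "label"))
}

## Bilinear sampling --------------------------------------------------------

## Sample matrix `m` at fractional (row, col) coordinates with zero fill
## outside the grid.  Used by rotation; resize goes through EBImage.
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  get <- function(ri, ci) {
    v <- numeric(length(ri))
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- get(r0, c0);     v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}
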