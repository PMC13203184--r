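## Synthetic apical-view phantoms ------------------------------------------
##
## The generator emulates the *statistical structure* of an apical TTE
## dataset -- a sector-shaped bright tissue field with multiplicative
## speckle texture, containing 2..5 dark elliptical "chambers" whose count
## and arrangement distinguish the four view classes, grouped into short
## clips of temporally correlated frames.  It makes no claim of acoustic
## realism (no point-spread function, no scanline geometry).

#' Apical view classes
#'
#' @return Character vector `c("A2C", "A3C", "A4C", "A5C")`.
#' @export
view_classes <- function() c("A2C", "A3C", "A4C", "A5C")

#' Number of chambers rendered for a view
#'
#' @param view one of [view_classes()].
#' @return Integer in 2..5 (the numeral in the label).
#' @export
chamber_count <- function(view) {
  view <- match.arg(view, view_classes())
  as.integer(substr(view, 2, 2))
}

#' Phantom generator configuration
#'
#' Defaults reproduce the study dataset shape: 217 clips in four classes
#' with frame totals A2C 518, A3C 390, A4C 1075, A5C 187 (2170 frames,
#' about 10 frames per clip).
#'
#' @param image_height,image_width frame size in pixels (>= 64).
#' @param frames_per_sequence nominal frames per clip.
#' @param sequences_per_class named integer vector of clip counts.
#' @param frames_per_class named integer vector of exact per-class frame
#'   totals, distributed over clips by largest remainder (clips get
#'   `floor(total/n)` or one more).  `NULL` gives every clip exactly
#'   `frames_per_sequence` frames.  When both clip counts and
#'   `frames_per_sequence` are left at their defaults, the study totals
#'   above are used.
#' @param baseline_speckle_sigma standard deviation of the log-multiplicative
#'   baseline texture (dimensionless).
#' @param motion_amplitude maximal rigid inter-frame jitter of the chamber
#'   layout, in pixels.
#' @param pulsation_amplitude relative sinusoidal modulation of chamber axes
#'   over the cardiac-cycle surrogate phase.
#' @param regenerate_speckle logical; draw a fresh texture field per frame
#'   (`TRUE`) or share one per clip.
#' @param tissue_level,chamber_level mean intensity of tissue and chamber
#'   interiors before texturing.
#' @param chamber_edge_softness fraction of each chamber's normalized
#'   radius over which its boundary blends into tissue (blood-tissue
#'   interfaces in B-mode are diffuse, not razor-sharp; 0 gives hard
#'   edges).
#' @param sector_half_angle sector fan half-opening angle, degrees.
#' @param sector_radius_fraction sector depth as a fraction of image height.
#' @param chamber_jitter positional jitter of chamber centres (fraction of
#'   image size).
#' @param axis_scale_range multiplicative sampling range for chamber axes.
#' @param max_geometry_retries resampling attempts before failing on an
#'   invalid chamber layout.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 256L, image_width = 256L,
                           frames_per_sequence = 10L,
                           sequences_per_class = c(A2C = 52L, A3C = 39L,
                                                   A4C = 107L, A5C = 19L),
                           frames_per_class = NULL,
                           baseline_speckle_sigma = 0.15,
                           motion_amplitude = 2,
                           pulsation_amplitude = 0.1,
                           regenerate_speckle = TRUE,
                           tissue_level = 0.55,
                           chamber_level = 0.10,
                           chamber_edge_softness = 0.4,
                           sector_half_angle = 40,
                           sector_radius_fraction = 0.95,
                           chamber_jitter = 0.01,
                           axis_scale_range = c(0.9, 1.1),
                           max_geometry_retries = 20L) {
  default_counts <- missing(sequences_per_class) && missing(frames_per_sequence)
  if (is.null(frames_per_class) && default_counts)
    frames_per_class <- c(A2C = 518L, A3C = 390L, A4C = 1075L, A5C = 187L)
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              frames_per_sequence = as.integer(frames_per_sequence),
              sequences_per_class = sequences_per_class,
              frames_per_class = frames_per_class,
              baseline_speckle_sigma = baseline_speckle_sigma,
              motion_amplitude = motion_amplitude,
              pulsation_amplitude = pulsation_amplitude,
              regenerate_speckle = isTRUE(regenerate_speckle),
              tissue_level = tissue_level,
              chamber_level = chamber_level,
              chamber_edge_softness = chamber_edge_softness,
              sector_half_angle = sector_half_angle,
              sector_radius_fraction = sector_radius_fraction,
              chamber_jitter = chamber_jitter,
              axis_scale_range = axis_scale_range,
              max_geometry_retries = as.integer(max_geometry_retries))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_height < 64L || cfg$image_width < 64L)
    stop("image dimensions must be at least 64 pixels")
  if (cfg$frames_per_sequence < 1L)
    stop("frames_per_sequence must be >= 1")
  if (any(cfg$sequences_per_class < 1L))
    stop("all sequence counts must be >= 1")
  if (!all(names(cfg$sequences_per_class) %in% view_classes()))
    stop("sequences_per_class must be named by view classes")
  if (cfg$baseline_speckle_sigma < 0)
    stop("baseline_speckle_sigma must be >= 0")
  if (!is.null(cfg$frames_per_class)) {
    if (!identical(sort(names(cfg$frames_per_class)),
                   sort(names(cfg$sequences_per_class))))
      stop("frames_per_class must be named like sequences_per_class")
    if (any(cfg$frames_per_class < cfg$sequences_per_class[
          names(cfg$frames_per_class)]))
      stop("each class needs at least one frame per sequence")
  }
  invisible(cfg)
}

#' @export
#' @method print phantom_config
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config %dx%d, %s clips, speckle sigma %.2f>\n",
              x$image_height, x$image_width,
              sum(x$sequences_per_class), x$baseline_speckle_sigma))
  invisible(x)
}

## Sector geometry ----------------------------------------------------------

.sector_cache <- new.env(parent = emptyenv())

#' Sector fan mask
#'
#' Logical `H x W` matrix, `TRUE` inside the imaging sector: a fan with its
#' apex at the top centre, half-opening angle and depth taken from `config`.
#'
#' @param config a [phantom_config()].
#' @return Logical matrix.
#' @export
sector_mask <- function(config) {
  H <- config$image_height; W <- config$image_width
  key <- sprintf("%d_%d_%g_%g", H, W, config$sector_half_angle,
                 config$sector_radius_fraction)
  if (!is.null(.sector_cache[[key]])) return(.sector_cache[[key]])
  x0 <- (W + 1) / 2
  dy <- matrix(seq_len(H) - 1, H, W)            # depth from apex row
  dx <- matrix(seq_len(W) - x0, H, W, byrow = TRUE)
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(abs(dx), dy)                     # 0 = straight down
  m <- rad <= config$sector_radius_fraction * H &
    ang <= config$sector_half_angle * pi / 180 & dy >= 0
  .sector_cache[[key]] <- m
  m
}

## canonical chamber layouts (fractions of image size; cx relative to the
## vertical centreline, cy from the top edge)
chamber_layout <- function(view) {
  lv  <- c(-0.105, 0.42, 0.080, 0.140)  # left ventricle
  rv  <- c( 0.115, 0.42, 0.065, 0.110)  # right ventricle
  la  <- c(-0.105, 0.72, 0.075, 0.085)  # left atrium
  ra  <- c( 0.115, 0.71, 0.065, 0.080)  # right atrium
  ao  <- c( 0.000, 0.565, 0.040, 0.048) # aortic root / LVOT
  rows <- switch(view,
    A2C = list(c(0, 0.43, 0.105, 0.145), c(0, 0.755, 0.090, 0.090)),
    A3C = list(c(0.04, 0.44, 0.090, 0.145), c(0.04, 0.755, 0.085, 0.090),
               c(-0.145, 0.60, 0.050, 0.068)),
    A4C = list(lv, rv, la, ra),
    A5C = list(c(-0.115, 0.40, 0.075, 0.120), c(0.115, 0.40, 0.062, 0.100),
               c(-0.115, 0.70, 0.070, 0.080), c(0.115, 0.695, 0.062, 0.078),
               ao),
    stop("unknown view"))
  g <- do.call(rbind, rows)
  colnames(g) <- c("cx", "cy", "a", "b")
  as.data.frame(g)
}

## is every sampled boundary point of each (maximally dilated) ellipse
## inside the sector with margin, and are ellipses pairwise disjoint?
## Rigid motion shifts all chambers together, so it widens the sector
## margin but cannot cause chamber-chamber overlap.
geometry_valid <- function(geom, config) {
  H <- config$image_height; W <- config$image_width
  x0 <- (W + 1) / 2
  dil <- 1 + config$pulsation_amplitude
  sec_margin <- config$motion_amplitude + 2
  th <- seq(0, 2 * pi, length.out = 64L)
  boundary <- function(i, margin) {
    cx <- x0 + geom$cx[i] * W; cy <- geom$cy[i] * H
    a <- geom$a[i] * W * dil + margin; b <- geom$b[i] * H * dil + margin
    cbind(x = cx + a * cos(th), y = cy + b * sin(th))
  }
  half <- config$sector_half_angle * pi / 180
  Rmax <- config$sector_radius_fraction * H
  inside_sector <- function(p) {
    dx <- p[, "x"] - x0; dy <- p[, "y"] - 1
    all(dy >= 0 & sqrt(dx^2 + dy^2) <= Rmax & atan2(abs(dx), dy) <= half)
  }
  n <- nrow(geom)
  for (i in seq_len(n))
    if (!inside_sector(boundary(i, sec_margin))) return(FALSE)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      pts_i <- boundary(i, 1)
      for (j in (i + 1L):n) {
        cx <- x0 + geom$cx[j] * W; cy <- geom$cy[j] * H
        a <- geom$a[j] * W * dil + 1; b <- geom$b[j] * H * dil + 1
        d <- ((pts_i[, "x"] - cx) / a)^2 + ((pts_i[, "y"] - cy) / b)^2
        if (any(d < 1)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Sample a randomized chamber layout for a view
#'
#' Perturbs the canonical layout (centre jitter, axis rescaling) using the
#' current RNG stream; layouts whose chambers would leave the sector or
#' overlap are rejected and resampled up to `config$max_geometry_retries`
#' times.
#'
#' @param view one of [view_classes()].
#' @param config a [phantom_config()].
#' @return Data frame with columns `cx`, `cy`, `a`, `b` (image-size
#'   fractions), one row per chamber.
#' @export
sample_geometry <- function(view, config) {
  base <- chamber_layout(view)
  for (try in seq_len(config$max_geometry_retries)) {
    g <- base
    n <- nrow(g)
    g$cx <- g$cx + stats::runif(n, -config$chamber_jitter, config$chamber_jitter)
    g$cy <- g$cy + stats::runif(n, -config$chamber_jitter, config$chamber_jitter)
    sc <- stats::runif(n, config$axis_scale_range[1], config$axis_scale_range[2])
    g$a <- g$a * sc
    g$b <- g$b * sc * stats::runif(n, 0.97, 1.03)
    if (geometry_valid(g, config)) return(g)
  }
  stop("failed to sample a valid chamber geometry for ", view)
}

## log-uniform multiplicative texture with sd ~ sigma
speckle_texture <- function(H, W, sigma) {
  if (sigma <= 0) return(matrix(1, H, W))
  a <- sqrt(3) * sigma
  matrix(exp(stats::runif(H * W, -a, a)), H, W)
}

#' Render one phantom frame
#'
#' Draws the sector-shaped tissue field with multiplicative speckle texture
#' and the view's dark chambers, with chamber areas modulated sinusoidally
#' by the cardiac-cycle surrogate `phase`.  Consumes the current RNG stream
#' (texture) and is deterministic given the RNG state and inputs.
#'
#' @param view one of [view_classes()].
#' @param phase scalar in `[0, 1)`.
#' @param geometry chamber layout from [sample_geometry()].
#' @param config a [phantom_config()].
#' @param texture optional pre-drawn texture matrix (shared across a clip
#'   when `config$regenerate_speckle` is `FALSE`).
#' @param offset length-2 numeric, rigid (row, col) displacement of the
#'   chamber layout in pixels.
#' @param frame_id,sequence_id,frame_index,label identity attributes.
#' @return An [echo_frame()].
#' @export
render_frame <- function(view, phase, geometry, config, texture = NULL,
                         offset = c(0, 0), frame_id = "f0",
                         sequence_id = "s0", frame_index = 0L,
                         label = view) {
  stopifnot(phase >= 0, phase < 1, nrow(geometry) == chamber_count(view))
  H <- config$image_height; W <- config$image_width
  if (is.null(texture))
    texture <- speckle_texture(H, W, config$baseline_speckle_sigma)
  sec <- sector_mask(config)
  level <- matrix(config$tissue_level, H, W)

  x0 <- (W + 1) / 2
  pulse <- 1 + config$pulsation_amplitude * sin(2 * pi * phase)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  soft <- config$chamber_edge_softness
  wmax <- matrix(0, H, W)      # chamber darkness weight, max over chambers
  for (i in seq_len(nrow(geometry))) {
    cx <- x0 + geometry$cx[i] * W + offset[2]
    cy <- geometry$cy[i] * H + offset[1]
    a <- geometry$a[i] * W * pulse
    b <- geometry$b[i] * H * pulse
    r <- sqrt(((X - cx) / a)^2 + ((Y - cy) / b)^2)
    ## full darkness for r < 1 - soft, blending into tissue at r = 1
    wgt <- if (soft > 0) pmin(1, pmax(0, (1 - r) / soft))
           else as.numeric(r <= 1)
    wmax <- pmax(wmax, wgt)
  }
  level <- level + (config$chamber_level - config$tissue_level) * wmax
  img <- clip01(level * texture)
  img[!sec] <- 0
  echo_frame(img, frame_id = frame_id, sequence_id = sequence_id,
             frame_index = frame_index, label = label)
}

#' Generate one phantom clip
#'
#' All frames of a clip share one sampled chamber geometry; frame `k` of
#' `n` is rendered at phase `k/n` with a small rigid jitter of at most
#' `config$motion_amplitude` pixels, so frames within a clip are more
#' similar to each other than to frames of other clips.
#'
#' @param view one of [view_classes()].
#' @param seed integer seed; generation is fully reproducible from
#'   `(view, seed, config)`.
#' @param config a [phantom_config()].
#' @param sequence_id clip identifier (default derived from view and seed).
#' @param n_frames number of frames (default `config$frames_per_sequence`).
#' @return A list of class `echo_sequence` with elements `sequence_id`,
#'   `view` and `frames` (list of [echo_frame()]).
#' @export
generate_sequence <- function(view, seed, config = phantom_config(),
                              sequence_id = NULL, n_frames = NULL) {
  view <- match.arg(view, view_classes())
  if (is.null(sequence_id)) sequence_id <- sprintf("%s_seed%d", view, seed)
  if (is.null(n_frames)) n_frames <- config$frames_per_sequence
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "sequence", view, sequence_id))
  geometry <- sample_geometry(view, config)
  shared_tex <- if (!config$regenerate_speckle)
    speckle_texture(config$image_height, config$image_width,
                    config$baseline_speckle_sigma)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    offset <- if (config$motion_amplitude > 0)
      stats::runif(2, -config$motion_amplitude, config$motion_amplitude)
    else c(0, 0)
    tex <- if (config$regenerate_speckle) NULL else shared_tex
    frames[[k]] <- render_frame(
      view, phase = (k - 1) / n_frames, geometry = geometry, config = config,
      texture = tex, offset = offset,
      frame_id = sprintf("%s_f%02d", sequence_id, k - 1L),
      sequence_id = sequence_id, frame_index = k - 1L, label = view)
  }
  structure(list(sequence_id = sequence_id, view = view, frames = frames),
            class = "echo_sequence")
}

#' @export
#' @method print echo_sequence
print.echo_sequence <- function(x, ...) {
  cat(sprintf("<echo_sequence %s: view %s, %d frames>\n",
              x$sequence_id, x$view, length(x$frames)))
  invisible(x)
}

## largest-remainder distribution of `total` frames over `n` clips
distribute_frames <- function(total, n) {
  base <- total %/% n
  extra <- total - base * n
  counts <- rep(base, n)
  if (extra > 0) counts[seq_len(extra)] <- base + 1L
  counts
}

#' Generate a full phantom dataset
#'
#' Generates every clip of every class under `config`, returning an
#' in-memory frame list and a manifest; optionally writes 8-bit grayscale
#' PNG frames plus CSV and JSON manifests to `dir`.  Byte-for-byte
#' reproducible from `(config, seed)`.
#'
#' @param config a [phantom_config()].
#' @param seed integer master seed.
#' @param dir optional output directory (created if missing).
#' @param keep_frames logical; keep frames in memory (default `TRUE`).
#' @return List with `manifest` (data frame: `frame_id`, `sequence_id`,
#'   `label`, `frame_index`, `path`) and `frames` (named list of
#'   [echo_frame()], or `NULL` when `keep_frames = FALSE`).
#' @export
generate_dataset <- function(config = phantom_config(), seed = 1L,
                             dir = NULL, keep_frames = TRUE) {
  validate_phantom_config(config)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  rows <- list(); frames <- list()
  for (view in intersect(view_classes(), names(config$sequences_per_class))) {
    nseq <- config$sequences_per_class[[view]]
    counts <- if (!is.null(config$frames_per_class))
      distribute_frames(config$frames_per_class[[view]], nseq)
    else rep(config$frames_per_sequence, nseq)
    for (i in seq_len(nseq)) {
      sid <- sprintf("%s_s%03d", view, i)
      sq <- generate_sequence(view, seed = derive_seed(seed, "clip", view, i),
                              config = config, sequence_id = sid,
                              n_frames = counts[i])
      for (fr in sq$frames) {
        meta <- frame_meta(fr)
        path <- file.path(view, paste0(meta$frame_id, ".png"))
        if (!is.null(dir)) {
          full <- file.path(dir, path)
          if (!dir.exists(dirname(full))) dir.create(dirname(full), TRUE)
          png::writePNG(round(unclass(fr) * 255) / 255, full)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          frame_id = meta$frame_id, sequence_id = meta$sequence_id,
          label = meta$label, frame_index = meta$frame_index, path = path,
          stringsAsFactors = FALSE)
        if (keep_frames) frames[[meta$frame_id]] <- fr
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) write_manifest(manifest, dir)
  list(manifest = manifest, frames = if (keep_frames) frames)
}
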